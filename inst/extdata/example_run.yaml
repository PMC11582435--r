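# Example run configuration for the command-line front end.
#
#   Rscript inst/cli/rpmlogit.R simulate --config example_run.yaml --seed 1 --out out/
#   Rscript inst/cli/rpmlogit.R fit      --config example_run.yaml --seed 1 --out out/
#
# The `fit`/`effects` subcommands read `data`; point it at a CSV written by
# `simulate` (or any casualty-level file matching the scheme).
scheme: default
counts:
  - {year: 2015, season: rainy, n: 1000}
  - {year: 2015, season: dry, n: 800}
data: out/2015_rainy.csv
label: "2015 rainy"
model:
  reference: MI
  fixed:
    SI: [constant, hit_pedestrian, rider, helmet]
    FI: [constant, hit_pedestrian, rider, helmet]
  random:
    - alternative: FI
      covariate: speeding
      mean_covariates: [male]
      var_covariates: [rider]
options:
  R: 200
  burn: 100
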