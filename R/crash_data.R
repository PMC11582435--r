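#' Injury severity levels
#'
#' The outcome of a casualty record is one of three nominal (unordered)
#' severity levels: minor injury (MI), severe injury (SI) and fatal injury
#' (FI). The model treats them as unordered alternatives of a multinomial
#' choice.
#'
#' @return Character vector `c("MI", "SI", "FI")`.
#' @export
severity_levels <- function() c("MI", "SI", "FI")

#' Declare a casualty-record schema
#'
#' A schema names the binary indicator covariates of a casualty-level crash
#' dataset, groups mutually exclusive indicators into blocks (e.g.
#' rider/pillion, the five age bands, the collision types), and declares how
#' the severity outcome is coded on disk.
#'
#' @param covariates Character vector of covariate (indicator) column names.
#' @param exclusive_blocks Named list of character vectors; each vector is a
#'   group of covariate names of which at most one may equal 1 per record.
#' @param exhaustive Character vector naming the entries of
#'   `exclusive_blocks` in which exactly one indicator must equal 1
#'   (e.g. rider/pillion, sex, age bands).
#' @param severity_coding Either `"label"` (severity column holds
#'   MI/SI/FI) or `"integer"` (1 = MI, 2 = SI, 3 = FI).
#' @return An object of class `crash_schema`.
#' @export
crash_schema <- function(covariates, exclusive_blocks = list(),
                         exhaustive = character(0),
                         severity_coding = c("label", "integer")) {
  severity_coding <- match.arg(severity_coding)
  stopifnot(is.character(covariates), length(covariates) > 0,
            !anyDuplicated(covariates))
  for (nm in names(exclusive_blocks)) {
    blk <- exclusive_blocks[[nm]]
    if (!all(blk %in% covariates)) {
      stop("exclusive block '", nm, "' names unknown covariates: ",
           paste(setdiff(blk, covariates), collapse = ", "))
    }
  }
  if (!all(exhaustive %in% names(exclusive_blocks))) {
    stop("'exhaustive' must name entries of 'exclusive_blocks'")
  }
  structure(list(covariates = covariates,
                 exclusive_blocks = exclusive_blocks,
                 exhaustive = exhaustive,
                 severity_coding = severity_coding),
            class = "crash_schema")
}

#' @export
print.crash_schema <- function(x, ...) {
  cat("Casualty-record schema:", length(x$covariates), "indicator covariates,",
      length(x$exclusive_blocks), "exclusive blocks\n")
  invisible(x)
}

validate_crash_rows <- function(df, schema) {
  probs <- character(0)
  for (v in schema$covariates) {
    bad <- which(!(df[[v]] %in% c(0, 1)))
    if (length(bad)) {
      probs <- c(probs, paste0("row ", bad, ": covariate '", v,
                               "' is not in {0,1} (value ", df[[v]][bad], ")"))
    }
  }
  for (nm in names(schema$exclusive_blocks)) {
    blk <- schema$exclusive_blocks[[nm]]
    s <- rowSums(df[, blk, drop = FALSE])
    bad <- which(s > 1)
    if (length(bad)) {
      probs <- c(probs, paste0("row ", bad, ": more than one indicator set in ",
                               "exclusive block '", nm, "'"))
    }
    if (nm %in% schema$exhaustive) {
      bad <- which(s != 1)
      if (length(bad)) {
        probs <- c(probs, paste0("row ", bad,
                                 ": exactly one indicator required in ",
                                 "exhaustive block '", nm, "'"))
      }
    }
  }
  probs
}

#' Construct a casualty-level crash dataset
#'
#' The container for the unit of analysis: one row per casualty with a
#' three-level severity outcome, binary indicator covariates, and optional
#' date / season / year labels. All invariants (binary values, exclusive
#' blocks) are checked on construction.
#'
#' @param data A data.frame with a `severity` column (factor or character in
#'   MI/SI/FI) plus one column per schema covariate; optional `date`,
#'   `season`, `year` columns.
#' @param schema A [crash_schema()].
#' @param label Free-text label, e.g. `"2015 rainy"`.
#' @return An object of class `crash_dataset`.
#' @export
crash_dataset <- function(data, schema, label = "") {
  stopifnot(inherits(schema, "crash_schema"), is.data.frame(data))
  if (!"severity" %in% names(data)) stop("missing severity column")
  miss <- setdiff(schema$covariates, names(data))
  if (length(miss)) stop("missing covariate columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(data) == 0) stop("dataset must contain at least one record (N > 0)")
  sev <- data$severity
  if (is.numeric(sev)) sev <- severity_levels()[sev]
  sev <- factor(as.character(sev), levels = severity_levels())
  if (anyNA(sev)) {
    stop("invalid severity values at rows ",
         paste(which(is.na(sev)), collapse = ", "))
  }
  data$severity <- sev
  if ("date" %in% names(data)) {
    data$date <- as.Date(data$date)
    season <- assign_season(data$date)
    if ("season" %in% names(data)) {
      mism <- which(!is.na(data$date) & as.character(data$season) != season)
      if (length(mism)) {
        stop("season label inconsistent with date at rows ",
             paste(mism, collapse = ", "))
      }
    } else {
      data$season <- season
    }
    if (!"year" %in% names(data)) {
      data$year <- as.integer(format(data$date, "%Y"))
    }
  }
  probs <- validate_crash_rows(data, schema)
  if (length(probs)) {
    stop("invalid casualty records:\n  ",
         paste(utils::head(probs, 10), collapse = "\n  "))
  }
  structure(list(data = data, schema = schema, label = label),
            class = "crash_dataset")
}

#' @export
print.crash_dataset <- function(x, ...) {
  tab <- table(x$data$severity)
  cat("crash_dataset", if (nzchar(x$label)) paste0("'", x$label, "'"),
      ": N =", nrow(x$data), "casualties\n")
  cat("  severity: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  covariates:", length(x$schema$covariates), "binary indicators\n")
  invisible(x)
}

#' @export
dim.crash_dataset <- function(x) dim(x$data)

#' Number of casualty records
#' @param dataset A [crash_dataset()].
#' @return Integer record count.
#' @export
n_records <- function(dataset) nrow(dataset$data)

#' Read a casualty-level crash dataset from delimited text
#'
#' Reads a delimited file with a header row, validates every record against
#' the schema, and returns a [crash_dataset()]. Severity may be coded as
#' labels (MI/SI/FI) or integers (1/2/3), as declared in the schema. Rows
#' with missing covariate values are dropped with a message (mirroring the
#' usual police-registry cleaning step); rows violating the binary or
#' exclusive-block invariants raise an error naming the row and column.
#'
#' @param path Path to a delimited text file.
#' @param schema A [crash_schema()].
#' @param sep Field delimiter (default comma).
#' @param label Dataset label.
#' @return A [crash_dataset()].
#' @export
read_crash_data <- function(path, schema, sep = ",", label = "") {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!"severity" %in% names(df)) stop("missing severity column in ", path)
  if (schema$severity_coding == "integer") {
    sv <- suppressWarnings(as.integer(df$severity))
    if (anyNA(sv) || any(!(sv %in% 1:3))) {
      stop("severity column must be coded 1/2/3 under integer coding")
    }
    df$severity <- severity_levels()[sv]
  }
  keep <- stats::complete.cases(df[, c("severity", schema$covariates)])
  if (any(!keep)) {
    message("dropping ", sum(!keep), " record(s) with missing values")
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  crash_dataset(df, schema, label = label)
}

#' Write a crash dataset to delimited text
#'
#' Inverse of [read_crash_data()]: severity is written in the schema's
#' on-disk coding.
#'
#' @param dataset A [crash_dataset()].
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_crash_data <- function(dataset, path, sep = ",") {
  df <- dataset$data
  if (dataset$schema$severity_coding == "integer") {
    df$severity <- as.integer(df$severity)
  } else {
    df$severity <- as.character(df$severity)
  }
  if ("date" %in% names(df)) df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign monsoon season from a calendar date
#'
#' The study window splits each calendar year into a rainy season
#' (May 1 to November 30) and a dry season (December 1 to April 30);
#' every date is classified by its month. Dry-season records spanning the
#' New Year keep the calendar year of the crash date as their year label.
#'
#' @param date A `Date` vector (or coercible).
#' @return Character vector with values `"rainy"` / `"dry"`.
#' @export
assign_season <- function(date) {
  date <- as.Date(date)
  if (anyNA(date)) stop("invalid calendar date")
  m <- as.integer(format(date, "%m"))
  ifelse(m >= 5L & m <= 11L, "rainy", "dry")
}

#' Season-by-severity contingency table
#'
#' Cross-tabulates severity counts over a list of season-labelled datasets
#' (typically the rainy and dry subsets of one year), in the layout used for
#' seasonal chi-square testing.
#'
#' @param datasets List of [crash_dataset()] objects; names (or labels) give
#'   the row labels.
#' @return An object of class `contingency_table`: an integer matrix with
#'   season rows and severity columns.
#' @export
build_contingency <- function(datasets) {
  if (length(datasets) == 0) stop("empty dataset list")
  labs <- names(datasets)
  if (is.null(labs)) labs <- vapply(datasets, function(d) d$label, "")
  counts <- t(vapply(datasets,
                     function(d) as.integer(table(d$data$severity)),
                     integer(3)))
  dimnames(counts) <- list(labs, severity_levels())
  structure(counts, class = c("contingency_table", "matrix"))
}

#' Construct a contingency table from raw counts
#'
#' @param counts Numeric matrix of non-negative integer counts.
#' @param row_labels,col_labels Dimension labels; defaults are seasons and
#'   severity levels.
#' @return A `contingency_table`.
#' @export
contingency_table <- function(counts,
                              row_labels = c("rainy", "dry"),
                              col_labels = severity_levels()) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(counts) <= 0) || any(colSums(counts) <= 0)) {
    stop("row and column sums must be positive")
  }
  dimnames(counts) <- list(row_labels, col_labels)
  structure(counts, class = c("contingency_table", "matrix"))
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- unclass(x)
  m <- cbind(m, Total = rowSums(m))
  m <- rbind(m, Total = colSums(m))
  print(m)
  invisible(x)
}
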