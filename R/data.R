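#' Construct and validate a competing-risk dataset
#'
#' A competing-risk dataset is a tibble with one row per subject holding a
#' unique subject identifier, a strictly positive follow-up time, a status
#' code (0 = censored, 1 = primary event, 2 = competing event) and zero or
#' more numeric covariate columns. More than one competing cause must be
#' collapsed to code 2 before construction. The time unit is caller-defined
#' and never interpreted; all prediction horizons must be expressed in the
#' same unit.
#'
#' @param data A data frame with the columns named below.
#' @param id_col,time_col,status_col Names of the identifier, follow-up time
#'   and status columns. Defaults `"id"`, `"time"`, `"status"`.
#' @param covariate_cols Character vector of covariate column names. `NULL`
#'   (default) takes every remaining column.
#'
#' @return A tibble of class `cr_data` with columns `id`, `time`, `status`
#'   followed by the covariates, in their original row order. The covariate
#'   names are stored in the `"covariates"` attribute.
#'
#' @examples
#' d <- cr_data(data.frame(id = 1:4, time = c(1, 2, 3, 4),
#'                         status = c(1, 0, 2, 0), x = rnorm(4)))
#' table(d$status)
#' @export
cr_data <- function(data, id_col = "id", time_col = "time",
                    status_col = "status", covariate_cols = NULL) {
  data <- as.data.frame(data)
  needed <- c(id_col, time_col, status_col, covariate_cols)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop_crcalib(
      sprintf("Column(s) not found in data: %s.",
              paste(missing_cols, collapse = ", ")),
      "crcalib_error_missing_column")
  }
  if (is.null(covariate_cols)) {
    covariate_cols <- setdiff(names(data), c(id_col, time_col, status_col))
  }

  time <- data[[time_col]]
  if (!is.numeric(time)) {
    stop_crcalib("Follow-up time column must be numeric.",
                 "crcalib_error_time")
  }
  bad_time <- which(!is.finite(time) | time <= 0)
  if (length(bad_time) > 0) {
    stop_crcalib(
      sprintf("Follow-up times must be strictly positive and finite; offending row(s): %s.",
              paste(head(bad_time, 5L), collapse = ", ")),
      "crcalib_error_time")
  }

  status <- data[[status_col]]
  bad_status <- which(!(status %in% c(0, 1, 2)))
  if (length(bad_status) > 0) {
    stop_crcalib(
      sprintf("Status codes must be 0 (censored), 1 (primary) or 2 (competing); offending row(s): %s.",
              paste(head(bad_status, 5L), collapse = ", ")),
      "crcalib_error_status")
  }

  id <- data[[id_col]]
  if (anyDuplicated(id)) {
    stop_crcalib(
      sprintf("Subject identifiers must be unique; duplicated: %s.",
              paste(head(unique(id[duplicated(id)]), 5L), collapse = ", ")),
      "crcalib_error_duplicate_id")
  }

  for (cv in covariate_cols) {
    v <- data[[cv]]
    if (!is.numeric(v)) {
      stop_crcalib(sprintf("Covariate column '%s' must be numeric.", cv),
                   "crcalib_error_covariate")
    }
    if (anyNA(v)) {
      stop_crcalib(sprintf("Covariate column '%s' contains missing values.", cv),
                   "crcalib_error_missing_values")
    }
  }

  out <- tibble(id = id, time = as.numeric(time), status = as.integer(status))
  for (cv in covariate_cols) out[[cv]] <- as.numeric(data[[cv]])
  structure(out, covariates = covariate_cols,
            class = c("cr_data", class(out)))
}

#' Read a competing-risk dataset from a CSV file
#'
#' The expected dialect is comma-separated, header row required, `.` decimal
#' mark, UTF-8 encoding. Validation is identical to [cr_data()]: each
#' violation (missing column, non-numeric or non-positive time, status code
#' outside \{0,1,2\}, duplicated id, missing covariate value) raises a
#' distinct, named error.
#'
#' @inheritParams cr_data
#' @param path Path to the CSV file.
#' @return A validated [cr_data] tibble, row order preserved.
#' @seealso [write_cr_data()]
#' @export
read_cr_data <- function(path, id_col = "id", time_col = "time",
                         status_col = "status", covariate_cols = NULL) {
  if (!file.exists(path)) {
    stop_crcalib(sprintf("File not found: %s", path), "crcalib_error_io")
  }
  raw <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  cr_data(raw, id_col = id_col, time_col = time_col,
          status_col = status_col, covariate_cols = covariate_cols)
}

#' Write a competing-risk dataset to a CSV file
#'
#' Writes the same dialect [read_cr_data()] expects, so
#' `read_cr_data(write_cr_data(d, path))` reproduces `d` exactly, including
#' column order.
#'
#' @param data A [cr_data] tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cr_data <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Attach a prediction horizon to a vector of predicted risks
#'
#' Bundles externally produced predicted cumulative-incidence values at a
#' fixed horizon `t0` into a one-column tibble carrying the horizon as an
#' attribute. Any prediction model may produce the values; they only need to
#' be probabilities aligned with the rows of the dataset they refer to.
#'
#' @param predicted Numeric vector of predicted risks in \[0, 1\].
#' @param horizon Positive prediction horizon `t0`, in the time unit of the
#'   accompanying dataset.
#' @return A tibble of class `risk_predictions` with column `predicted` and
#'   attribute `horizon`.
#' @export
risk_predictions <- function(predicted, horizon) {
  assert_scalar_number(horizon, "horizon", positive = TRUE)
  if (!is.numeric(predicted) || anyNA(predicted) ||
      any(predicted < 0 | predicted > 1)) {
    stop_crcalib("Predicted risks must be numeric values in [0, 1].",
                 "crcalib_error_prediction")
  }
  structure(tibble(predicted = as.numeric(predicted)),
            horizon = as.numeric(horizon),
            class = c("risk_predictions", class(tibble())))
}

# resolve (predictions, t0) from either a risk_predictions object or a bare
# numeric vector plus explicit t0
resolve_predictions <- function(predictions, t0, n) {
  if (inherits(predictions, "risk_predictions")) {
    pred <- predictions$predicted
    t0 <- t0 %||% attr(predictions, "horizon")
  } else {
    pred <- as.numeric(predictions)
    if (anyNA(pred) || any(pred < 0 | pred > 1)) {
      stop_crcalib("Predicted risks must be numeric values in [0, 1].",
                   "crcalib_error_prediction")
    }
  }
  if (is.null(t0)) {
    stop_crcalib("A prediction horizon `t0` is required.",
                 "crcalib_error_argument")
  }
  assert_scalar_number(t0, "t0", positive = TRUE)
  if (length(pred) != n) {
    stop_crcalib("Predictions must be aligned with the dataset (same length).",
                 "crcalib_error_prediction")
  }
  list(predicted = pred, t0 = t0)
}
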