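#' Right-continuous step functions of time
#'
#' The nonparametric estimators in this package (censoring-distribution
#' Kaplan-Meier, Aalen-Johansen cumulative incidence, Breslow baseline
#' cumulative subdistribution hazard) are all right-continuous piecewise
#' constant functions of time. `step_function()` builds one from its jump
#' locations: the function equals `initial_value` on `[0, jump_times[1])` and
#' `values[i]` on `[jump_times[i], jump_times[i + 1])`.
#'
#' @param jump_times Strictly increasing, strictly positive jump locations.
#' @param values Function value attained at (and right of) each jump.
#' @param initial_value Value on `[0, jump_times[1])`. Default 1 suits
#'   survival-type functions; use 0 for cumulative-type functions.
#' @return An object of class `cr_step`.
#' @examples
#' G <- step_function(c(2, 4), c(2 / 3, 0))
#' eval_step(G, 3)            # 2/3
#' eval_step(G, 2, "left")    # 1
#' @export
step_function <- function(jump_times, values, initial_value = 1) {
  jump_times <- as.numeric(jump_times)
  values <- as.numeric(values)
  if (length(jump_times) != length(values)) {
    stop_crcalib("`jump_times` and `values` must have equal length.",
                 "crcalib_error_step")
  }
  if (length(jump_times) > 0) {
    if (any(!is.finite(jump_times)) || any(jump_times <= 0) ||
        any(diff(jump_times) <= 0)) {
      stop_crcalib("`jump_times` must be strictly increasing positive reals.",
                   "crcalib_error_step")
    }
  }
  structure(list(jump_times = jump_times, values = values,
                 initial_value = as.numeric(initial_value)),
            class = "cr_step")
}

#' Evaluate a step function
#'
#' @param f A [step_function()] object.
#' @param t Nonnegative evaluation times (vectorised).
#' @param side `"right"` returns `f(t)` (the right-continuous value);
#'   `"left"` returns the left limit `f(t-)`. Before the first jump both
#'   sides return the initial value. Left evaluation is what the
#'   inverse-probability-of-censoring weights require (`G(t-)`).
#' @return Numeric vector of function values.
#' @export
eval_step <- function(f, t, side = c("right", "left")) {
  side <- match.arg(side)
  t <- as.numeric(t)
  if (anyNA(t) || any(t < 0)) {
    stop_crcalib("Evaluation times must be nonnegative.", "crcalib_error_step")
  }
  if (length(f$jump_times) == 0) {
    return(rep(f$initial_value, length(t)))
  }
  idx <- findInterval(t, f$jump_times, left.open = (side == "left"))
  out <- c(f$initial_value, f$values)[idx + 1L]
  out
}

#' @export
print.cr_step <- function(x, ...) {
  cat("<cr_step> right-continuous step function\n")
  cat("  initial value:", format(x$initial_value), "\n")
  cat("  jumps:", length(x$jump_times), "\n")
  if (length(x$jump_times) > 0) {
    k <- min(5L, length(x$jump_times))
    cat("  first jumps at", paste(format(x$jump_times[seq_len(k)], digits = 4),
                                  collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method as_tibble cr_step
#' @export
as_tibble.cr_step <- function(x, ...) {
  tibble(time = x$jump_times, value = x$values)
}

#' Serialize a step function to CSV
#'
#' Writes a two-column CSV (`time`, `value`) preceded by a `#` comment line
#' carrying the initial value, the format [read_step_function()] reads back.
#'
#' @param f A [step_function()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_step_function <- function(f, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# initial_value=%.17g", f$initial_value), con)
  writeLines("time,value", con)
  if (length(f$jump_times) > 0) {
    writeLines(sprintf("%.17g,%.17g", f$jump_times, f$values), con)
  }
  invisible(path)
}

#' Read a step function from CSV
#'
#' @param path Path written by [write_step_function()].
#' @return A [step_function()] object.
#' @export
read_step_function <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 || !grepl("^# *initial_value=", lines[1])) {
    stop_crcalib("Missing '# initial_value=' header comment.",
                 "crcalib_error_io")
  }
  iv <- as.numeric(sub("^# *initial_value=", "", lines[1]))
  body <- utils::read.csv(text = lines[-1], header = TRUE)
  step_function(body$time, body$value, initial_value = iv)
}
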