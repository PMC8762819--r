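# internal helpers

# all quantiles in the package use the linear-interpolation (type 7) convention
quantile7 <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
}

stop_crcalib <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "crcalib_error"), ...)
}

# derive a stream of per-replicate seeds from one master seed; values stay
# below 2^31 so they are valid R integer seeds
derive_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed), {
    sample.int(.Machine$integer.max - 1L, n)
  })
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_crcalib(sprintf("`%s` must be a single finite number.", name),
                 "crcalib_error_argument")
  }
  if (positive && x <= 0) {
    stop_crcalib(sprintf("`%s` must be strictly positive.", name),
                 "crcalib_error_argument")
  }
  invisible(x)
}
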