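#' Percentile-based knot placement for restricted cubic splines
#'
#' Places the knots of a restricted (natural) cubic spline at fixed sample
#' percentiles, following Harrell's convention: 3 knots at the 10th/50th/90th
#' percentiles, 4 knots at the 5th/35th/65th/95th, and 5 knots at the
#' 5th/27.5th/50th/72.5th/95th. Percentiles are computed with the
#' linear-interpolation (type 7) definition.
#'
#' @param values Numeric vector the spline will be fitted over.
#' @param k Number of knots: 3, 4 or 5.
#' @return Strictly increasing numeric vector of `k` knot locations.
#' @export
place_knots <- function(values, k = 3) {
  if (!k %in% c(3, 4, 5)) {
    stop_crcalib("`k` must be 3, 4 or 5.", "crcalib_error_argument")
  }
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop_crcalib("`values` must be finite and non-missing.",
                 "crcalib_error_argument")
  }
  if (length(unique(values)) < k) {
    stop_crcalib(
      sprintf("Need at least %d distinct values to place %d knots.", k, k),
      "crcalib_error_knot_degeneracy")
  }
  probs <- switch(as.character(k),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95))
  knots <- quantile7(values, probs)
  if (any(diff(knots) <= 0)) {
    stop_crcalib(
      "Computed knots are not strictly increasing (degenerate distribution).",
      "crcalib_error_knot_degeneracy")
  }
  knots
}

#' Restricted cubic spline design matrix
#'
#' Builds the `k - 1` column design of a restricted cubic spline with knots
#' `t_1 < ... < t_k`: the first column is `x` itself; nonlinear column
#' `j` (for `j = 1, ..., k - 2`) is
#' \deqn{[(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'       + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / c,}
#' which constrains the spline to be exactly linear below the first and above
#' the last knot. The normalization constant `c = (t_k - t_1)^2` (default)
#' only rescales coefficients; fitted values are invariant to it.
#'
#' @param x Numeric vector of evaluation points.
#' @param knots Strictly increasing knot vector of length 3, 4 or 5,
#'   typically from [place_knots()].
#' @param normalize If `TRUE` (default) divide the nonlinear columns by
#'   `(t_k - t_1)^2` for numeric conditioning; `FALSE` uses constant 1.
#' @return Numeric matrix with `length(x)` rows and `length(knots) - 1`
#'   columns, named `s1, s2, ...`.
#' @export
rcs_design <- function(x, knots, normalize = TRUE) {
  knots <- as.numeric(knots)
  k <- length(knots)
  if (!k %in% c(3, 4, 5) || any(diff(knots) <= 0)) {
    stop_crcalib("`knots` must be a strictly increasing vector of length 3-5.",
                 "crcalib_error_argument")
  }
  x <- as.numeric(x)
  norm_c <- if (normalize) (knots[k] - knots[1])^2 else 1
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, nrow = length(x), ncol = k - 1,
                dimnames = list(NULL, paste0("s", seq_len(k - 1))))
  out[, 1] <- x
  tk <- knots[k]
  tk1 <- knots[k - 1]
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (pos3(x - tj) -
                       pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                       pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm_c
  }
  out
}
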