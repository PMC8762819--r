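#' Complementary log-log transform
#'
#' `log(-log(1 - p))`, the transform that linearises predicted cumulative
#' incidence on the Fine-Gray linear-predictor scale. Inputs are clipped to
#' `[1e-10, 1 - 1e-10]` so that 0 and 1 map to large finite values.
#'
#' @param p Numeric vector of probabilities in \[0, 1\].
#' @return Numeric vector of transformed values.
#' @examples
#' cloglog(1 - exp(-1))  # 0
#' @export
cloglog <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop_crcalib("`p` must be numeric values in [0, 1].",
                 "crcalib_error_argument")
  }
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  log(-log1p(-p))
}

#' Numerical calibration metrics
#'
#' Summaries of the per-subject absolute difference between smoothed
#' observed risk and predicted risk: the integrated calibration index
#' `ICI` (mean), `E50` (median), `E90` (90th percentile,
#' linear-interpolation convention) and `Emax` (maximum).
#'
#' @param predicted,observed Equal-length vectors of probabilities in
#'   \[0, 1\]; `observed` is typically the smoothed observed risk from a
#'   calibration curve.
#' @return A one-row tibble with columns `ici`, `e50`, `e90`, `emax`.
#' @examples
#' calibration_metrics(c(0.10, 0.20, 0.30, 0.40),
#'                     c(0.12, 0.18, 0.36, 0.38))
#' @export
calibration_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 1) {
    stop_crcalib("`predicted` and `observed` must have equal, positive length.",
                 "crcalib_error_argument")
  }
  if (anyNA(predicted) || anyNA(observed) ||
      any(predicted < 0 | predicted > 1) || any(observed < 0 | observed > 1)) {
    stop_crcalib("Metric inputs must be probabilities in [0, 1].",
                 "crcalib_error_argument")
  }
  d <- abs(observed - predicted)
  tibble(ici = mean(d), e50 = median(d), e90 = quantile7(d, 0.90),
         emax = max(d))
}

#' Smoothed calibration curve for a competing-risk prediction model
#'
#' Assesses, at horizon `t0`, the agreement between externally produced
#' predicted cumulative-incidence values and the risk actually observed in
#' the data, accounting for competing events. A secondary Fine-Gray model
#' regresses the subdistribution hazard of the primary event on a restricted
#' cubic spline in the complementary log-log of the predicted risk; the
#' secondary model's predicted cumulative incidence at `t0` is the smoothed
#' "observed" risk for each subject. The curve of observed versus predicted
#' risk should track the diagonal when the prediction model is well
#' calibrated.
#'
#' Knots are placed at Harrell's percentiles of the transformed predictions;
#' the display grid spans the 1st to 99th percentile of the predicted risks
#' (100 equally spaced values by default). The ICI/E50/E90/Emax metrics are
#' always computed from the per-subject values, never from the display grid.
#'
#' @param data A [cr_data] tibble.
#' @param predictions A [risk_predictions()] object or a numeric vector of
#'   predicted risks aligned with `data`.
#' @param t0 Prediction horizon; defaults to the horizon carried by
#'   `predictions`.
#' @param n_knots Number of spline knots (3, 4 or 5). Default 3, the value
#'   that gave the best calibration of a correctly specified model in the
#'   knot-selection simulations.
#' @param administrative_censor_at_t0 If `TRUE`, subjects with follow-up
#'   beyond `t0` are recoded as censored at `t0` before fitting the
#'   secondary model; a safeguard when proportional subdistribution hazards
#'   are in doubt. Default `FALSE`.
#' @param grid_size Number of display-grid points.
#' @param expansion Advanced: a precomputed [fg_expand()] result for `data`,
#'   reusable across horizons because the expansion depends only on times
#'   and status. Ignored when `administrative_censor_at_t0` is `TRUE`.
#' @return An object of class `cr_calibration`: a list with `t0`, `n_knots`,
#'   `predicted` and `observed` (per subject), `curve` (a tibble with the
#'   display grid), `metrics` (a one-row tibble) and the secondary-model
#'   `fit`.
#' @export
calibration_curve <- function(data, predictions, t0 = NULL, n_knots = 3,
                              administrative_censor_at_t0 = FALSE,
                              grid_size = 100L, expansion = NULL) {
  resolved <- resolve_predictions(predictions, t0, nrow(data))
  predicted <- resolved$predicted
  t0 <- resolved$t0
  if (t0 > max(data$time)) {
    stop_crcalib("`t0` lies beyond the observed follow-up.",
                 "crcalib_error_argument")
  }
  if (administrative_censor_at_t0) {
    over <- data$time > t0
    data$status[over] <- 0L
    data$time[over] <- t0
    expansion <- NULL
  }

  cll <- cloglog(predicted)
  knots <- place_knots(cll, n_knots)
  basis <- rcs_design(cll, knots)
  fit_data <- data
  for (j in seq_len(ncol(basis))) fit_data[[paste0("cal_s", j)]] <- basis[, j]
  cov_names <- paste0("cal_s", seq_len(ncol(basis)))

  fit <- withCallingHandlers(
    fine_gray(fit_data, cov_names, expansion = expansion),
    crcalib_warning_nonconvergence = function(w) {
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) {
    stop_crcalib("Secondary calibration model did not converge.",
                 "crcalib_error_nonconvergence", fit = fit)
  }

  observed <- predict(fit, fit_data, t0)

  bounds <- quantile7(predicted, c(0.01, 0.99))
  grid_pred <- seq(bounds[1], bounds[2], length.out = grid_size)
  grid_basis <- rcs_design(cloglog(grid_pred), knots)
  colnames(grid_basis) <- cov_names
  grid_obs <- predict(fit, as.data.frame(grid_basis), t0)

  structure(list(t0 = t0, n_knots = n_knots,
                 predicted = predicted, observed = observed,
                 curve = tibble(predicted = grid_pred, observed = grid_obs),
                 metrics = calibration_metrics(predicted, observed),
                 knots = knots, fit = fit,
                 administrative_censor_at_t0 = administrative_censor_at_t0),
            class = "cr_calibration")
}

#' @export
print.cr_calibration <- function(x, ...) {
  cat(sprintf("Calibration at t0 = %.4g (%d subjects, %d-knot spline)\n",
              x$t0, length(x$predicted), x$n_knots))
  m <- x$metrics
  cat(sprintf("  ICI %.4f | E50 %.4f | E90 %.4f | Emax %.4f\n",
              m$ici, m$e50, m$e90, m$emax))
  invisible(x)
}

#' @rdname calibration_curve
#' @param x A `cr_calibration` object.
#' @param ... Unused.
#' @method tidy cr_calibration
#' @export
tidy.cr_calibration <- function(x, ...) {
  x$curve
}

#' @rdname calibration_curve
#' @method glance cr_calibration
#' @export
glance.cr_calibration <- function(x, ...) {
  dplyr::bind_cols(tibble(t0 = x$t0, n = length(x$predicted),
                          n_knots = x$n_knots), x$metrics)
}

#' Decile-binned calibration comparator
#'
#' The stratified comparator: subjects are grouped by quantiles of predicted
#' risk and, within each bin, the mean predicted risk is compared with the
#' observed risk, estimated by the Aalen-Johansen cumulative incidence for
#' the primary event at `t0` among the bin's subjects. Bin boundaries are
#' prediction quantiles, so tied prediction values are never split across
#' bins.
#'
#' @inheritParams calibration_curve
#' @param n_bins Number of quantile bins (default 10).
#' @return A tibble with one row per bin: `bin`, `n`, `mean_predicted`,
#'   `observed`.
#' @export
binned_calibration <- function(data, predictions, t0 = NULL, n_bins = 10L) {
  if (n_bins < 2) {
    stop_crcalib("`n_bins` must be at least 2.", "crcalib_error_argument")
  }
  resolved <- resolve_predictions(predictions, t0, nrow(data))
  predicted <- resolved$predicted
  t0 <- resolved$t0
  breaks <- unique(quantile7(predicted, seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 3) {
    stop_crcalib("Too few distinct predicted values to form bins.",
                 "crcalib_error_bin_degeneracy")
  }
  grp <- cut(predicted, breaks, include.lowest = TRUE, labels = FALSE)
  counts <- tabulate(grp, nbins = length(breaks) - 1)
  if (any(counts == 0)) {
    stop_crcalib("Quantile binning produced an empty bin.",
                 "crcalib_error_bin_degeneracy")
  }
  purrr::map_dfr(seq_len(length(breaks) - 1), function(b) {
    idx <- which(grp == b)
    cif <- aalen_johansen(data[idx, ], cause = 1)
    tibble(bin = b, n = length(idx),
           mean_predicted = mean(predicted[idx]),
           observed = eval_step(cif, t0))
  })
}
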