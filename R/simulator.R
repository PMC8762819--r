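#' Configuration of the competing-risk data-generating process
#'
#' The generator uses indirect simulation from a Fine-Gray subdistribution
#' model. A standard-normal covariate `x` (or a bivariate-normal pair with
#' correlation `rho` in the two-covariate design) drives the subject-specific
#' probability of the primary event: the event-type indicator `Z` is
#' Bernoulli with parameter \eqn{1 - (1 - p)^{\exp(lp_1)}}, where `p` is the
#' proportion of subjects with covariate 0 who experience the primary event
#' as `t` tends to infinity and `lp1` is the primary-event linear predictor.
#' Primary-event times are drawn by inverse transform from the conditional
#' subdistribution; competing-event times are exponential with rate
#' `exp(lp2)`. The observed event time is `Z T1 + (1 - Z) T2`. Optional
#' exponential censoring is applied at a rate calibrated by
#' [calibrate_censoring_rate()] so that a target proportion of subjects is
#' censored.
#'
#' Linear predictors by design:
#' * default: `lp1 = beta1 * x`, `lp2 = beta2 * x`;
#' * `quadratic = TRUE`: `lp1 = beta1 * x + 0.25 * beta1 * x^2` (same `lp2`);
#' * `two_covariate = list(rho, beta2)`:
#'   `lp1 = 0.50 * x1 + beta2 * x2`, `lp2 = 0.25 * x1 + 0.25 * x2`, with
#'   `cor(x1, x2) = rho` and no censoring.
#'
#' `p_validation`, when set, replaces `p` in outcome generation only; the
#' covariate distribution is untouched. This emulates a validation population
#' whose incidence differs from the derivation population's.
#'
#' @param n Number of subjects.
#' @param p Limiting primary-event proportion at covariate 0, in (0, 1).
#' @param beta1 Log subdistribution hazard ratio for the primary event.
#' @param beta2 Log subdistribution hazard ratio for the competing event.
#' @param censor_proportion Target censored proportion in \[0, 1).
#' @param quadratic Use the quadratic primary-event linear predictor.
#' @param two_covariate `NULL` or `list(rho =, beta2 =)` for the
#'   two-covariate design (mutually exclusive with `quadratic`).
#' @param p_validation Optional shifted incidence parameter for outcome
#'   generation.
#' @param censor_rate Optional precomputed exponential censoring rate; when
#'   `NULL` and `censor_proportion > 0` it is calibrated on first use.
#' @param seed Default seed used by [generate_cr()] when none is supplied.
#' @return A list of class `dgp_config`.
#' @export
dgp_config <- function(n, p, beta1 = 1, beta2 = 0.25,
                       censor_proportion = 0, quadratic = FALSE,
                       two_covariate = NULL, p_validation = NULL,
                       censor_rate = NULL, seed = NULL) {
  assert_scalar_number(n, "n", positive = TRUE)
  assert_scalar_number(p, "p")
  if (p <= 0 || p > 1) {
    stop_crcalib("`p` must lie in (0, 1].", "crcalib_error_argument")
  }
  assert_scalar_number(censor_proportion, "censor_proportion")
  if (censor_proportion < 0 || censor_proportion >= 1) {
    stop_crcalib("`censor_proportion` must lie in [0, 1).",
                 "crcalib_error_argument")
  }
  if (isTRUE(quadratic) && !is.null(two_covariate)) {
    stop_crcalib("`quadratic` and `two_covariate` are mutually exclusive.",
                 "crcalib_error_argument")
  }
  if (!is.null(two_covariate)) {
    if (!is.list(two_covariate) ||
        !all(c("rho", "beta2") %in% names(two_covariate))) {
      stop_crcalib("`two_covariate` must be list(rho =, beta2 =).",
                   "crcalib_error_argument")
    }
    if (abs(two_covariate$rho) > 1) {
      stop_crcalib("`two_covariate$rho` must lie in [-1, 1].",
                   "crcalib_error_argument")
    }
    if (censor_proportion > 0) {
      stop_crcalib("The two-covariate design does not use censoring.",
                   "crcalib_error_argument")
    }
  }
  if (!is.null(p_validation) && (p_validation <= 0 || p_validation > 1)) {
    stop_crcalib("`p_validation` must lie in (0, 1].",
                 "crcalib_error_argument")
  }
  structure(list(n = as.integer(n), p = p, beta1 = beta1, beta2 = beta2,
                 censor_proportion = censor_proportion,
                 quadratic = isTRUE(quadratic),
                 two_covariate = two_covariate,
                 p_validation = p_validation,
                 censor_rate = censor_rate,
                 seed = seed),
            class = "dgp_config")
}

# draw covariates and uncensored outcomes under the current RNG state
sim_outcomes <- function(config, n) {
  if (!is.null(config$two_covariate)) {
    rho <- config$two_covariate$rho
    x1 <- rnorm(n)
    x2 <- rho * x1 + sqrt(1 - rho^2) * rnorm(n)
    X <- cbind(x1 = x1, x2 = x2)
    lp1 <- 0.50 * x1 + config$two_covariate$beta2 * x2
    lp2 <- 0.25 * x1 + 0.25 * x2
  } else {
    x <- rnorm(n)
    X <- cbind(x = x)
    lp1 <- if (config$quadratic) {
      config$beta1 * x + 0.25 * config$beta1 * x^2
    } else {
      config$beta1 * x
    }
    lp2 <- config$beta2 * x
  }
  p_eff <- config$p_validation %||% config$p
  elp1 <- exp(lp1)
  phi <- -expm1(elp1 * log1p(-p_eff))   # 1 - (1 - p)^exp(lp1)
  z <- rbinom(n, 1L, phi)
  u <- runif(n)
  while (any(u <= 0 | u >= 1)) {
    bad <- u <= 0 | u >= 1
    u[bad] <- runif(sum(bad))
  }
  # inverse-transform draw from the conditional subdistribution of T1 | Z = 1
  draw_t1 <- function(u) {
    ip <- exp(log1p(-u * phi) / elp1)   # (1 - u * phi)^(1 / exp(lp1))
    -log1p(-(1 - ip) / p_eff)
  }
  t1 <- draw_t1(u)
  # u in the extreme upper tail can make (1 - u*phi)^(1/e^lp1) round to
  # 1 - p, sending t1 to Inf; redraw those u
  for (i in 1:100) {
    bad <- !is.finite(t1)
    if (!any(bad)) break
    u[bad] <- runif(sum(bad))
    t1[bad] <- draw_t1(u)[bad]
  }
  t2 <- rexp(n, rate = exp(lp2))
  list(time = ifelse(z == 1L, t1, t2), z = z, X = X)
}

#' Generate a competing-risk sample
#'
#' Draws `config$n` subjects from the data-generating process described in
#' [dgp_config()]. Fully reproducible: identical seeds give bit-identical
#' datasets, and the caller's RNG state is left untouched.
#'
#' @param config A [dgp_config()] object.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A [cr_data] tibble with covariate column `x` (or `x1`, `x2`).
#' @export
generate_cr <- function(config, seed = config$seed) {
  if (is.null(seed)) {
    stop_crcalib("A seed is required (in the config or as an argument).",
                 "crcalib_error_argument")
  }
  rate <- config$censor_rate
  if (config$censor_proportion > 0 && is.null(rate)) {
    rate <- calibrate_censoring_rate(config)
  }
  withr::with_seed(as.integer(seed), {
    out <- sim_outcomes(config, config$n)
    if (config$censor_proportion > 0) {
      cc <- rexp(config$n, rate = rate)
      time <- pmin(out$time, cc)
      status <- ifelse(cc < out$time, 0L, ifelse(out$z == 1L, 1L, 2L))
    } else {
      time <- out$time
      status <- ifelse(out$z == 1L, 1L, 2L)
    }
    df <- data.frame(id = seq_len(config$n), time = time, status = status)
    df <- cbind(df, as.data.frame(out$X))
    cr_data(df, covariate_cols = colnames(out$X))
  })
}

#' Closed-form true cumulative incidence of the primary event
#'
#' Under the default (linear, single-covariate) data-generating process the
#' cause-1 subdistribution is exactly a Fine-Gray model, with true CIF
#' \deqn{F_1(t \mid x) = 1 - \{1 - p (1 - e^{-t})\}^{\exp(\beta_1 x)}.}
#' At `x = 0` the value tends to `p` as `t` grows, matching the definition
#' of `p`. This is the oracle the nonparametric and Fine-Gray estimators are
#' checked against.
#'
#' @param x Covariate value(s).
#' @param t Nonnegative time(s).
#' @param p Limiting incidence at covariate 0.
#' @param beta1 Primary-event log subdistribution hazard ratio.
#' @return Cumulative incidence value(s) in \[0, 1\].
#' @export
true_cif <- function(x, t, p, beta1) {
  if (any(t < 0)) {
    stop_crcalib("`t` must be nonnegative.", "crcalib_error_argument")
  }
  1 - (1 - p * (1 - exp(-t)))^exp(beta1 * x)
}

#' Calibrate the exponential censoring rate by bisection
#'
#' Finds the exponential rate at which the proportion of censored subjects in
#' a large super-population equals the target. Event times and censoring
#' uniforms are drawn once under a fixed internal seed; the censored
#' proportion is then a monotone increasing function of the rate, and
#' bisection over `bracket` runs until the proportion is within `tol` of the
#' target.
#'
#' @param config A [dgp_config()] object.
#' @param target Target censored proportion; defaults to
#'   `config$censor_proportion`. A target of 0 returns rate 0 immediately.
#' @param superpop_n Super-population size used in the search.
#' @param tol Tolerance on the censored proportion.
#' @param bracket Search interval for the rate.
#' @param seed Internal seed for the super-population draw.
#' @return The calibrated rate (a positive scalar, or 0 when `target` is 0).
#' @export
calibrate_censoring_rate <- function(config,
                                     target = config$censor_proportion,
                                     superpop_n = 200000L, tol = 0.001,
                                     bracket = c(1e-6, 100),
                                     seed = 20220117L) {
  assert_scalar_number(target, "target")
  if (target < 0 || target >= 1) {
    stop_crcalib("`target` must lie in [0, 1).", "crcalib_error_argument")
  }
  if (target == 0) return(0)
  draws <- withr::with_seed(as.integer(seed), {
    out <- sim_outcomes(config, superpop_n)
    list(time = out$time, uc = runif(superpop_n))
  })
  prop_at <- function(lambda) mean(-log(draws$uc) / lambda < draws$time)
  lo <- bracket[1]
  hi <- bracket[2]
  if (prop_at(lo) > target || prop_at(hi) < target) {
    stop_crcalib("Bracket does not contain the target censored proportion.",
                 "crcalib_error_bracket")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    pm <- prop_at(mid)
    if (abs(pm - target) <= tol) return(mid)
    if (pm < target) lo <- mid else hi <- mid
  }
  stop_crcalib("Bisection failed to reach the requested tolerance.",
               "crcalib_error_bracket")
}

#' Percentiles of event or observed time in a super-population
#'
#' Returns the 10th, 25th, 50th, 75th and 90th percentiles of event time
#' (without censoring) or of observed time `min(T, C)` (when the
#' configuration censors), computed on a seeded super-population. These are
#' the horizons at which calibration is assessed in the simulation studies.
#'
#' @param config A [dgp_config()] object.
#' @param superpop_n Super-population size (default 1,000,000).
#' @param seed Seed for the super-population draw.
#' @return Named numeric vector `c(t10, t25, t50, t75, t90)`, strictly
#'   increasing.
#' @export
evaluation_times <- function(config, superpop_n = 1000000L,
                             seed = config$seed %||% 1L) {
  rate <- config$censor_rate
  if (config$censor_proportion > 0 && is.null(rate)) {
    rate <- calibrate_censoring_rate(config)
  }
  times <- withr::with_seed(as.integer(seed), {
    out <- sim_outcomes(config, superpop_n)
    if (config$censor_proportion > 0) {
      pmin(out$time, rexp(superpop_n, rate = rate))
    } else {
      out$time
    }
  })
  stats::setNames(quantile7(times, c(0.10, 0.25, 0.50, 0.75, 0.90)),
                  c("t10", "t25", "t50", "t75", "t90"))
}
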