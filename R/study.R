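#' Default scenario grid for a Monte Carlo study design
#'
#' Six study designs are supported, each a factor grid over the
#' data-generating process of [dgp_config()]:
#' * `knot_selection`: p in \{0.25, 0.5, 0.75\}, N = 1000, beta1 = 1,
#'   beta2 = 0.25, no censoring; every replicate is assessed with 3, 4 and
#'   5 spline knots.
#' * `censoring`: censored proportion in \{0, 0.2, 0.4, 0.6\} crossed with
#'   p in \{0.25, 0.5, 0.75\}, N = 2000, 3 knots.
#' * `correct_no_censoring`: N in \{500, 1000, 2000\} x beta1 in
#'   \{0.25, 0.5, 1\} x p in \{0.25, 0.5, 0.75\} (27 cells).
#' * `quadratic`: the same 27 cells, but event times follow a quadratic
#'   primary-event linear predictor while the fitted model keeps only the
#'   linear term.
#' * `omitted_main_effect`: rho in \{0, 0.25, 0.5, 0.75\} x beta2 in
#'   \{0.25, 0.5, 1\} (12 cells), N = 1000, p = 0.5, two correlated
#'   covariates; the fitted model omits the second covariate.
#' * `validation_shift`: p_validation in \{0.3, 0.4, 0.5, 0.6, 0.7\},
#'   N = 1000, beta1 = 0.5, p = 0.5; the model is fit on a derivation
#'   sample and assessed on a validation sample with shifted incidence.
#'
#' @param study_name One of the six design names.
#' @return A tibble with one row per scenario cell.
#' @export
study_grid <- function(study_name = c("knot_selection", "censoring",
                                      "correct_no_censoring", "quadratic",
                                      "omitted_main_effect",
                                      "validation_shift")) {
  study_name <- match.arg(study_name)
  g <- switch(
    study_name,
    knot_selection = tidyr::expand_grid(p = c(0.25, 0.50, 0.75)) |>
      dplyr::mutate(sample_n = 1000L, beta1 = 1, beta2 = 0.25,
                    censor_proportion = 0),
    censoring = tidyr::expand_grid(p = c(0.25, 0.50, 0.75),
                                   censor_proportion = c(0, 0.20, 0.40, 0.60)) |>
      dplyr::mutate(sample_n = 2000L, beta1 = 1, beta2 = 0.25),
    correct_no_censoring = tidyr::expand_grid(sample_n = c(500L, 1000L, 2000L),
                                              beta1 = c(0.25, 0.50, 1),
                                              p = c(0.25, 0.50, 0.75)) |>
      dplyr::mutate(beta2 = 0.25, censor_proportion = 0),
    quadratic = tidyr::expand_grid(sample_n = c(500L, 1000L, 2000L),
                                   beta1 = c(0.25, 0.50, 1),
                                   p = c(0.25, 0.50, 0.75)) |>
      dplyr::mutate(beta2 = 0.25, censor_proportion = 0, quadratic = TRUE),
    omitted_main_effect = tidyr::expand_grid(rho = c(0, 0.25, 0.50, 0.75),
                                             beta2_second = c(0.25, 0.50, 1)) |>
      dplyr::mutate(sample_n = 1000L, p = 0.50, beta1 = NA_real_,
                    beta2 = NA_real_, censor_proportion = 0),
    validation_shift = tidyr::expand_grid(
      p_validation = c(0.3, 0.4, 0.5, 0.6, 0.7)) |>
      dplyr::mutate(sample_n = 1000L, p = 0.50, beta1 = 0.50, beta2 = 0.25,
                    censor_proportion = 0))
  dplyr::mutate(g, study_name = study_name, .before = 1)
}

#' Specify a Monte Carlo calibration study
#'
#' @param study_name One of the six designs listed in [study_grid()].
#' @param replicates Number of Monte Carlo replicates per scenario cell
#'   (default 100, a desk-scale reduction of the full 1000).
#' @param master_seed Integer master seed; per-scenario and per-replicate
#'   seeds are derived from it by a fixed counter scheme so every scenario
#'   is independently reproducible.
#' @param superpop_n Super-population size used for evaluation-time
#'   percentiles and censoring-rate calibration (default 100,000; the
#'   full-scale value is 1,000,000).
#' @param grid Scenario grid; defaults to `study_grid(study_name)`. Supply a
#'   filtered grid to run a subset of cells.
#' @param knot_values Spline knot counts evaluated per replicate; defaults
#'   to `c(3, 4, 5)` for the knot-selection study and 3 otherwise.
#' @param grid_size Display-grid resolution for curves.
#' @param time_labels Optional subset of `c("t10", "t25", "t50", "t75",
#'   "t90")`; calibration is assessed only at these horizons.
#' @return A list of class `study_spec`.
#' @export
study_spec <- function(study_name, replicates = 100L, master_seed = 1L,
                       superpop_n = 100000L, grid = NULL,
                       knot_values = NULL, grid_size = 100L,
                       time_labels = NULL) {
  grid <- grid %||% study_grid(study_name)
  knot_values <- knot_values %||%
    if (study_name == "knot_selection") c(3L, 4L, 5L) else 3L
  structure(list(study_name = study_name,
                 replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed),
                 superpop_n = as.integer(superpop_n),
                 grid = grid, knot_values = as.integer(knot_values),
                 grid_size = as.integer(grid_size),
                 time_labels = time_labels),
            class = "study_spec")
}

# build the data-generating config for one scenario row
scenario_config <- function(scen, n = scen$sample_n, p_validation = NULL) {
  if (identical(scen$study_name, "omitted_main_effect")) {
    dgp_config(n = n, p = scen$p, censor_proportion = 0,
               two_covariate = list(rho = scen$rho, beta2 = scen$beta2_second))
  } else {
    dgp_config(n = n, p = scen$p, beta1 = scen$beta1, beta2 = scen$beta2,
               censor_proportion = scen$censor_proportion %||% 0,
               quadratic = isTRUE(scen$quadratic),
               p_validation = p_validation,
               censor_rate = scen$censor_rate)
  }
}

# covariates entering the fitted (possibly deliberately mis-specified) model
scenario_model_covariates <- function(scen) {
  if (identical(scen$study_name, "omitted_main_effect")) "x1" else "x"
}

#' Run one Monte Carlo replicate of a scenario
#'
#' Draws a sample from the scenario's data-generating process, fits the
#' scenario's Fine-Gray model (deliberately mis-specified in the quadratic
#' and omitted-main-effect designs; for the validation-shift design the
#' model is fit on a derivation sample and assessed on a separately drawn
#' validation sample), and assesses calibration at each supplied horizon.
#' Secondary-model failures are recorded, not fatal.
#'
#' @param scen One scenario row (a one-row data frame or named list) from a
#'   [study_grid()], with `censor_rate` resolved if censoring is present.
#' @param times Named vector of evaluation horizons from
#'   [evaluation_times()].
#' @param seed Integer replicate seed.
#' @param knot_values Spline knot counts to assess.
#' @param grid_size Display-grid resolution.
#' @return A list with `metrics` (one row per horizon x knot count) and
#'   `curves` (display grids, stacked).
#' @export
run_replicate <- function(scen, times, seed, knot_values = 3L,
                          grid_size = 100L) {
  scen <- as.list(scen)
  seeds <- derive_seeds(seed, 2L)
  fit_config <- scenario_config(scen)
  fit_data <- generate_cr(fit_config, seed = seeds[1])

  if (identical(scen$study_name, "validation_shift")) {
    val_config <- scenario_config(scen, p_validation = scen$p_validation)
    val_data <- generate_cr(val_config, seed = seeds[2])
  } else {
    val_data <- fit_data
  }

  covs <- scenario_model_covariates(scen)
  fit <- withCallingHandlers(
    fine_gray(fit_data, covs),
    crcalib_warning_nonconvergence = function(w) invokeRestart("muffleWarning"))
  expansion <- fg_expand(val_data)

  res <- list()
  for (i in seq_along(times)) {
    tl <- names(times)[i]
    t0 <- times[[i]]
    pred <- predict(fit, val_data, t0)
    for (k in knot_values) {
      cal <- tryCatch(
        calibration_curve(val_data, pred, t0, n_knots = k,
                          grid_size = grid_size, expansion = expansion),
        crcalib_error = function(e) NULL)
      res[[length(res) + 1]] <- if (is.null(cal)) {
        list(metrics = tibble(time_label = tl, time = t0, n_knots = k,
                              ici = NA_real_, e50 = NA_real_, e90 = NA_real_,
                              emax = NA_real_, failed = TRUE),
             curve = NULL, params = NULL)
      } else {
        list(metrics = dplyr::bind_cols(
               tibble(time_label = tl, time = t0, n_knots = k),
               cal$metrics, tibble(failed = FALSE)),
             curve = dplyr::mutate(cal$curve, time_label = tl, n_knots = k,
                                   .before = 1),
             # compact secondary-model description so the curve can later be
             # evaluated exactly on a scenario-wide common grid
             params = tibble(time_label = tl, n_knots = k,
                             lo = min(cal$curve$predicted),
                             hi = max(cal$curve$predicted),
                             lam0 = eval_step(cal$fit$baseline, t0),
                             knots = list(cal$knots),
                             coef = list(unname(cal$fit$coefficients))))
      }
    }
  }
  list(metrics = purrr::map_dfr(res, "metrics"),
       curves = purrr::map_dfr(res, "curve"),
       params = purrr::map_dfr(res, "params"),
       primary_converged = fit$converged)
}

#' Run a Monte Carlo calibration study
#'
#' Evaluates every cell of the study's scenario grid: resolves the censoring
#' rate and evaluation-time percentiles on a seeded super-population, runs
#' the replicates, and aggregates per-horizon metrics (mean and SD of ICI,
#' E50, E90 across replicates) and mean calibration curves with 2.5th/97.5th
#' percentile bands. All replicate curves of a scenario are evaluated on one
#' common prediction grid (spanning the union of the per-replicate display
#' ranges, clipped to \[0, 1\]) before averaging. Replicates whose secondary
#' calibration model fails are excluded from averages but counted.
#'
#' @param spec A [study_spec()].
#' @param out_dir Optional directory; when given, per-scenario metric and
#'   curve CSVs plus a JSON run manifest are written there.
#' @return A list of class `cr_study`: one element per scenario with the
#'   scenario description, evaluation times, per-replicate metrics, metric
#'   summaries and aggregated curves.
#' @export
run_study <- function(spec, out_dir = NULL) {
  grid <- spec$grid
  n_scen <- nrow(grid)
  scen_seeds <- derive_seeds(spec$master_seed, n_scen)
  results <- vector("list", n_scen)

  for (s in seq_len(n_scen)) {
    scen <- as.list(grid[s, ])
    if ((scen$censor_proportion %||% 0) > 0 && is.null(scen$censor_rate)) {
      scen$censor_rate <- calibrate_censoring_rate(
        scenario_config(scen, n = 1L), target = scen$censor_proportion,
        superpop_n = spec$superpop_n)
    }
    sp_config <- scenario_config(scen, n = 1L)
    times <- evaluation_times(sp_config, superpop_n = spec$superpop_n,
                              seed = scen_seeds[s])
    if (!is.null(spec$time_labels)) times <- times[spec$time_labels]
    rep_seeds <- derive_seeds(scen_seeds[s], spec$replicates)
    reps <- vector("list", spec$replicates)
    for (r in seq_len(spec$replicates)) {
      reps[[r]] <- run_replicate(scen, times, rep_seeds[r],
                                 knot_values = spec$knot_values,
                                 grid_size = spec$grid_size)
    }
    metrics <- purrr::imap_dfr(reps, function(x, i) {
      dplyr::mutate(x$metrics, replicate = i, .before = 1)
    })
    summary <- summarize_replicate_metrics(metrics, spec$replicates)
    curves <- aggregate_curves(reps, spec$grid_size)
    results[[s]] <- list(scenario = grid[s, ], times = times,
                         metrics = metrics, summary = summary,
                         curves = curves,
                         n_failed = sum(metrics$failed))
  }
  out <- structure(results, class = "cr_study",
                   spec = spec)
  if (!is.null(out_dir)) write_study_results(out, out_dir)
  out
}

summarize_replicate_metrics <- function(metrics, replicates) {
  ok <- dplyr::filter(metrics, !.data$failed)
  sm <- ok |>
    dplyr::group_by(.data$time_label, .data$time, .data$n_knots) |>
    dplyr::summarise(dplyr::across(c("ici", "e50", "e90", "emax"),
                                   list(mean = mean,
                                        sd = function(v) {
                                          if (length(v) > 1) stats::sd(v)
                                          else NA_real_
                                        })),
                     n_ok = dplyr::n(), .groups = "drop")
  dplyr::mutate(sm, n_failed = replicates - .data$n_ok)
}

# Evaluate every replicate's secondary calibration model exactly on one
# common grid per (horizon, knot count) and average pointwise. The common
# grid spans the union of the per-replicate display ranges (1st-99th
# percentile of predicted risk), clipped to [0, 1]; each replicate's spline
# is evaluated analytically on that grid, so no interpolation is involved.
aggregate_curves <- function(reps, grid_size) {
  all_params <- purrr::imap_dfr(reps, function(x, i) {
    if (is.null(x$params) || nrow(x$params) == 0) return(NULL)
    dplyr::mutate(x$params, replicate = i)
  })
  if (is.null(all_params) || nrow(all_params) == 0) return(tibble())
  all_params |>
    dplyr::group_by(.data$time_label, .data$n_knots) |>
    dplyr::group_modify(function(df, key) {
      lo <- max(min(df$lo), 0)
      hi <- min(max(df$hi), 1)
      grid <- seq(lo, hi, length.out = grid_size)
      cll <- cloglog(grid)
      mat <- do.call(rbind, purrr::map(seq_len(nrow(df)), function(r) {
        basis <- rcs_design(cll, df$knots[[r]])
        lp <- drop(basis %*% df$coef[[r]])
        -expm1(-df$lam0[r] * exp(lp))
      }))
      tibble(predicted = grid,
             mean = colMeans(mat),
             lower = apply(mat, 2, quantile7, probs = 0.025),
             upper = apply(mat, 2, quantile7, probs = 0.975),
             n_curves = nrow(mat))
    }) |>
    dplyr::ungroup()
}

#' Tidy summary tables of a Monte Carlo study
#'
#' @param results A `cr_study` object from [run_study()].
#' @return A list with two tidy tibbles: `metrics` (per scenario x horizon x
#'   knot count: mean and SD of each metric, counts of usable and failed
#'   replicates) and `curves` (mean curve with percentile bands).
#' @export
summarize_study <- function(results) {
  scen_cols <- function(res) {
    keep <- setdiff(names(res$scenario),
                    c("censor_rate"))
    res$scenario[, keep]
  }
  metrics <- purrr::map_dfr(results, function(res) {
    dplyr::bind_cols(scen_cols(res)[rep(1, nrow(res$summary)), ],
                     res$summary)
  })
  curves <- purrr::map_dfr(results, function(res) {
    if (nrow(res$curves) == 0) return(NULL)
    dplyr::bind_cols(scen_cols(res)[rep(1, nrow(res$curves)), ],
                     res$curves)
  })
  list(metrics = metrics, curves = curves)
}

#' Write study results to CSV files plus a manifest
#'
#' @param results A `cr_study` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- attr(results, "spec")
  summ <- summarize_study(results)
  utils::write.csv(summ$metrics, file.path(dir, "metrics_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(summ$curves, file.path(dir, "curves_summary.csv"),
                   row.names = FALSE)
  manifest <- list(study_name = spec$study_name,
                   replicates = spec$replicates,
                   master_seed = spec$master_seed,
                   superpop_n = spec$superpop_n,
                   knot_values = spec$knot_values,
                   n_scenarios = nrow(spec$grid),
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("crcalib")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
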