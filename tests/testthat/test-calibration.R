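test_that("cloglog matches its closed form and clips the boundary", {
  expect_equal(cloglog(1 - exp(-1)), 0)
  expect_equal(cloglog(0.5), log(log(2)))
  expect_equal(cloglog(0), log(-log1p(-1e-10)))
  expect_true(is.finite(cloglog(1)))
  expect_error(cloglog(c(0.2, 1.3)), class = "crcalib_error_argument")
})

test_that("the metrics reproduce the worked four-pair example exactly", {
  m <- calibration_metrics(c(0.10, 0.20, 0.30, 0.40),
                           c(0.12, 0.18, 0.36, 0.38))
  expect_equal(m$ici, 0.03)
  expect_equal(m$e50, 0.02)
  expect_equal(m$e90, 0.048)
  expect_equal(m$emax, 0.06)
})

test_that("metric identities and orderings hold", {
  p <- runif(100)
  m0 <- calibration_metrics(p, p)
  expect_equal(unlist(m0), c(ici = 0, e50 = 0, e90 = 0, emax = 0))

  set.seed(149)
  for (i in 1:10) {
    pred <- runif(50, 0.05, 0.6)
    obs <- pmin(pmax(pred + rnorm(50, 0, 0.05), 0), 1)
    m <- calibration_metrics(pred, obs)
    expect_lte(m$e50, m$e90)
    expect_lte(m$e90, m$emax)
    expect_lte(m$ici, m$emax)
  }

  # translating one-signed differences shifts ICI by the same constant
  pred <- c(0.1, 0.2, 0.3)
  obs <- pred + c(0.01, 0.02, 0.03)
  m1 <- calibration_metrics(pred, obs)
  m2 <- calibration_metrics(pred, obs + 0.05)
  expect_equal(m2$ici - m1$ici, 0.05)

  expect_error(calibration_metrics(c(0.1, 0.2), 0.1),
               class = "crcalib_error_argument")
})

test_that("constant predictions raise a knot-degeneracy error", {
  d <- generate_cr(dgp_config(n = 100, p = 0.5, beta1 = 1), seed = 151)
  expect_error(calibration_curve(d, rep(0.3, 100), t0 = 0.5),
               class = "crcalib_error_knot_degeneracy")
})

test_that("three knots give a two-column secondary model", {
  d <- generate_cr(dgp_config(n = 500, p = 0.5, beta1 = 1), seed = 157)
  pred <- true_cif(d$x, 0.6, 0.5, 1)
  cal <- calibration_curve(d, pred, t0 = 0.6, n_knots = 3)
  expect_length(cal$fit$covariate_names, 2)
  cal4 <- calibration_curve(d, pred, t0 = 0.6, n_knots = 4)
  expect_length(cal4$fit$covariate_names, 3)
  expect_equal(nrow(cal$curve), 100)
  expect_true(all(cal$observed >= 0 & cal$observed <= 1))
})

test_that("self-consistent predictions on a large sample give a near-diagonal curve", {
  d <- generate_cr(dgp_config(n = 10000, p = 0.5, beta1 = 1, beta2 = 0.25),
                   seed = 163)
  fit <- fine_gray(d, "x")
  t50 <- quantile(d$time, 0.5, type = 7)
  pred <- predict(fit, d, t50)
  cal <- calibration_curve(d, pred, t50)
  expect_lt(max(abs(cal$curve$observed - cal$curve$predicted)), 0.02)
  expect_lt(cal$metrics$ici, 0.02)
})

test_that("subject reordering changes nothing", {
  d <- generate_cr(dgp_config(n = 400, p = 0.5, beta1 = 1), seed = 167)
  pred <- true_cif(d$x, 0.6, 0.5, 1)
  cal1 <- calibration_curve(d, pred, t0 = 0.6)
  perm <- sample(400)
  d2 <- d[perm, ]
  cal2 <- calibration_curve(d2, pred[perm], t0 = 0.6)
  expect_equal(cal2$metrics, cal1$metrics, tolerance = 1e-10)
  expect_equal(cal2$curve$observed, cal1$curve$observed, tolerance = 1e-10)
})

test_that("administrative censoring at the horizon recodes later follow-up", {
  d <- generate_cr(dgp_config(n = 600, p = 0.5, beta1 = 1), seed = 173)
  pred <- true_cif(d$x, 0.5, 0.5, 1)
  cal <- calibration_curve(d, pred, t0 = 0.5,
                           administrative_censor_at_t0 = TRUE)
  # identical to recoding by hand before the call
  d2 <- as.data.frame(d)
  d2$status[d2$time > 0.5] <- 0L
  d2$time[d2$time > 0.5] <- 0.5
  cal2 <- calibration_curve(cr_data(d2), pred, t0 = 0.5)
  expect_equal(cal$metrics, cal2$metrics, tolerance = 1e-12)
  # and still close to the diagonal for correct predictions
  expect_lt(cal$metrics$ici, 0.05)
})

test_that("a single large mis-specified fit is visibly worse calibrated than the correct one", {
  d <- generate_cr(dgp_config(n = 20000, p = 0.5, beta1 = 1,
                              quadratic = TRUE), seed = 179)
  t50 <- quantile(d$time, 0.5, type = 7)
  fit_lin <- fine_gray(d, "x")          # omits the quadratic term
  d_ok <- as.data.frame(d)
  d_ok$x2 <- d_ok$x^2
  fit_ok <- fine_gray(cr_data(d_ok), c("x", "x2"))
  cal_lin <- calibration_curve(d, predict(fit_lin, d, t50), t50)
  cal_ok <- calibration_curve(d, predict(fit_ok, d_ok, t50), t50)
  expect_gt(cal_lin$metrics$ici, cal_ok$metrics$ici)
  expect_gt(cal_lin$metrics$ici, 0.01)
  expect_lt(cal_ok$metrics$ici, 0.01)
})

test_that("binned calibration balances counts, respects ties and tracks truth", {
  d <- generate_cr(dgp_config(n = 1000, p = 0.5, beta1 = 1), seed = 181)
  pred <- true_cif(d$x, 0.6, 0.5, 1)
  b <- binned_calibration(d, pred, t0 = 0.6, n_bins = 10)
  expect_equal(nrow(b), 10)
  expect_lte(diff(range(b$n)), 1)
  expect_equal(sum(b$n), 1000)

  # tied predictions are never split across bins
  pred_tied <- round(pred, 1)
  bt <- binned_calibration(d, pred_tied, t0 = 0.6, n_bins = 5)
  expect_equal(sum(bt$n), 1000)
  grp <- cut(pred_tied,
             unique(quantile(pred_tied, seq(0, 1, length.out = 6), type = 7)),
             include.lowest = TRUE, labels = FALSE)
  expect_true(all(tapply(grp, pred_tied, function(g) length(unique(g))) == 1))

  # large correctly specified sample: central bins near the diagonal
  d2 <- generate_cr(dgp_config(n = 20000, p = 0.5, beta1 = 1), seed = 191)
  pred2 <- true_cif(d2$x, 0.6, 0.5, 1)
  b2 <- binned_calibration(d2, pred2, t0 = 0.6, n_bins = 10)
  central <- b2[b2$bin %in% 3:8, ]
  expect_lt(max(abs(central$observed - central$mean_predicted)), 0.03)

  expect_error(binned_calibration(d, rep(0.3, 1000), t0 = 0.6, n_bins = 10),
               class = "crcalib_error_bin_degeneracy")
})

test_that("a correct model stays well calibrated under 20% censoring", {
  res <- cached("censoring20_t50", function() {
    g <- subset(study_grid("censoring"), p == 0.5 & censor_proportion == 0.2)
    run_cells("censoring", g, time_labels = "t50")
  })
  s <- res[[1]]$summary
  expect_equal(s$n_failed, 0L)
  expect_lte(s$ici_mean, 0.02)
  cv <- res[[1]]$curves
  expect_lt(max(abs(cv$mean - cv$predicted)), 0.02)
})

test_that("glance and tidy expose the curve and the metrics", {
  d <- generate_cr(dgp_config(n = 300, p = 0.5, beta1 = 1), seed = 193)
  pred <- true_cif(d$x, 0.6, 0.5, 1)
  cal <- calibration_curve(d, risk_predictions(pred, 0.6))
  expect_equal(cal$t0, 0.6)
  gl <- glance(cal)
  expect_true(all(c("t0", "n", "n_knots", "ici", "e50", "e90", "emax")
                  %in% names(gl)))
  td <- tidy(cal)
  expect_named(td, c("predicted", "observed"))
})
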