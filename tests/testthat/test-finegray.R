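test_that("without competing events or censoring the expansion is the identity", {
  d <- cr_data(data.frame(id = 1:6, time = c(3, 1, 4, 2, 6, 5), status = 1L))
  rows <- fg_expand(d)
  expect_equal(nrow(rows), 6)
  expect_equal(rows$weight, rep(1, 6))
  expect_equal(rows$start, rep(0, 6))
  expect_equal(rows$stop, d$time[match(rows$id, d$id)])
  expect_equal(rows$event, rep(1L, 6))
})

test_that("the worked censored expansion gives the competing subject weight one half", {
  rows <- fg_expand(mixed_record_data())
  comp <- rows[rows$id == 2, ]
  # intervals (0,2], (2,3], (3,4]; event time 4 is covered with weight
  # G(4-)/G(2-) = 0.5
  expect_equal(comp$start, c(0, 2, 3))
  expect_equal(comp$stop, c(2, 3, 4))
  expect_equal(comp$weight, c(1, 1, 0.5))
  expect_equal(comp$event, c(0L, 0L, 0L))
  # censored and primary-event subjects keep a single weight-1 row
  expect_equal(nrow(rows[rows$id == 3, ]), 1)
  expect_equal(nrow(rows[rows$id == 4, ]), 1)
})

test_that("weights are non-increasing within subject on simulated censored data", {
  cfg <- dgp_config(n = 400, p = 0.5, beta1 = 1, beta2 = 0.25,
                    censor_proportion = 0.4, censor_rate = 0.6)
  d <- generate_cr(cfg, seed = 53)
  rows <- fg_expand(d)
  bad <- tapply(rows$weight, rows$id, function(w) any(diff(w) > 1e-12))
  expect_false(any(bad))
  # intervals are contiguous per subject
  gaps <- tapply(seq_len(nrow(rows)), rows$id, function(i) {
    r <- rows[i, ]
    if (nrow(r) < 2) return(0)
    max(abs(head(r$stop, -1) - tail(r$start, -1)))
  })
  expect_lt(max(unlist(gaps)), 1e-12)
})

test_that("degenerate external censoring survival functions are caught", {
  d <- cr_data(data.frame(id = 1:3, time = c(1, 2, 3), status = c(1, 2, 1)))
  # a malformed G that is zero everywhere leaves the competing subject's
  # weight undefined
  G0 <- step_function(numeric(0), numeric(0), initial_value = 0)
  expect_error(fg_expand(d, G = G0),
               class = "crcalib_error_degenerate_weight")
  # whereas a G that merely reaches zero stops the risk-set extension there
  G1 <- step_function(0.5, 0, initial_value = 1)
  rows <- fg_expand(d, G = G1)
  expect_equal(nrow(rows[rows$id == 2, ]), 1)
})

test_that("with no competing events the fit reduces to a plain Cox model", {
  skip_if_not_installed("survival")
  for (seed in c(61, 62)) {
    set.seed(seed)
    n <- 300
    x <- rnorm(n)
    tt <- rexp(n, exp(0.7 * x))
    cens <- rexp(n, 0.3)
    d <- cr_data(data.frame(id = 1:n, time = pmin(tt, cens),
                            status = as.integer(tt <= cens), x = x))
    fit <- fine_gray(d, "x")
    cox <- survival::coxph(survival::Surv(time, status == 1) ~ x, data = d,
                           ties = "breslow")
    expect_lt(abs(fit$coefficients - coef(cox)), 1e-6)
    expect_true(fit$converged)
  }
})

test_that("the four-subject fit matches brute-force partial-likelihood maximization", {
  d <- cr_data(data.frame(id = 1:4, time = c(1, 2, 3, 4), status = 1L,
                          x = c(1, 0, 1, 0)))
  fit <- fine_gray(d, "x")
  # explicit 4-term partial likelihood over the nested risk sets
  pl <- function(b) {
    r <- exp(d$x * b)
    log(r[1] / sum(r)) + log(r[2] / sum(r[2:4])) +
      log(r[3] / sum(r[3:4])) + log(r[4] / r[4])
  }
  grid <- seq(-5, 5, by = 1e-4)
  b_grid <- grid[which.max(vapply(grid, pl, numeric(1)))]
  expect_lt(abs(fit$coefficients - b_grid), 1e-4)
  expect_equal(fit$log_partial_likelihood, pl(fit$coefficients),
               tolerance = 1e-10)
})

test_that("negating the covariate negates the coefficient", {
  cfg <- dgp_config(n = 300, p = 0.5, beta1 = 1, beta2 = 0.25)
  d <- generate_cr(cfg, seed = 67)
  f1 <- fine_gray(d, "x")
  d$x <- -d$x
  f2 <- fine_gray(d, "x")
  expect_equal(unname(f1$coefficients), -unname(f2$coefficients),
               tolerance = 1e-8)
})

test_that("without censoring the fit equals a Cox fit with competing subjects retained forever", {
  skip_if_not_installed("survival")
  cfg <- dgp_config(n = 500, p = 0.5, beta1 = 1, beta2 = 0.25)
  d <- generate_cr(cfg, seed = 71)
  fit <- fine_gray(d, "x")
  # administratively censor competing-event subjects beyond the last event
  d2 <- as.data.frame(d)
  horizon <- max(d$time) + 1
  d2$time[d2$status == 2] <- horizon
  cox <- survival::coxph(survival::Surv(time, status == 1) ~ x, data = d2,
                         ties = "breslow")
  expect_lt(abs(fit$coefficients - coef(cox)), 1e-6)
})

test_that("with censoring the fit matches the weighted expansion route of the survival package", {
  skip_if_not_installed("survival")
  cfg <- dgp_config(n = 800, p = 0.5, beta1 = 1, beta2 = 0.25,
                    censor_proportion = 0.3, censor_rate = 0.4)
  d <- generate_cr(cfg, seed = 73)
  fit <- fine_gray(d, "x")
  fgd <- survival::finegray(
    survival::Surv(time, factor(status, 0:2, c("cens", "ev1", "ev2"))) ~ x,
    data = d, etype = "ev1")
  cox <- survival::coxph(
    survival::Surv(fgstart, fgstop, fgstatus) ~ x, weights = fgwt,
    data = fgd, ties = "breslow")
  expect_lt(abs(fit$coefficients - coef(cox)), 1e-8)
})

test_that("the fit agrees with the original estimating-equation implementation", {
  skip_if_not_installed("cmprsk")
  cfg <- dgp_config(n = 600, p = 0.5, beta1 = 1, beta2 = 0.25,
                    censor_proportion = 0.3, censor_rate = 0.4)
  for (s in c(73, 301)) {
    d <- generate_cr(cfg, seed = s)
    fit <- fine_gray(d, "x")
    cr <- cmprsk::crr(d$time, d$status, cov1 = matrix(d$x),
                      failcode = 1, cencode = 0)
    expect_lt(abs(unname(fit$coefficients) - unname(cr$coef)), 1e-4)
  }
})

test_that("the accepted Newton path never decreases the partial likelihood", {
  cfg <- dgp_config(n = 400, p = 0.5, beta1 = 1, beta2 = 0.25,
                    censor_proportion = 0.3, censor_rate = 0.4)
  d <- generate_cr(cfg, seed = 79)
  lls <- vapply(1:5, function(k) {
    quiet_fine_gray(d, "x", max_iter = k)$log_partial_likelihood
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-10))
})

test_that("predicted incidence is zero before the first event and monotone in the horizon", {
  cfg <- dgp_config(n = 300, p = 0.5, beta1 = 1, beta2 = 0.25)
  d <- generate_cr(cfg, seed = 83)
  fit <- fine_gray(d, "x")
  t_first <- min(d$time[d$status == 1])
  expect_equal(predict(fit, d[1:5, ], t_first * 0.5), rep(0, 5))
  horizons <- seq(0.05, max(d$time), length.out = 25)
  for (row in c(1, 7)) {
    path <- vapply(horizons, function(t0) predict(fit, d[row, ], t0),
                   numeric(1))
    expect_true(all(diff(path) >= 0))
    expect_true(all(path >= 0 & path <= 1))
  }
})

test_that("large-sample predicted incidence at covariate zero matches the closed form", {
  cfg <- dgp_config(n = 20000, p = 0.5, beta1 = 1, beta2 = 0.25)
  d <- generate_cr(cfg, seed = 89)
  fit <- fine_gray(d, "x")
  t50 <- quantile(d$time, 0.5, type = 7)
  expect_lt(abs(predict(fit, data.frame(x = 0), t50) -
                  true_cif(0, t50, 0.5, 1)), 0.02)
  # at the largest event time the prediction at x = 0 approaches p
  t_max <- max(d$time[d$status == 1])
  expect_lt(abs(predict(fit, data.frame(x = 0), t_max) - 0.5), 0.02)
})

test_that("a fit round-trips through its JSON serialization", {
  cfg <- dgp_config(n = 200, p = 0.5, beta1 = 1, beta2 = 0.25)
  d <- generate_cr(cfg, seed = 97)
  fit <- fine_gray(d, "x")
  path <- withr::local_tempfile(fileext = ".json")
  write_fine_gray(fit, path)
  fit2 <- read_fine_gray(path)
  expect_equal(fit2$coefficients, fit$coefficients)
  expect_equal(fit2$baseline$jump_times, fit$baseline$jump_times)
  expect_equal(fit2$baseline$values, fit$baseline$values)
  expect_equal(fit2$converged, fit$converged)
  expect_equal(predict(fit2, d[1:10, ], 1), predict(fit, d[1:10, ], 1))
})

test_that("tidy and glance return the broom-style summaries", {
  cfg <- dgp_config(n = 200, p = 0.5, beta1 = 1, beta2 = 0.25)
  d <- generate_cr(cfg, seed = 101)
  fit <- fine_gray(d, "x")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$term, "x")
  gl <- glance(fit)
  expect_true(all(c("n", "n_events", "log_partial_likelihood",
                    "converged") %in% names(gl)))
  expect_equal(gl$n, 200)
})
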