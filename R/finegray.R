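#' Weighted counting-process expansion for the Fine-Gray model
#'
#' Realises the Fine-Gray risk set by data expansion with
#' inverse-probability-of-censoring weights (the construction of Geskus, as
#' implemented by `mstate::crprep`). Subjects who are censored or experience
#' the primary event contribute a single interval `(0, T_i]` with weight 1.
#' Subjects with a competing event remain in the risk set after their event:
#' they contribute `(0, T_i]` with weight 1 and are then extended over
#' successive censoring-time segments up to the last primary-event time (or
#' the last time at which the censoring survival `G` is positive, whichever
#' comes first). On a segment starting at `a` the weight is
#' `G(a) / G(T_i-)`, which equals `G(s-) / G(T_i-)` for every primary-event
#' time `s` inside the segment, so the weighted partial likelihood is
#' identical to the per-event-time expansion.
#'
#' @param data A [cr_data] tibble.
#' @param G Censoring survival function; defaults to
#'   `km_survival(data, "censoring")`.
#' @return A tibble with columns `id`, `start`, `stop`, `event` (0/1 primary
#'   event at `stop`), `weight`. Intervals of a subject are disjoint and
#'   contiguous and the weight is non-increasing across them.
#' @export
fg_expand <- function(data, G = NULL) {
  if (is.null(G)) G <- km_survival(data, "censoring")
  tt <- data$time
  st <- data$status
  id <- data$id

  base <- tibble(id = id, start = 0, stop = tt,
                 event = as.integer(st == 1L), weight = 1)

  comp <- which(st == 2L)
  pt <- tt[st == 1L]
  if (length(comp) == 0 || length(pt) == 0) {
    return(base[order(match(base$id, id)), ])
  }
  last_pt <- max(pt)
  ct <- G$jump_times
  gv <- G$values
  zero_at <- if (any(gv <= 0)) ct[match(TRUE, gv <= 0)] else Inf
  t_stop <- min(last_pt, zero_at)

  ti <- tt[comp]
  ext <- which(ti < t_stop)
  if (length(ext) == 0) {
    return(base[order(match(base$id, id)), ])
  }
  ti_e <- ti[ext]
  g_ti_minus <- eval_step(G, ti_e, side = "left")
  if (any(g_ti_minus <= 0)) {
    bad <- id[comp[ext]][g_ti_minus <= 0]
    stop_crcalib(
      sprintf("Censoring survival G(T-) is zero for competing-event subject(s) %s; weights undefined.",
              paste(head(bad, 5L), collapse = ", ")),
      "crcalib_error_degenerate_weight")
  }

  # censoring times strictly inside (T_i, t_stop) split each extension
  lo <- findInterval(ti_e, ct)                       # censor times <= T_i
  hi <- findInterval(t_stop, ct, left.open = TRUE)   # censor times <  t_stop
  hi <- rep(hi, length(ti_e))
  nseg <- pmax(hi - lo, 0L) + 1L

  subj <- rep(seq_along(ti_e), nseg)
  pos <- sequence(nseg)
  seg_start <- ifelse(pos == 1L, ti_e[subj],
                      ct[pmax(lo[subj] + pos - 1L, 1L)])
  seg_stop <- ifelse(pos == nseg[subj], t_stop,
                     ct[pmin(lo[subj] + pos, length(ct))])
  seg_weight <- eval_step(G, seg_start, side = "right") / g_ti_minus[subj]

  keep <- seg_weight > 0
  ext_rows <- tibble(id = id[comp[ext]][subj][keep],
                     start = seg_start[keep], stop = seg_stop[keep],
                     event = 0L, weight = seg_weight[keep])
  out <- dplyr::bind_rows(base, ext_rows)
  out[order(match(out$id, id), out$start), ]
}

# Weighted Cox partial likelihood on counting-process rows, Breslow ties,
# Newton-Raphson with step-halving. Covariates are centred internally; the
# Breslow baseline is rescaled back to the original covariate scale.
fit_weighted_cox_engine <- function(start, stop, event, weight, X,
                                    max_iter = 50L, grad_tol = 1e-8,
                                    ll_tol = 1e-10, max_halving = 20L) {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- nrow(X)
  stopifnot(length(start) == n, length(stop) == n, length(event) == n,
            length(weight) == n)
  ev <- event == 1L & weight > 0
  if (!any(ev)) {
    stop_crcalib("No primary-event rows with positive weight; cannot fit.",
                 "crcalib_error_design")
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (qr(crossprod(Xc))$rank < p) {
    stop_crcalib("Covariate matrix is rank deficient.", "crcalib_error_design")
  }

  s_times <- sort(unique(stop[ev]))
  E <- length(s_times)
  grp <- match(stop[ev], s_times)
  dsum <- as.numeric(rowsum(weight[ev], grp))
  xev_sum <- rowsum(weight[ev] * Xc[ev, , drop = FALSE], grp)

  oA <- order(start)
  oB <- order(stop)
  idxA <- findInterval(s_times, start[oA], left.open = TRUE)
  idxB <- findInterval(s_times, stop[oB], left.open = TRUE)

  # packed second-moment column index pairs
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  npair <- nrow(pairs)
  m <- 1L + p + npair

  # iteration-invariant weighted moments, pre-sorted for the entering
  # (start < s) and leaving (stop < s) cumulative sums
  w_mom <- weight * cbind(1, Xc,
                          Xc[, pairs[, 1], drop = FALSE] *
                            Xc[, pairs[, 2], drop = FALSE])
  dimnames(w_mom) <- NULL
  momA <- w_mom[oA, , drop = FALSE]
  momB <- w_mom[oB, , drop = FALSE]

  risk_sums <- function(ee, cols) {
    # S_k(s) = sum over rows with start < s <= stop of w e^eta * moment_k
    SA <- matrix(0, E, length(cols))
    SB <- matrix(0, E, length(cols))
    posA <- idxA > 0L
    posB <- idxB > 0L
    for (j in seq_along(cols)) {
      ca <- cumsum(momA[, cols[j]] * ee[oA])
      cb <- cumsum(momB[, cols[j]] * ee[oB])
      SA[posA, j] <- ca[idxA[posA]]
      SB[posB, j] <- cb[idxB[posB]]
    }
    SA - SB
  }

  ll_at <- function(eta, ee) {
    S0 <- risk_sums(ee, 1L)[, 1]
    if (any(S0 <= 0)) return(NULL)
    list(ll = sum(weight[ev] * eta[ev]) - sum(dsum * log(S0)), S0 = S0)
  }

  deriv_at <- function(ee, S0) {
    S <- risk_sums(ee, 2:m)
    m1 <- S[, seq_len(p), drop = FALSE] / S0
    grad <- colSums(xev_sum) - colSums(dsum * m1)
    H <- matrix(0, p, p)
    S2n <- S[, p + seq_len(npair), drop = FALSE] / S0
    for (q in seq_len(npair)) {
      j <- pairs[q, 1]; l <- pairs[q, 2]
      v <- sum(dsum * (S2n[, q] - m1[, j] * m1[, l]))
      H[j, l] <- v
      H[l, j] <- v
    }
    list(grad = grad, hess = H)
  }

  beta <- rep(0, p)
  eta <- drop(Xc %*% beta)
  cur <- ll_at(eta, exp(eta))
  cur_deriv <- deriv_at(exp(eta), cur$S0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(cur_deriv$grad)) < grad_tol) {
      converged <- TRUE
      break
    }
    delta <- tryCatch(solve(cur_deriv$hess, cur_deriv$grad),
                      error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) break
    step <- 1
    nxt <- NULL
    for (h in 0:max_halving) {
      cand <- beta + step * delta
      cand_eta <- drop(Xc %*% cand)
      cand_ee <- exp(cand_eta)
      trial <- if (all(is.finite(cand_ee))) ll_at(cand_eta, cand_ee) else NULL
      if (!is.null(trial) && is.finite(trial$ll) &&
          trial$ll >= cur$ll - 1e-12) {
        nxt <- trial
        beta <- cand
        eta <- cand_eta
        break
      }
      step <- step / 2
    }
    if (is.null(nxt)) break
    rel_change <- abs(nxt$ll - cur$ll) / (abs(cur$ll) + 1)
    cur <- nxt
    cur_deriv <- deriv_at(exp(eta), cur$S0)
    if (max(abs(beta)) > 200) break  # monotone-likelihood divergence
    if (rel_change < ll_tol) {
      converged <- TRUE
      break
    }
  }
  if (max(abs(beta)) > 200) converged <- FALSE

  # Breslow baseline cumulative subdistribution hazard, original scale
  lam0 <- cumsum(dsum / cur$S0) * exp(-sum(mu * beta))
  baseline <- step_function(s_times, lam0, initial_value = 0)

  list(coefficients = beta, baseline = baseline, loglik = cur$ll,
       gradient = cur_deriv$grad, info_diag = diag(cur_deriv$hess),
       iterations = iter, converged = converged, center = mu)
}

#' Fit a Fine-Gray subdistribution hazard model
#'
#' Proportional-hazards regression on the subdistribution hazard of the
#' primary event. The model is fit by the weighted-data route: the risk set
#' is realised by [fg_expand()], and the weighted Cox partial likelihood
#' (Breslow tie handling) is maximised by Newton-Raphson with step-halving,
#' starting from zero coefficients. Convergence requires the gradient
#' max-norm to fall below `1e-8` or the relative log-likelihood change below
#' `1e-10` within 50 iterations; divergence of the coefficients flags the
#' fit as non-converged rather than failing silently. The Breslow baseline
#' cumulative subdistribution hazard jumps only at observed primary-event
#' times.
#'
#' @param data A [cr_data] tibble.
#' @param covariate_cols Covariate column names; default all covariates of
#'   `data`.
#' @param expansion Optional precomputed [fg_expand()] result for `data`
#'   (the expansion depends only on times and status, so it can be reused
#'   across fits with different covariates).
#' @param max_iter,grad_tol,ll_tol,max_halving Newton-Raphson controls.
#' @return An object of class `fine_gray` with elements `coefficients`
#'   (named), `baseline` (a [step_function()]), `log_partial_likelihood`,
#'   `iterations`, `converged`, `covariate_names`, `n`, `n_events`, and the
#'   observed-information diagonal `info_diag` (a convergence diagnostic
#'   only).
#' @examples
#' set.seed(1)
#' d <- generate_cr(dgp_config(n = 300, p = 0.5, beta1 = 1), seed = 1)
#' fit <- fine_gray(d, "x")
#' tidy(fit)
#' @export
fine_gray <- function(data, covariate_cols = NULL, expansion = NULL,
                      max_iter = 50L, grad_tol = 1e-8, ll_tol = 1e-10,
                      max_halving = 20L) {
  covariate_cols <- covariate_cols %||% attr(data, "covariates")
  if (is.null(covariate_cols) || length(covariate_cols) == 0) {
    stop_crcalib("At least one covariate column is required.",
                 "crcalib_error_argument")
  }
  if (!all(covariate_cols %in% names(data))) {
    stop_crcalib("Covariate column(s) not found in data.",
                 "crcalib_error_missing_column")
  }
  rows <- expansion %||% fg_expand(data)
  Xsub <- as.matrix(as.data.frame(data)[, covariate_cols, drop = FALSE])
  X <- Xsub[match(rows$id, data$id), , drop = FALSE]
  eng <- fit_weighted_cox_engine(rows$start, rows$stop, rows$event,
                                 rows$weight, X,
                                 max_iter = max_iter, grad_tol = grad_tol,
                                 ll_tol = ll_tol, max_halving = max_halving)
  if (!eng$converged) {
    warn("Fine-Gray fit did not converge; inspect $converged and $gradient.",
         class = "crcalib_warning_nonconvergence")
  }
  structure(list(coefficients = stats::setNames(eng$coefficients,
                                                covariate_cols),
                 baseline = eng$baseline,
                 log_partial_likelihood = eng$loglik,
                 gradient = eng$gradient,
                 info_diag = eng$info_diag,
                 iterations = eng$iterations,
                 converged = eng$converged,
                 covariate_names = covariate_cols,
                 n = nrow(data),
                 n_events = sum(data$status == 1L)),
            class = "fine_gray")
}

#' @export
print.fine_gray <- function(x, ...) {
  cat("Fine-Gray subdistribution hazard model (weighted partial likelihood)\n")
  cat(sprintf("  n = %d subjects, %d primary events\n", x$n, x$n_events))
  cat("  coefficients:\n")
  print(round(x$coefficients, 6))
  cat(sprintf("  log partial likelihood: %.4f (%d iterations%s)\n",
              x$log_partial_likelihood, x$iterations,
              if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' @rdname fine_gray
#' @param x,object A `fine_gray` fit.
#' @param ... Unused.
#' @method tidy fine_gray
#' @export
tidy.fine_gray <- function(x, ...) {
  tibble(term = x$covariate_names,
         estimate = unname(x$coefficients))
}

#' @rdname fine_gray
#' @method glance fine_gray
#' @export
glance.fine_gray <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events,
         log_partial_likelihood = x$log_partial_likelihood,
         iterations = x$iterations, converged = x$converged)
}

#' Predicted cumulative incidence from a Fine-Gray fit
#'
#' Computes \eqn{1 - \exp(-\Lambda_0(t_0) e^{X\beta})} per subject, the
#' model-based probability of the primary event occurring by `t0`.
#'
#' @param fit A [fine_gray()] object.
#' @param newdata Data frame (or matrix) containing the fit's covariate
#'   columns.
#' @param t0 Positive prediction horizon.
#' @return A [risk_predictions()] tibble (column `predicted`, horizon
#'   attribute `t0`).
#' @export
predict_cif <- function(fit, newdata, t0) {
  assert_scalar_number(t0, "t0", positive = TRUE)
  X <- as.matrix(as.data.frame(newdata)[, fit$covariate_names, drop = FALSE])
  lp <- drop(X %*% fit$coefficients)
  lam <- eval_step(fit$baseline, t0)
  risk <- if (lam == 0) rep(0, length(lp)) else -expm1(-lam * exp(lp))
  risk_predictions(pmin(pmax(risk, 0), 1), horizon = t0)
}

#' @export
predict.fine_gray <- function(object, newdata, t0, ...) {
  predict_cif(object, newdata, t0)$predicted
}

#' Serialize a Fine-Gray fit to JSON
#'
#' @param fit A [fine_gray()] object.
#' @param path Output path for the JSON document.
#' @return `path`, invisibly.
#' @export
write_fine_gray <- function(fit, path) {
  doc <- list(coefficients = unname(fit$coefficients),
              covariate_names = fit$covariate_names,
              baseline = list(jump_times = fit$baseline$jump_times,
                              values = fit$baseline$values,
                              initial_value = fit$baseline$initial_value),
              convergence = list(
                log_partial_likelihood = fit$log_partial_likelihood,
                iterations = fit$iterations,
                converged = fit$converged,
                gradient = unname(fit$gradient),
                info_diag = unname(fit$info_diag)),
              n = fit$n, n_events = fit$n_events)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Fine-Gray fit from JSON
#'
#' @param path Path written by [write_fine_gray()].
#' @return A `fine_gray` object.
#' @export
read_fine_gray <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = stats::setNames(doc$coefficients,
                                                doc$covariate_names),
                 baseline = step_function(doc$baseline$jump_times,
                                          doc$baseline$values,
                                          doc$baseline$initial_value),
                 log_partial_likelihood = doc$convergence$log_partial_likelihood,
                 gradient = doc$convergence$gradient,
                 info_diag = doc$convergence$info_diag,
                 iterations = doc$convergence$iterations,
                 converged = doc$convergence$converged,
                 covariate_names = doc$covariate_names,
                 n = doc$n, n_events = doc$n_events),
            class = "fine_gray")
}
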