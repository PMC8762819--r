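#' Kaplan-Meier estimator, including the reverse (censoring) form
#'
#' Product-limit estimator \eqn{S(t) = \prod_{t_j \le t} (1 - d_j / n_j)}.
#' With `event_definition = "any_event"` both event types (status 1 and 2)
#' count as events, giving the all-cause survival function that the
#' Aalen-Johansen estimator needs. With `event_definition = "censoring"` the
#' roles are reversed: censorings (status 0) are the "events", yielding the
#' censoring-distribution survival function `G` used for
#' inverse-probability-of-censoring weights.
#'
#' Tie convention: events at `t` are counted before censorings at `t`, so a
#' subject censored at `t` remains in the risk set for events at `t`. For the
#' reverse form the roles swap symmetrically: the risk set for censorings at
#' `t` excludes subjects with an event at exactly `t`.
#'
#' @param data A [cr_data] tibble.
#' @param event_definition `"any_event"` or `"censoring"`.
#' @return A [step_function()] (initial value 1, non-increasing).
#' @export
km_survival <- function(data, event_definition = c("any_event", "censoring")) {
  event_definition <- match.arg(event_definition)
  if (nrow(data) == 0) {
    stop_crcalib("Dataset is empty.", "crcalib_error_argument")
  }
  tt <- data$time
  is_ev <- if (event_definition == "any_event") data$status %in% c(1L, 2L)
           else data$status == 0L
  et <- sort(unique(tt[is_ev]))
  if (length(et) == 0) {
    return(step_function(numeric(0), numeric(0), initial_value = 1))
  }
  d <- tabulate(match(tt[is_ev], et), nbins = length(et))
  # n at risk: subjects with time >= t_j ...
  n_ge <- length(tt) - findInterval(et, sort(tt), left.open = TRUE)
  if (event_definition == "censoring") {
    # ... minus subjects with a true event at exactly t_j (events precede
    # censorings at tied times)
    other <- tt[!is_ev]
    m <- match(other, et)
    tied_events <- tabulate(m[!is.na(m)], nbins = length(et))
    n <- n_ge - tied_events
  } else {
    n <- n_ge
  }
  step_function(et, cumprod(1 - d / n), initial_value = 1)
}

#' Aalen-Johansen cumulative incidence estimator
#'
#' Nonparametric estimate of the cumulative incidence function for one event
#' type in the presence of the other:
#' \deqn{\mathrm{CIF}_c(t) = \sum_{t_j \le t} S(t_j-) \, d_{c,j} / n_j,}
#' where `S` is the all-cause Kaplan-Meier survival function and `d_{c,j}`
#' counts cause-`c` events at `t_j`. Unlike the complement of a single
#' Kaplan-Meier curve, this quantity is an unbiased estimate of crude
#' incidence under competing risks.
#'
#' @param data A [cr_data] tibble.
#' @param cause Event type, 1 (primary) or 2 (competing).
#' @return A [step_function()] starting at 0, non-decreasing, values in
#'   \[0, 1\].
#' @export
aalen_johansen <- function(data, cause = 1) {
  if (nrow(data) == 0) {
    stop_crcalib("Dataset is empty.", "crcalib_error_argument")
  }
  if (!cause %in% c(1, 2)) {
    stop_crcalib("`cause` must be 1 or 2.", "crcalib_error_argument")
  }
  tt <- data$time
  is_ev <- data$status %in% c(1L, 2L)
  et <- sort(unique(tt[is_ev]))
  if (length(et) == 0) {
    return(step_function(numeric(0), numeric(0), initial_value = 0))
  }
  d_all <- tabulate(match(tt[is_ev], et), nbins = length(et))
  is_c <- data$status == cause
  d_c <- tabulate(match(tt[is_c], et), nbins = length(et))
  n <- length(tt) - findInterval(et, sort(tt), left.open = TRUE)
  s <- cumprod(1 - d_all / n)
  s_minus <- c(1, s[-length(s)])
  cif <- cumsum(s_minus * d_c / n)
  step_function(et, cif, initial_value = 0)
}
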