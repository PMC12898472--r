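#' IPCW cumulative/dynamic time-dependent AUC
#'
#' Uno-type estimator of the time-dependent AUC of a risk score: at horizon
#' `t`, cases are subjects with an observed event by `t`, controls are
#' subjects still at risk after `t`. Case contributions are weighted by the
#' inverse of the Kaplan-Meier estimate of the censoring survival function at
#' their event time; score ties count 0.5, so a constant score gives exactly
#' 0.5.
#'
#' @param score numeric risk score per sample (higher = higher risk).
#' @param time follow-up time (months).
#' @param event 0/1 event indicator.
#' @param horizons numeric horizons (months), within the observed follow-up.
#' @return named numeric vector of AUCs (`NA` where no case/control pair
#'   exists at the horizon).
#' @export
timeDependentAuc <- function(score, time, event, horizons = c(24, 48, 72, 96)) {
  stopifnot(length(score) == length(time), length(time) == length(event),
            all(event %in% c(0, 1)))
  if (any(horizons > max(time)))
    warning("horizon(s) beyond the observed follow-up")
  ## censoring KM: right-continuous survival of the censoring distribution
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  Ghat <- function(t) {
    ## left-continuous evaluation G(t-): probability of remaining uncensored
    ## just before t, so deaths at a censoring time keep positive weight
    idx <- findInterval(t - 1e-12, cfit$time)
    ifelse(idx == 0, 1, cfit$surv[pmax(idx, 1)])
  }
  out <- vapply(horizons, function(t) {
    cases <- which(event == 1 & time <= t)
    controls <- which(time > t)
    if (!length(cases) || !length(controls)) return(NA_real_)
    w <- 1 / Ghat(time[cases])
    w[!is.finite(w)] <- 0
    if (sum(w) == 0) return(NA_real_)
    ## per-case concordance fraction in [0, 1]; the weighted mean keeps a
    ## constant score at exactly 0.5
    conc <- vapply(cases, function(i) {
      (sum(score[i] > score[controls]) +
         0.5 * sum(score[i] == score[controls])) / length(controls)
    }, numeric(1))
    sum(w * conc) / sum(w)
  }, numeric(1))
  stats::setNames(out, as.character(horizons))
}
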