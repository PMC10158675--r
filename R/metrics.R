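#' Threshold confusion-matrix metrics
#'
#' @param labels 0/1 vector.
#' @param probabilities Scores in \[0,1\].
#' @param threshold Decision threshold (default 0.5; alarms are
#'   `probability >= threshold`).
#' @return List `sensitivity`, `specificity`, `accuracy`, `yi`
#'   (Youden index = sensitivity + specificity - 1).
#' @export
binary_metrics <- function(labels, probabilities, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stopf("class-conditional metrics need both classes present")
  }
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / length(labels), yi = sens + spec - 1)
}

#' Rank-based AUC
#'
#' Probability that a random positive outranks a random negative, ties
#' counted one half (Mann-Whitney form).
#'
#' @inheritParams binary_metrics
#' @return AUC in \[0,1\].
#' @export
auc <- function(labels, probabilities) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("AUC needs both classes present")
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Parameters of the time-dependent MODS utility
#'
#' Piecewise-linear per-hour utility around onset, patterned after the
#' physiological early-warning utility the score is inspired by and
#' re-centred on the 12-hour MODS horizon. An alarm on a deteriorating
#' patient earns a reward rising 0 to 1 over `[onset - early_bound,
#' onset + peak]` and falling back to 0 at `onset + late_bound`; outside that
#' window every alarm costs `u_fp`. Silence on a deteriorating patient
#' accrues a penalty ramping from 0 at `onset - early_bound` to `u_fn_floor`
#' at `onset + late_bound`; silence on a stable patient is worth `u_tn`.
#' The exact published breakpoints are in unavailable supplementary
#' material, so every number here is configurable.
#'
#' @param early_bound Hours before onset where reward begins (default 12).
#' @param peak Hours relative to onset where the reward peaks at 1
#'   (default 0).
#' @param late_bound Hours after onset where reward/penalty end (default 3).
#' @param u_fp Per-hour false-alarm utility (default -0.05).
#' @param u_fn_floor Utility reached by the missed-detection ramp
#'   (default -2).
#' @param u_tn Utility of correct silence (default 0).
#' @return A `utility_params` list.
#' @export
utility_params <- function(early_bound = 12, peak = 0, late_bound = 3,
                           u_fp = -0.05, u_fn_floor = -2, u_tn = 0) {
  stopifnot(early_bound > 0, u_fp <= 0, u_fn_floor <= 0, late_bound >= peak)
  structure(list(early_bound = early_bound, peak = peak,
                 late_bound = late_bound, u_fp = u_fp,
                 u_fn_floor = u_fn_floor, u_tn = u_tn),
            class = "utility_params")
}

# per-hour utilities for one patient; onset NA = never develops MODS
hour_utility <- function(hours, onset, alarm, params) {
  u <- numeric(length(hours))
  if (is.na(onset)) {
    u[alarm] <- params$u_fp
    u[!alarm] <- params$u_tn
    return(u)
  }
  lo <- onset - params$early_bound
  pk <- onset + params$peak
  hi <- onset + params$late_bound
  inside <- hours >= lo & hours <= hi
  rise <- alarm & hours >= lo & hours <= pk
  fall <- alarm & hours > pk & hours <= hi
  u[rise] <- (hours[rise] - lo) / max(pk - lo, 1e-12)
  u[fall] <- 1 - (hours[fall] - pk) / max(hi - pk, 1e-12)
  u[alarm & !inside] <- params$u_fp
  miss <- !alarm & inside
  u[miss] <- params$u_fn_floor * (hours[miss] - lo) / max(hi - lo, 1e-12)
  # silence outside the reward-relevant window is neutral
  u
}

#' Normalized MODS utility score of an alarm policy
#'
#' Raw per-hour utilities (see [utility_params()]) are summed over all
#' patients and normalized as `(U - U_silent) / (U_optimal - U_silent)`,
#' where the silent policy never alarms and the optimal policy alarms
#' exactly on the reward window of deteriorating patients. The silent
#' policy therefore scores 0 and the optimal policy 1. On a degenerate
#' cohort with no deteriorating patient the anchors coincide and the raw
#' difference `U - U_silent` is returned.
#'
#' @param per_patient List of per-patient records, each a list with `hours`
#'   (integer vector), `onset` (hour or NA) and `alarm` (logical vector
#'   aligned with `hours`).
#' @param params A [utility_params()].
#' @return Normalized utility (<= 1).
#' @export
utility_score <- function(per_patient, params = utility_params()) {
  if (!length(per_patient)) stopf("utility_score needs a non-empty cohort")
  total <- 0; silent <- 0; optimal <- 0
  for (p in per_patient) {
    hours <- p$hours
    stopifnot(length(p$alarm) == length(hours))
    total <- total + sum(hour_utility(hours, p$onset, as.logical(p$alarm), params))
    silent <- silent + sum(hour_utility(hours, p$onset, rep(FALSE, length(hours)), params))
    opt_alarm <- if (is.na(p$onset)) rep(FALSE, length(hours)) else {
      hours >= p$onset - params$early_bound & hours <= p$onset + params$late_bound
    }
    optimal <- optimal + sum(hour_utility(hours, p$onset, opt_alarm, params))
  }
  denom <- optimal - silent
  if (denom == 0) return(total - silent)
  (total - silent) / denom
}

# build utility_score() input from an entries-style prediction table
per_patient_alarms <- function(predictions, truth, threshold = 0.5) {
  onsets <- setNames(truth$onset_hour, truth$patient_id)
  lapply(split(predictions, predictions$patient_id), function(d) {
    d <- d[order(d$hour), ]
    list(hours = d$hour, onset = onsets[[d$patient_id[[1]]]],
         alarm = d$probability >= threshold)
  })
}

#' Full evaluation report
#'
#' @param predictions data.frame `patient_id`, `hour`, `probability`.
#' @param labels 0/1 entry labels aligned with `predictions` rows.
#' @param truth data.frame `patient_id`, `onset_hour`.
#' @param threshold Decision threshold (default 0.5); set
#'   `threshold = "yi"` to pick the Youden-maximizing threshold.
#' @param params [utility_params()].
#' @return `metrics_report` list: auc, accuracy, sensitivity, specificity,
#'   yi, utility_score, threshold, n_entries, n_patients.
#' @export
metrics_report <- function(predictions, labels, truth, threshold = 0.5,
                           params = utility_params()) {
  if (identical(threshold, "yi")) {
    cand <- sort(unique(round(predictions$probability, 3)))
    yis <- vapply(cand, function(th) {
      binary_metrics(labels, predictions$probability, th)$yi
    }, numeric(1))
    threshold <- cand[which.max(yis)]
  }
  bm <- binary_metrics(labels, predictions$probability, threshold)
  structure(list(auc = auc(labels, predictions$probability),
                 accuracy = bm$accuracy, sensitivity = bm$sensitivity,
                 specificity = bm$specificity, yi = bm$yi,
                 utility_score = utility_score(
                   per_patient_alarms(predictions, truth, threshold), params),
                 threshold = threshold,
                 n_entries = nrow(predictions),
                 n_patients = length(unique(predictions$patient_id))),
            class = "metrics_report")
}
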