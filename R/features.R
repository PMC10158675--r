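# short camel-case stems used in feature names, per clinical variable
variable_stem <- function() {
  c(heart_rate = "Hr", dopamine = "Dopamine", oxygenation_index = "Oi",
    gcs = "Gcs", lactate = "Lactate", creatinine = "Creatinine",
    bilirubin = "Bilirubin", platelets = "Platelet")
}

organ_stem <- function() {
  c(cardiovascular = "Cardiovascular", respiratory = "Respiratory",
    renal = "Renal", neurologic = "Gcs", hepatic = "Hepatic",
    hematologic = "Hematologic")
}

#' Canonical names of the 37 candidate features
#'
#' Order: elapsed ICU hour; mean/max/min of the eight clinical variables over
#' the current hourly window (24); the six current organ sub-scores; the six
#' trailing-24-hour maxima of those sub-scores.
#'
#' @return Character vector of length 37.
#' @export
feature_names <- function() {
  vs <- variable_stem()
  os <- organ_stem()
  c("currentHour",
    as.vector(t(outer(c("currentMean", "currentMax", "currentMin"), vs, paste0))),
    paste0("current", os, "Mods"),
    paste0(tolower(substring(os, 1, 1)), substring(os, 2), "24HoursMods"))
}

# hourly worst/mean aggregates per variable; windows (h-1, h], 1-based,
# observations at t = 0 assigned to window 1. NA where a window is empty.
hourly_aggregates <- function(stay, n_hours) {
  obs <- stay$observations
  out <- list()
  if (is.null(obs) || !nrow(obs)) {
    empty <- list(mean = rep(NA_real_, n_hours), max = rep(NA_real_, n_hours),
                  min = rep(NA_real_, n_hours))
    for (v in clinical_variables()) out[[v]] <- empty
    return(out)
  }
  hr <- pmax(1L, as.integer(ceiling(obs$time_offset)))
  keep <- hr <= n_hours
  dt <- data.table::data.table(hour = hr[keep], variable = obs$variable[keep],
                               value = obs$value[keep])
  agg <- dt[, list(mean = mean(value), max = max(value), min = min(value)),
            by = c("variable", "hour")]
  for (v in clinical_variables()) {
    sub <- agg[agg$variable == v, ]
    m <- rep(NA_real_, n_hours); mx <- m; mn <- m
    if (nrow(sub)) {
      m[sub$hour] <- sub$mean; mx[sub$hour] <- sub$max; mn[sub$hour] <- sub$min
    }
    out[[v]] <- list(mean = m, max = mx, min = mn)
  }
  out
}

#' Forward-then-backward fill of a gappy series
#'
#' Forward fill takes precedence; remaining leading gaps are back-filled. A
#' series with no observed value at all is returned unchanged (the stay is
#' flagged toward missing-rate accounting instead of being imputed).
#'
#' @param x Numeric vector with NA gaps.
#' @return Filled vector (or `x` unchanged if entirely NA).
#' @export
impute_clinical <- function(x) {
  if (all(is.na(x))) return(x)
  nocb(locf(x))
}

# filled per-variable aggregates plus an `absent` flag per variable; absent
# variables fall back to the healthy reference so downstream feature vectors
# stay complete (cohort filtering is expected to bound how often this fires)
filled_aggregates <- function(stay, n_hours) {
  agg <- hourly_aggregates(stay, n_hours)
  hp <- healthy_params()
  absent <- character(0)
  for (v in clinical_variables()) {
    if (all(is.na(agg[[v]]$mean))) {
      absent <- c(absent, v)
      agg[[v]] <- lapply(agg[[v]], function(x) rep(hp[[v]]$mean, n_hours))
    } else {
      agg[[v]] <- lapply(agg[[v]], impute_clinical)
    }
  }
  attr(agg, "absent") <- absent
  agg
}

# current organ score matrix (n_hours x 6) from filled aggregates; sub-scores
# are recomputed from filled clinical values, never imputed themselves
organ_score_matrix <- function(agg, table, n_hours) {
  scores <- matrix(0L, n_hours, length(organ_systems()),
                   dimnames = list(NULL, organ_systems()))
  map <- organ_aggregate_map()
  for (org in organ_systems()) {
    comp <- rep(0L, n_hours)
    for (agg_name in map[[org]]) {
      var <- sub("^(max|min)_", "", agg_name)
      kind <- sub("_.*$", "", agg_name)
      comp <- pmax(comp, score_variable(agg[[var]][[kind]], var, table))
    }
    scores[, org] <- comp
  }
  scores
}

# trailing window max (window w including current row) per column
rolling_max <- function(scores, w = 24L) {
  n <- nrow(scores)
  out <- scores
  for (h in seq_len(n)) {
    lo <- max(1L, h - w + 1L)
    if (lo < h) out[h, ] <- apply(scores[lo:h, , drop = FALSE], 2, max)
  }
  out
}

#' Per-hour MODS labels under a look-ahead horizon
#'
#' `label(t) = 1` iff the stay has an onset and `onset <= t + horizon`; hours
#' at and after onset stay positive. With `truncate_at_onset = TRUE` hours
#' strictly after onset are dropped (marked NA here; callers remove them).
#'
#' @param hours Integer vector of entry hours.
#' @param onset Onset hour or NA.
#' @param horizon Look-ahead in hours (default 12).
#' @param truncate_at_onset Drop post-onset hours (default FALSE).
#' @return Integer 0/1 labels (NA where truncated).
#' @export
label_entries <- function(hours, onset, horizon = 12L, truncate_at_onset = FALSE) {
  if (horizon < 1) stopf("horizon must be >= 1")
  lab <- if (is.na(onset)) rep(0L, length(hours)) else as.integer(onset <= hours + horizon)
  if (truncate_at_onset && !is.na(onset)) lab[hours > onset] <- NA_integer_
  lab
}

#' Hourly 37-feature entries for one stay
#'
#' @param stay An `icu_stay`.
#' @param table Score table.
#' @param onset Onset hour (NA = none); defaults to `stay$true_onset`.
#' @param horizon Label look-ahead (default 12).
#' @param truncate_at_onset Drop post-onset entries.
#' @return data.frame: `patient_id`, `hour`, `label`, then the 37 features of
#'   [feature_names()].
#' @export
featurize_stay <- function(stay, table = default_score_table(),
                           onset = stay$true_onset, horizon = 12L,
                           truncate_at_onset = FALSE) {
  n_hours <- max(1L, floor(stay$los_hours))
  agg <- filled_aggregates(stay, n_hours)
  if (length(attr(agg, "absent")) == length(clinical_variables())) {
    stopf("stay %s has no observations in any window", stay$patient_id)
  }
  cur <- organ_score_matrix(agg, table, n_hours)
  roll <- rolling_max(cur, 24L)
  vs <- variable_stem()
  cols <- list(patient_id = rep(stay$patient_id, n_hours),
               hour = seq_len(n_hours),
               label = label_entries(seq_len(n_hours), onset, horizon,
                                     truncate_at_onset),
               currentHour = as.numeric(seq_len(n_hours)))
  for (v in clinical_variables()) {
    cols[[paste0("currentMean", vs[[v]])]] <- agg[[v]]$mean
    cols[[paste0("currentMax", vs[[v]])]] <- agg[[v]]$max
    cols[[paste0("currentMin", vs[[v]])]] <- agg[[v]]$min
  }
  os <- organ_stem()
  for (org in organ_systems()) {
    cols[[paste0("current", os[[org]], "Mods")]] <- as.numeric(cur[, org])
  }
  for (org in organ_systems()) {
    nm <- paste0(tolower(substring(os[[org]], 1, 1)), substring(os[[org]], 2),
                 "24HoursMods")
    cols[[nm]] <- as.numeric(roll[, org])
  }
  out <- data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[, c("patient_id", "hour", "label", feature_names())]
  out <- out[!is.na(out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the 37-feature vector for a single patient-hour
#'
#' @inheritParams featurize_stay
#' @param hour Window index (1-based).
#' @return Named numeric vector of length 37.
#' @export
extract_features <- function(stay, hour, table = default_score_table()) {
  n_hours <- max(1L, floor(stay$los_hours))
  if (hour < 1 || hour > n_hours) stopf("hour %d outside stay windows 1..%d", hour, n_hours)
  ent <- featurize_stay(stay, table)
  row <- ent[ent$hour == hour, feature_names(), drop = FALSE]
  if (!nrow(row)) stopf("empty window at hour %d after imputation", hour)
  unlist(row[1, ])
}

#' Featurize a whole cohort
#'
#' @param cohort An `icu_cohort` (onsets taken from `cohort$truth`).
#' @inheritParams featurize_stay
#' @return Stacked entries data.frame.
#' @export
featurize_cohort <- function(cohort, table = default_score_table(),
                             horizon = 12L, truncate_at_onset = FALSE) {
  onsets <- setNames(cohort$truth$onset_hour, cohort$truth$patient_id)
  out <- lapply(cohort$stays, function(s) {
    featurize_stay(s, table, onset = onsets[[s$patient_id]], horizon = horizon,
                   truncate_at_onset = truncate_at_onset)
  })
  res <- as.data.frame(data.table::rbindlist(out))
  rownames(res) <- NULL
  res
}

#' Cohort inclusion filter
#'
#' Defaults mirror a geriatric ICU early-warning cohort: age >= 65, first ICU
#' stay, length of stay over 24 h, missing feature rate under 30%.
#'
#' @param min_age Minimum age in years (default 65, inclusive).
#' @param min_los Minimum length of stay in hours (default 24, exclusive).
#' @param max_missing_rate Exclusive upper bound on the missing feature rate
#'   (default 0.30).
#' @param first_stay_only Require first ICU admission (default TRUE).
#' @param missing_mode `"variables"` (default: fraction of the 8 clinical
#'   variables never observed during the stay) or `"hours"` (fraction of
#'   patient-hour x variable cells with no observation).
#' @return A `cohort_filter` list.
#' @export
cohort_filter <- function(min_age = 65, min_los = 24, max_missing_rate = 0.30,
                          first_stay_only = TRUE, missing_mode = "variables") {
  stopifnot(min_age > 0, min_los > 0,
            max_missing_rate > 0, max_missing_rate < 1,
            missing_mode %in% c("variables", "hours"))
  structure(list(min_age = min_age, min_los = min_los,
                 max_missing_rate = max_missing_rate,
                 first_stay_only = first_stay_only,
                 missing_mode = missing_mode),
            class = "cohort_filter")
}

stay_missing_rate <- function(stay, mode = "variables") {
  n_hours <- max(1L, floor(stay$los_hours))
  agg <- hourly_aggregates(stay, n_hours)
  if (mode == "variables") {
    mean(vapply(clinical_variables(), function(v) all(is.na(agg[[v]]$mean)),
                logical(1)))
  } else {
    mean(vapply(clinical_variables(), function(v) mean(is.na(agg[[v]]$mean)),
                numeric(1)))
  }
}

#' Apply inclusion criteria to a cohort
#'
#' @param cohort An `icu_cohort`.
#' @param filter A [cohort_filter()].
#' @return List with `included` (an `icu_cohort`) and `exclusions`
#'   (data.frame `patient_id`, `reason`: one reason per excluded stay, the
#'   first failing criterion in the order age, length of stay, missingness,
#'   readmission).
#' @export
filter_cohort <- function(cohort, filter = cohort_filter()) {
  reasons <- vapply(cohort$stays, function(s) {
    if (s$age < filter$min_age) return("age")
    if (s$los_hours <= filter$min_los) return("length of stay")
    if (stay_missing_rate(s, filter$missing_mode) >= filter$max_missing_rate) {
      return("missingness")
    }
    if (filter$first_stay_only && !isTRUE(s$first_icu_stay)) return("readmission")
    ""
  }, character(1))
  keep <- reasons == ""
  incl <- structure(list(stays = cohort$stays[keep],
                         truth = cohort$truth[cohort$truth$patient_id %in%
                                                names(cohort$stays)[keep], ,
                                              drop = FALSE]),
                    class = "icu_cohort")
  rownames(incl$truth) <- NULL
  list(included = incl,
       exclusions = data.frame(patient_id = names(cohort$stays)[!keep],
                               reason = unname(reasons[!keep]),
                               stringsAsFactors = FALSE))
}

#' Fit / apply Gaussian normalization
#'
#' `fit_normalizer` records per-feature training mean and standard deviation;
#' `apply_normalizer` z-scores `(x - mu) / sigma`, passing `sigma = 0`
#' features through centred only. Fit on the training split only and apply
#' the same parameters to every evaluation split.
#'
#' @param entries Entries data.frame from [featurize_cohort()].
#' @param features Feature columns (default [feature_names()]).
#' @return `fit_normalizer`: a `mods_normalizer` (lists `mu`, `sigma`);
#'   `apply_normalizer`: the entries with features replaced by z-scores.
#' @export
fit_normalizer <- function(entries, features = feature_names()) {
  X <- as.matrix(entries[, features, drop = FALSE])
  structure(list(mu = colMeans(X),
                 sigma = apply(X, 2, function(c) sqrt(mean((c - mean(c))^2)))),
            class = "mods_normalizer")
}

#' @rdname fit_normalizer
#' @param params A `mods_normalizer`.
#' @export
apply_normalizer <- function(entries, params) {
  feats <- names(params$mu)
  if (!all(feats %in% names(entries))) {
    stopf("feature-name mismatch between normalizer and entries")
  }
  for (f in feats) {
    s <- params$sigma[[f]]
    entries[[f]] <- (entries[[f]] - params$mu[[f]]) / (if (s > 0) s else 1)
  }
  entries
}

#' Serialize normalization parameters as JSON
#' @param params A `mods_normalizer`.
#' @param path File path.
#' @export
write_normalizer <- function(params, path) {
  obj <- lapply(names(params$mu), function(f) {
    list(mu = unname(params$mu[[f]]), sigma = unname(params$sigma[[f]]))
  })
  names(obj) <- names(params$mu)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalizer
#' @export
read_normalizer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mu = vapply(obj, `[[`, numeric(1), "mu"),
                 sigma = vapply(obj, `[[`, numeric(1), "sigma")),
            class = "mods_normalizer")
}

#' Patient-level train/validation split
#'
#' No patient contributes entries to both sides.
#'
#' @param entries Entries data.frame with a `patient_id` column.
#' @param train_fraction Fraction of patients assigned to training
#'   (default 0.8).
#' @param seed Integer seed.
#' @return List `train`, `validation` of entries data.frames.
#' @export
split_by_patient <- function(entries, train_fraction = 0.8, seed = 1L) {
  ids <- unique(entries$patient_id)
  if (length(ids) < 2L) stopf("need at least 2 patients to split")
  n_train <- min(max(1L, round(train_fraction * length(ids))), length(ids) - 1L)
  train_ids <- with_seed(seed, sample(ids, n_train))
  list(train = entries[entries$patient_id %in% train_ids, , drop = FALSE],
       validation = entries[!entries$patient_id %in% train_ids, , drop = FALSE])
}
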