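#' Configuration for the synthetic ICU cohort generator
#'
#' The generator emulates the structure of real critical-care observation
#' streams: irregular sampling (exponential inter-arrival times), per-variable
#' missingness, and controllable MODS deterioration episodes whose onset hour
#' is known exactly, so that every downstream stage can be tested without
#' credentialed clinical data.
#'
#' @param n_patients Number of ICU stays to simulate.
#' @param mean_los_hours Mean length of stay in hours (> 24; default 72).
#' @param age_range Two-element range of ages in years for the elderly bulk
#'   of the cohort (default 65-90).
#' @param mods_prevalence Probability that a stay carries a deterioration
#'   episode (default 0.3, matching the mid-range of reported adult ICU MODS
#'   incidence of 11-40%).
#' @param onset_window Hours after admission within which an onset may be
#'   placed (default 30-120).
#' @param missing_rate Per-observation thinning probability in \[0,1)
#'   (default 0.1).
#' @param sampling_interval Mean minutes between observations of one variable
#'   (default 60).
#' @param frac_young Fraction of stays drawn younger than 65 so cohort
#'   filtering is exercised (default 0.1).
#' @param readmit_rate Fraction of stays flagged as readmissions (default 0.1).
#' @param seed Integer seed; fully determines the cohort.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients, mean_los_hours = 72, age_range = c(65, 90),
                       mods_prevalence = 0.3, onset_window = c(30, 120),
                       missing_rate = 0.1, sampling_interval = 60,
                       frac_young = 0.1, readmit_rate = 0.1, seed = 1L) {
  cfg <- list(n_patients = n_patients, mean_los_hours = mean_los_hours,
              age_range = age_range, mods_prevalence = mods_prevalence,
              onset_window = onset_window, missing_rate = missing_rate,
              sampling_interval = sampling_interval, frac_young = frac_young,
              readmit_rate = readmit_rate, seed = seed)
  if (!is.numeric(n_patients) || n_patients < 0 || n_patients != round(n_patients)) {
    stopf("invalid config field 'n_patients': must be a non-negative integer")
  }
  if (mean_los_hours <= 24) stopf("invalid config field 'mean_los_hours': must exceed 24")
  if (mods_prevalence < 0 || mods_prevalence > 1) {
    stopf("invalid config field 'mods_prevalence': must be in [0,1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stopf("invalid config field 'missing_rate': must be in [0,1)")
  }
  if (length(onset_window) != 2L || onset_window[1] > onset_window[2] || onset_window[1] < 1) {
    stopf("invalid config field 'onset_window': need 1 <= min <= max")
  }
  if (sampling_interval <= 0) stopf("invalid config field 'sampling_interval': must be positive")
  structure(cfg, class = "sim_config")
}

# healthy operating point per variable: mean, sd, and clamp range chosen so
# baseline noise always maps to sub-score 0 under the default table
healthy_params <- function() {
  list(
    heart_rate        = list(mean = 80,  sd = 8,   lo = 55,  hi = 100, int = FALSE),
    dopamine          = list(mean = 0,   sd = 0,   lo = 0,   hi = 0,   int = FALSE),
    oxygenation_index = list(mean = 400, sd = 35,  lo = 310, hi = 520, int = FALSE),
    gcs               = list(mean = 15,  sd = 0,   lo = 15,  hi = 15,  int = TRUE),
    lactate           = list(mean = 1.2, sd = 0.3, lo = 0.4, hi = 2,   int = FALSE),
    creatinine        = list(mean = 80,  sd = 8,   lo = 50,  hi = 100, int = FALSE),
    bilirubin         = list(mean = 10,  sd = 3,   lo = 2,   hi = 20,  int = FALSE),
    platelets         = list(mean = 250, sd = 30,  lo = 130, hi = 400, int = FALSE)
  )
}

# representative value inside a given severity band of a variable
value_for_score <- function(variable, score, table = default_score_table()) {
  ent <- table[[variable]]
  cuts <- ent$cuts
  hp <- healthy_params()[[variable]]
  v <- if (score == 0) {
    hp$mean
  } else if (score < 4) {
    (cuts[score] + cuts[score + 1]) / 2
  } else if (ent$direction == "higher") {
    cuts[4] * 1.25 + 1
  } else {
    cuts[4] * 0.6
  }
  if (hp$int) v <- round(v)
  v
}

# organ -> variable ramped to drive its sub-score (cardiovascular uses lactate)
organ_drive_variable <- function() {
  c(cardiovascular = "lactate", respiratory = "oxygenation_index",
    renal = "creatinine", neurologic = "gcs", hepatic = "bilirubin",
    hematologic = "platelets")
}

#' Inject a deterioration episode into a stay
#'
#' Adds per-organ observation ramps such that scoring the returned stay with
#' [score_stay()] and [detect_mods()] under the same table and criterion
#' recovers `onset_hour` exactly: pre-onset ramp values stay strictly below
#' the dysfunction threshold band and the target band is first entered in the
#' onset hour's window.
#'
#' @param stay An `icu_stay`.
#' @param onset_hour Integer hour, `< floor(stay$los_hours)`.
#' @param profile Named numeric vector, organ id -> target sub-score (2..4).
#'   At least `organs_required` organs must be driven for the episode to
#'   register as MODS under the default criterion.
#' @param table Score table used to pick in-band values.
#' @param ramp_hours Length of the pre-onset linear ramp (default 12).
#' @param dysfunction_threshold Sub-score the episode first reaches at onset
#'   (default 2, the default criterion's threshold).
#' @return The stay with injected observations and `true_onset` set.
#' @export
inject_deterioration <- function(stay, onset_hour, profile,
                                 table = default_score_table(),
                                 ramp_hours = 12, dysfunction_threshold = 2L) {
  if (onset_hour >= floor(stay$los_hours)) {
    stopf("onset_hour %d is beyond discharge (LOS %.1f h)", onset_hour, stay$los_hours)
  }
  if (is.null(names(profile)) || !all(names(profile) %in% organ_systems())) {
    stopf("profile must be named by organ system")
  }
  drv <- organ_drive_variable()
  new_obs <- list()
  for (org in names(profile)) {
    target <- as.integer(profile[[org]])
    stopifnot(target >= 1, target <= 4)
    var <- drv[[org]]
    pre_v <- value_for_score(var, dysfunction_threshold - 1L, table)
    healthy_v <- healthy_params()[[var]]$mean
    ramp_t <- seq.int(max(1L, onset_hour - ramp_hours), onset_hour - 1L)
    if (length(ramp_t)) {
      frac <- seq_along(ramp_t) / (length(ramp_t) + 1)
      ramp_v <- healthy_v + frac * (pre_v - healthy_v)
      if (healthy_params()[[var]]$int) ramp_v <- round(ramp_v)
      new_obs[[length(new_obs) + 1L]] <- data.frame(
        time_offset = as.numeric(ramp_t), variable = var, value = ramp_v)
    }
    post_t <- seq.int(onset_hour, floor(stay$los_hours))
    post_v <- rep(value_for_score(var, target, table), length(post_t))
    new_obs[[length(new_obs) + 1L]] <- data.frame(
      time_offset = as.numeric(post_t), variable = var, value = post_v)
  }
  obs <- rbind(stay$observations, do.call(rbind, new_obs))
  obs <- obs[order(obs$time_offset, match(obs$variable, clinical_variables())), ]
  rownames(obs) <- NULL
  stay$observations <- obs
  stay$true_onset <- as.integer(onset_hour)
  stay
}

simulate_stay <- function(id, cfg, table, seed) {
  with_seed(seed, {
    young <- runif(1) < cfg$frac_young
    age <- if (young) runif(1, 45, 64.5) else runif(1, max(65, cfg$age_range[1]), cfg$age_range[2])
    first_stay <- runif(1) >= cfg$readmit_rate
    los <- 24 + rexp(1, 1 / max(1, cfg$mean_los_hours - 24))
    deteriorate <- runif(1) < cfg$mods_prevalence
    onset <- NA_integer_
    if (deteriorate) {
      w_lo <- cfg$onset_window[1]
      w_hi <- cfg$onset_window[2]
      if (floor(los) - 1 < w_lo) los <- w_lo + 24
      onset <- sample(seq.int(w_lo, min(w_hi, floor(los) - 1L)), 1L)
    }
    hp <- healthy_params()
    obs <- list()
    for (var in clinical_variables()) {
      gaps <- rexp(ceiling(los * 60 / cfg$sampling_interval * 2) + 5,
                   60 / cfg$sampling_interval)
      times <- cumsum(gaps)
      times <- times[times <= los]
      if (!length(times)) times <- runif(1, 0, los)
      p <- hp[[var]]
      vals <- pmin(p$hi, pmax(p$lo, rnorm(length(times), p$mean, p$sd)))
      if (p$int) vals <- round(vals)
      keep <- runif(length(times)) >= cfg$missing_rate
      if (any(keep)) {
        obs[[var]] <- data.frame(time_offset = times[keep], variable = var,
                                 value = vals[keep])
      }
    }
    obs <- do.call(rbind, obs)
    obs <- obs[order(obs$time_offset), ]
    rownames(obs) <- NULL
    stay <- structure(list(patient_id = id, age = age,
                           first_icu_stay = first_stay, los_hours = los,
                           observations = obs, true_onset = NA_integer_),
                      class = "icu_stay")
    if (deteriorate) {
      organs <- sample(organ_systems(), sample(2:3, 1))
      profile <- setNames(sample(2:4, length(organs), replace = TRUE), organs)
      stay <- inject_deterioration(stay, onset, profile, table)
    }
    stay
  })
}

#' Simulate a synthetic ICU cohort with known MODS onsets
#'
#' @param cfg A [sim_config()].
#' @param table Score table used when injecting deterioration episodes.
#' @return An `icu_cohort`: list with `stays` (list of `icu_stay`) and
#'   `truth` (data.frame `patient_id`, `onset_hour`, NA = never develops
#'   MODS). Fully reproducible from `cfg$seed`.
#' @export
simulate_cohort <- function(cfg, table = default_score_table()) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  stays <- lapply(seq_len(n), function(i) {
    simulate_stay(ids[[i]], cfg, table, child_seed(cfg$seed, i))
  })
  names(stays) <- ids
  truth <- data.frame(
    patient_id = ids,
    onset_hour = if (n) vapply(stays, function(s) s$true_onset, integer(1)) else integer(0),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  structure(list(stays = stays, truth = truth), class = "icu_cohort")
}

#' Score a stay hour by hour
#'
#' Aggregates raw observations into hourly worst-case values (windows
#' `(h-1, h]`, 1-based), carries the last aggregate forward over empty
#' windows (then back-fills leading gaps), and maps them to organ sub-scores.
#'
#' @param stay An `icu_stay`.
#' @param table Score table.
#' @param n_hours Number of hourly windows (default `floor(los_hours)`).
#' @return Integer matrix, `n_hours` x 6 organ systems.
#' @export
score_stay <- function(stay, table = default_score_table(), n_hours = NULL) {
  n_hours <- n_hours %||% max(1L, floor(stay$los_hours))
  agg <- hourly_aggregates(stay, n_hours)
  scores <- matrix(0L, n_hours, length(organ_systems()),
                   dimnames = list(NULL, organ_systems()))
  map <- organ_aggregate_map()
  for (org in organ_systems()) {
    comp <- rep(0L, n_hours)
    for (agg_name in map[[org]]) {
      var <- sub("^(max|min)_", "", agg_name)
      kind <- sub("_.*$", "", agg_name)
      x <- agg[[var]][[kind]]
      x <- nocb(locf(x))
      if (all(is.na(x))) next  # variable never observed: contributes score 0
      comp <- pmax(comp, score_variable(x, var, table))
    }
    scores[, org] <- comp
  }
  scores
}

#' Write / read a cohort's observations as long-format CSV
#'
#' Header `patient_id,age,first_icu_stay,time_offset_hours,variable,value`,
#' UTF-8, `.` decimal separator. Values are written with full precision
#' (`%.17g`) so that `read_observations(write_observations(x))` reproduces
#' every observation tuple exactly.
#'
#' @param cohort An `icu_cohort`.
#' @param path Output path.
#' @return `write_observations` invisibly returns `path`;
#'   `read_observations` returns an `icu_cohort` (with unknown onsets: the
#'   observation file carries measurements only — see [write_truth()]).
#' @export
write_observations <- function(cohort, path) {
  rows <- lapply(cohort$stays, function(s) {
    if (is.null(s$observations) || !nrow(s$observations)) return(NULL)
    data.frame(patient_id = s$patient_id,
               age = sprintf("%.17g", s$age),
               first_icu_stay = as.integer(s$first_icu_stay),
               time_offset_hours = sprintf("%.17g", s$observations$time_offset),
               variable = s$observations$variable,
               value = sprintf("%.17g", s$observations$value),
               stringsAsFactors = FALSE)
  })
  dt <- data.table::rbindlist(rows)
  if (!nrow(dt)) {
    dt <- data.table::data.table(patient_id = character(), age = character(),
                                 first_icu_stay = integer(),
                                 time_offset_hours = character(),
                                 variable = character(), value = character())
  }
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = c(1, 2, 4, 5, 6)),
                          header = TRUE)
  expected <- c("patient_id", "age", "first_icu_stay", "time_offset_hours",
                "variable", "value")
  if (!identical(names(dt), expected)) {
    stopf("parse error: header must be '%s'", paste(expected, collapse = ","))
  }
  if (!nrow(dt)) {
    return(structure(list(stays = list(),
                          truth = data.frame(patient_id = character(),
                                             onset_hour = integer())),
                     class = "icu_cohort"))
  }
  bad_var <- which(!dt$variable %in% clinical_variables())
  if (length(bad_var)) {
    stopf("parse error at line %d: unknown variable '%s'",
          bad_var[[1]] + 1L, dt$variable[bad_var[[1]]])
  }
  tm <- suppressWarnings(as.numeric(dt$time_offset_hours))
  vl <- suppressWarnings(as.numeric(dt$value))
  bad_num <- which(is.na(tm) | is.na(vl))
  if (length(bad_num)) stopf("parse error at line %d: non-numeric field", bad_num[[1]] + 1L)
  ids <- unique(dt$patient_id)
  stays <- lapply(ids, function(id) {
    rows <- dt$patient_id == id
    obs <- data.frame(time_offset = tm[rows], variable = dt$variable[rows],
                      value = vl[rows], stringsAsFactors = FALSE)
    structure(list(patient_id = id,
                   age = as.numeric(dt$age[rows][1]),
                   first_icu_stay = as.logical(as.integer(dt$first_icu_stay[rows][1])),
                   los_hours = max(obs$time_offset),
                   observations = obs, true_onset = NA_integer_),
              class = "icu_stay")
  })
  names(stays) <- ids
  structure(list(stays = stays,
                 truth = data.frame(patient_id = ids, onset_hour = NA_integer_,
                                    stringsAsFactors = FALSE)),
            class = "icu_cohort")
}

#' Write / read the ground-truth onset table
#' @param truth data.frame `patient_id`, `onset_hour` (NA = no MODS).
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  data.table::fwrite(truth, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  as.data.frame(data.table::fread(path, header = TRUE,
                                  colClasses = list(character = 1L)))
}
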