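#' Clinical variables scored by the modified MODS system
#'
#' The eight raw variables consumed by the pipeline, in canonical order.
#' Units: heart rate per minute, dopamine ug/kg/min, oxygenation index
#' (PaO2/FiO2), GCS points (integer 3-15), lactate mmol/L, creatinine umol/L,
#' bilirubin umol/L, platelets 10^9/L.
#'
#' @return Character vector of the eight variable ids.
#' @export
clinical_variables <- function() {
  c("heart_rate", "dopamine", "oxygenation_index", "gcs",
    "lactate", "creatinine", "bilirubin", "platelets")
}

#' The six organ systems of the modified MODS score
#' @return Character vector of organ ids in canonical order.
#' @export
organ_systems <- function() {
  c("cardiovascular", "respiratory", "renal", "neurologic",
    "hepatic", "hematologic")
}

#' Default severity score table
#'
#' Maps each scored variable to a 0-4 severity band. For a "higher"-direction
#' variable (higher value = worse) the four cuts are upper band edges and the
#' score is the number of cuts the value exceeds; for a "lower" variable the
#' cuts are given in decreasing order and the score is the number of cuts the
#' value is at or below. Bands are half-open, closed on the healthy side. The
#' exact cut-points of the source scoring system's supplementary table are not
#' published, so these Marshall-style defaults are placeholders and the whole
#' table is a plain list that can be replaced wholesale or loaded from JSON
#' with [read_score_table()].
#'
#' @return A `mods_score_table`: named list with `direction` and `cuts` per
#'   variable.
#' @examples
#' tb <- default_score_table()
#' score_variable(3, "gcs", tb)    # 4
#' score_variable(90, "creatinine", tb) # 0
#' @export
default_score_table <- function() {
  tb <- list(
    heart_rate        = list(direction = "higher", cuts = c(100, 120, 140, 160)),
    dopamine          = list(direction = "higher", cuts = c(0, 5, 10, 15)),
    lactate           = list(direction = "higher", cuts = c(2, 3.5, 5, 8)),
    creatinine        = list(direction = "higher", cuts = c(100, 200, 350, 500)),
    bilirubin         = list(direction = "higher", cuts = c(20, 60, 120, 240)),
    oxygenation_index = list(direction = "lower",  cuts = c(300, 225, 150, 75)),
    gcs               = list(direction = "lower",  cuts = c(14, 12, 9, 6)),
    platelets         = list(direction = "lower",  cuts = c(120, 80, 50, 20))
  )
  structure(tb, class = "mods_score_table")
}

validate_score_table <- function(table) {
  if (!is.list(table) || !length(table)) stopf("score table must be a non-empty list")
  for (v in names(table)) {
    ent <- table[[v]]
    if (!ent$direction %in% c("higher", "lower")) {
      stopf("score table entry '%s': direction must be 'higher' or 'lower'", v)
    }
    cuts <- ent$cuts
    if (length(cuts) != 4L || anyNA(cuts)) {
      stopf("score table entry '%s': exactly 4 finite cuts required", v)
    }
    ordered <- if (ent$direction == "higher") all(diff(cuts) > 0) else all(diff(cuts) < 0)
    if (!ordered) stopf("score table entry '%s': cuts must be strictly ordered", v)
  }
  invisible(table)
}

#' Read / write a score table as JSON
#'
#' @param path File path.
#' @return `read_score_table` returns a `mods_score_table`.
#' @export
read_score_table <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tb <- lapply(raw, function(e) list(direction = e$direction, cuts = as.numeric(e$cuts)))
  tb <- structure(tb, class = "mods_score_table")
  validate_score_table(tb)
  tb
}

#' @rdname read_score_table
#' @param table A `mods_score_table`.
#' @export
write_score_table <- function(table, path) {
  validate_score_table(table)
  jsonlite::write_json(lapply(unclass(table), function(e) {
    list(direction = e$direction, cuts = e$cuts)
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Map a clinical value to its 0-4 severity sub-score
#'
#' @param value Numeric value(s), finite.
#' @param variable One of the table's variable ids.
#' @param table Score table, see [default_score_table()].
#' @return Integer score(s) in 0..4, monotone in the severity direction.
#' @export
score_variable <- function(value, variable, table = default_score_table()) {
  if (!variable %in% names(table)) stopf("unknown scored variable '%s'", variable)
  if (!all(is.finite(value))) stopf("non-finite value for variable '%s'", variable)
  ent <- table[[variable]]
  if (ent$direction == "higher") {
    as.integer(rowSums(outer(value, ent$cuts, `>`)))
  } else {
    as.integer(rowSums(outer(value, ent$cuts, `<=`)))
  }
}

# aggregate (worst-case within the hour) required per organ
organ_aggregate_map <- function() {
  list(
    cardiovascular = c("max_dopamine", "max_lactate", "max_heart_rate"),
    respiratory    = "min_oxygenation_index",
    renal          = "max_creatinine",
    neurologic     = "min_gcs",
    hepatic        = "max_bilirubin",
    hematologic    = "min_platelets"
  )
}

#' Per-organ sub-scores from hourly worst-case aggregates
#'
#' The cardiovascular sub-score is the maximum of the dopamine-, lactate- and
#' heart-rate-mapped scores; each other organ is governed by a single
#' aggregate (minimum oxygenation index, maximum creatinine, minimum GCS,
#' maximum bilirubin, minimum platelets).
#'
#' @param aggregates Named list/vector with elements `max_dopamine`,
#'   `max_lactate`, `max_heart_rate`, `min_oxygenation_index`,
#'   `max_creatinine`, `min_gcs`, `max_bilirubin`, `min_platelets`.
#' @param table Score table.
#' @return Named integer vector over [organ_systems()], each in 0..4.
#' @export
organ_scores <- function(aggregates, table = default_score_table()) {
  map <- organ_aggregate_map()
  need <- unlist(map, use.names = FALSE)
  missing <- setdiff(need, names(aggregates))
  if (length(missing)) stopf("missing aggregate '%s'", missing[[1]])
  one <- function(agg_name) {
    var <- sub("^(max|min)_", "", agg_name)
    score_variable(as.numeric(aggregates[[agg_name]]), var, table)
  }
  out <- vapply(organ_systems(), function(org) {
    max(vapply(map[[org]], one, integer(1)))
  }, integer(1))
  out
}

#' Detect MODS onset in a sequence of hourly organ scores
#'
#' @param hourly_scores Integer matrix, rows = contiguous hours starting at 1,
#'   columns = the six organ systems.
#' @param dysfunction_threshold Minimum sub-score counting as dysfunction
#'   (default 2).
#' @param organs_required Number of simultaneously dysfunctional organs
#'   defining MODS (default 2, "two or more organs").
#' @return The first hour satisfying the criterion, or `NA_integer_`.
#' @export
detect_mods <- function(hourly_scores, dysfunction_threshold = 2L,
                        organs_required = 2L) {
  if (is.null(dim(hourly_scores)) || nrow(hourly_scores) == 0L) {
    stopf("hourly_scores must be a non-empty matrix of organ scores")
  }
  if (dysfunction_threshold < 1 || dysfunction_threshold > 4) {
    stopf("dysfunction_threshold must be in 1..4")
  }
  if (organs_required < 1 || organs_required > ncol(hourly_scores)) {
    stopf("organs_required must be in 1..%d", ncol(hourly_scores))
  }
  n_dys <- rowSums(hourly_scores >= dysfunction_threshold)
  hit <- which(n_dys >= organs_required)
  if (length(hit)) as.integer(hit[[1]]) else NA_integer_
}
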