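# mapping from organ sub-score feature to its governing raw aggregate
# feature(s) under the score table
organ_feature_map <- function() {
  list(
    currentCardiovascularMods = list(vars = c(heart_rate = "currentMaxHr",
                                              dopamine = "currentMaxDopamine",
                                              lactate = "currentMaxLactate")),
    currentRespiratoryMods = list(vars = c(oxygenation_index = "currentMinOi")),
    currentRenalMods = list(vars = c(creatinine = "currentMaxCreatinine")),
    currentGcsMods = list(vars = c(gcs = "currentMinGcs")),
    currentHepaticMods = list(vars = c(bilirubin = "currentMaxBilirubin")),
    currentHematologicMods = list(vars = c(platelets = "currentMinPlatelet"))
  )
}

rolling_of_current <- function() {
  c(currentCardiovascularMods = "cardiovascular24HoursMods",
    currentRespiratoryMods = "respiratory24HoursMods",
    currentRenalMods = "renal24HoursMods",
    currentGcsMods = "gcs24HoursMods",
    currentHepaticMods = "hepatic24HoursMods",
    currentHematologicMods = "hematologic24HoursMods")
}

# derive each current organ sub-score from the candidate's raw aggregates
derive_subscores <- function(x, table) {
  out <- x
  for (sub in names(organ_feature_map())) {
    vars <- organ_feature_map()[[sub]]$vars
    sc <- max(vapply(seq_along(vars), function(i) {
      score_variable(x[[vars[[i]]]], names(vars)[[i]], table)
    }, integer(1)))
    out[[sub]] <- as.numeric(sc)
  }
  out
}

# make a candidate internally consistent: sub-scores follow from raw
# aggregates, rolling >= current, min <= mean <= max
repair_candidate <- function(x, table) {
  for (v in unname(variable_stem())) {
    mn <- paste0("currentMin", v); me <- paste0("currentMean", v)
    mx <- paste0("currentMax", v)
    if (!all(c(mn, me, mx) %in% names(x))) next
    lo <- min(x[[mn]], x[[me]], x[[mx]])
    hi <- max(x[[mn]], x[[me]], x[[mx]])
    x[[mn]] <- lo; x[[mx]] <- hi
    x[[me]] <- min(max(x[[me]], lo), hi)
  }
  x <- derive_subscores(x, table)
  roll <- rolling_of_current()
  for (cur in names(roll)) x[[roll[[cur]]]] <- max(x[[roll[[cur]]]], x[[cur]])
  x
}

#' Default admissible intervals for the 37 features
#'
#' Physiologically plausible ranges spanning healthy to severely deranged
#' values; sub-scores range over 0..4 and `currentHour` is pinned at the
#' instance's value (it is immutable by default anyway).
#'
#' @param instance Named feature vector.
#' @param table Score table used to anchor the severe end of each raw range.
#' @return Named list feature -> `c(lo, hi)`.
#' @export
default_feature_ranges <- function(instance, table = default_score_table()) {
  ranges <- list()
  raw_range <- list(
    Hr = c(30, 220), Dopamine = c(0, 30), Oi = c(30, 600), Gcs = c(3, 15),
    Lactate = c(0, 15), Creatinine = c(20, 900), Bilirubin = c(1, 400),
    Platelet = c(1, 600))
  for (v in names(raw_range)) {
    for (pre in c("currentMean", "currentMax", "currentMin")) {
      ranges[[paste0(pre, v)]] <- raw_range[[v]]
    }
  }
  for (f in grep("Mods$", feature_names(), value = TRUE)) ranges[[f]] <- c(0, 4)
  ranges$currentHour <- rep(instance[["currentHour"]], 2)
  ranges
}

#' Counterfactual query
#'
#' @param instance Named 37-feature vector with a positive (undesired)
#'   prediction.
#' @param k Number of counterfactuals requested (>= 1).
#' @param immutable_features Features that must not change (default
#'   `"currentHour"`: the elapsed ICU hour cannot be intervened on).
#' @param feature_ranges Admissible interval per mutable feature
#'   (default [default_feature_ranges()]).
#' @param lambda_proximity,lambda_diversity Non-negative loss weights
#'   (defaults 0.1 and 0.5).
#' @param seed Search seed.
#' @return A `cf_query`.
#' @export
cf_query <- function(instance, k = 3L, immutable_features = "currentHour",
                     feature_ranges = NULL, lambda_proximity = 0.1,
                     lambda_diversity = 0.5, seed = 1L) {
  stopifnot(k >= 1, lambda_proximity >= 0, lambda_diversity >= 0)
  instance <- unlist(instance)
  structure(list(instance = instance, k = as.integer(k),
                 immutable_features = immutable_features,
                 feature_ranges = feature_ranges,
                 lambda_proximity = lambda_proximity,
                 lambda_diversity = lambda_diversity, seed = as.integer(seed)),
            class = "cf_query")
}

#' Scaled L1 proximity between an instance and a counterfactual
#'
#' `sum_i |x_i - cf_i| / scale_i` over the supplied features; scales are
#' per-feature median absolute deviations of the training data (zero-MAD
#' features use 1).
#'
#' @param x,cf Named feature vectors with identical names.
#' @param scales Named positive scales (default all 1).
#' @return Non-negative real.
#' @export
cf_proximity <- function(x, cf, scales = NULL) {
  if (!identical(names(x), names(cf))) stopf("feature mismatch between x and cf")
  s <- scales %||% setNames(rep(1, length(x)), names(x))
  s <- ifelse(s > 0, s, 1)
  sum(abs(x - cf) / s[names(x)])
}

#' Determinantal diversity of a counterfactual set
#'
#' `det(K)` with `K_ij = 1 / (1 + proximity(cf_i, cf_j))`; 1 for a single
#' candidate, 0 when two candidates coincide.
#'
#' @param candidates List of named feature vectors.
#' @param scales Proximity scales.
#' @return Determinant in \[0, 1\].
#' @export
cf_diversity <- function(candidates, scales = NULL) {
  k <- length(candidates)
  if (k == 0) stopf("need at least one candidate")
  K <- diag(1, k)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        K[i, j] <- K[j, i] <- 1 / (1 + cf_proximity(candidates[[i]],
                                                    candidates[[j]], scales))
      }
    }
  }
  det(K)
}

#' Per-feature MAD scales from training entries
#' @param entries Entries data.frame.
#' @return Named numeric vector over [feature_names()] (zero MADs -> 1).
#' @export
mad_scales <- function(entries) {
  s <- vapply(feature_names(), function(f) {
    stats::mad(entries[[f]], constant = 1)
  }, numeric(1))
  ifelse(s > 0, s, 1)
}

#' Generate diverse counterfactuals that avert a positive prediction
#'
#' Seeded derivative-free coordinate-perturbation search over mutable
#' features within their admissible ranges. Each candidate is found in two
#' phases of the same objective (validity hinge plus
#' `lambda_proximity`-weighted scaled-L1 proximity, minus a diversity
#' credit): a descent phase perturbs random coordinates until the predicted
#' probability drops below the threshold, then a refinement phase greedily
#' restores changed features to their original values while the prediction
#' stays flipped, minimizing proximity. With `lambda_diversity > 0` later
#' candidates down-weight features already used by earlier ones, so
#' changed-feature sets differ across the set. With `repair = TRUE`
#' (default) every proposal is made physiologically coherent first
#' (sub-scores rederived from raw aggregates, rolling maxima floored at
#' current scores, min <= mean <= max), so emitted candidates pass the rule
#' screen by construction.
#'
#' @param model_fn Function(matrix) -> probability vector.
#' @param query A [cf_query()].
#' @param threshold Decision threshold to flip below (default 0.5).
#' @param scales Proximity scales (see [mad_scales()]).
#' @param table Score table used by repair.
#' @param budget Model-evaluation budget for the whole query (default 5000).
#' @param repair Co-mutate derived features for coherence (default TRUE).
#' @param reference_data Optional entries data.frame (or feature matrix):
#'   phase-1 proposals then copy feature values from reference rows the
#'   model predicts on the desired side, instead of sampling uniformly from
#'   the admissible ranges. Analogous to dataset-sourced counterfactual
#'   candidates in diverse-counterfactual tooling; markedly more reliable
#'   for models whose positive predictions are robust to uncoordinated
#'   perturbations.
#' @return A `cf_set`: list with `candidates` (list of `candidate`
#'   (vector), `probability`, `proximity`, `n_changed`), `diversity`, and a
#'   `diagnostic` message when no valid candidate was found. Candidates are
#'   sorted by proximity; immutable features are never changed.
#' @export
generate_counterfactuals <- function(model_fn, query, threshold = 0.5,
                                     scales = NULL, table = default_score_table(),
                                     budget = 5000L, repair = TRUE,
                                     reference_data = NULL) {
  x0 <- query$instance
  ranges <- query$feature_ranges %||% default_feature_ranges(x0, table)
  mutable <- setdiff(names(x0), query$immutable_features)
  mutable <- intersect(mutable, names(ranges))
  predict1 <- function(v) model_fn(matrix(v, 1, dimnames = list(NULL, names(v))))[[1]]
  if (predict1(x0) < threshold) {
    stopf("instance is already on the desired side of the threshold")
  }
  margin <- 0.05
  steps_per_candidate <- max(50L, budget %/% query$k)
  # reference pool: rows already on the desired side of the threshold
  ref <- NULL
  if (!is.null(reference_data)) {
    Xr <- as.matrix(as.data.frame(reference_data)[,
      intersect(names(x0), colnames(as.data.frame(reference_data))),
      drop = FALSE])
    if (!identical(colnames(Xr), names(x0))) {
      Xr <- as.matrix(as.data.frame(reference_data)[, names(x0), drop = FALSE])
    }
    neg <- model_fn(Xr) < threshold - margin
    if (any(neg)) ref <- Xr[neg, , drop = FALSE]
  }
  fix_cand <- function(cand) {
    if (repair) cand <- repair_candidate(cand, table)
    cand[query$immutable_features] <- x0[query$immutable_features]
    cand
  }
  perturb <- function(cand, feats) {
    if (!is.null(ref)) {
      row <- ref[sample.int(nrow(ref), 1), ]
      cand[feats] <- row[feats]
    } else {
      for (f in feats) {
        rg <- ranges[[f]]
        cand[[f]] <- runif(1, rg[1], rg[2])
        if (grepl("Mods$", f) || grepl("Gcs$", f)) cand[[f]] <- round(cand[[f]])
      }
    }
    fix_cand(cand)
  }
  accepted <- list()
  with_seed(query$seed, {
    for (j in seq_len(query$k)) {
      # features already used by earlier candidates; the diversity weight
      # discourages reusing them so changed-feature sets differ
      used <- unique(unlist(lapply(accepted, function(a) {
        names(x0)[abs(a$candidate - x0) > 1e-9]
      })))
      wts <- ifelse(mutable %in% used & query$lambda_diversity > 0,
                    1 / (1 + query$lambda_diversity), 1)
      # phase 1: descend on predicted probability until the prediction flips
      cur <- x0
      cur_p <- predict1(cur)
      n1 <- steps_per_candidate %/% 2L
      max_nf <- min(length(mutable), 12L)
      for (step in seq_len(n1)) {
        nf <- sample.int(max_nf, 1)
        cand <- perturb(cur, sample(mutable, nf, prob = wts))
        p <- predict1(cand)
        if (p < cur_p) { cur <- cand; cur_p <- p }
        if (cur_p < threshold - margin) break
      }
      if (cur_p >= threshold && !is.null(ref)) {
        # last resort: adopt a whole desired-side reference row
        for (t in seq_len(min(nrow(ref), 20L))) {
          cand <- fix_cand(ref[sample.int(nrow(ref), 1), ])
          p <- predict1(cand)
          if (p < cur_p) { cur <- cand; cur_p <- p }
          if (cur_p < threshold - margin) break
        }
      }
      if (cur_p >= threshold) next
      # phase 2: restore changed features toward the instance while the
      # prediction stays flipped (minimizes the scaled-L1 proximity)
      improved <- TRUE
      evals <- 0L
      while (improved && evals < steps_per_candidate %/% 2L) {
        improved <- FALSE
        changed <- names(x0)[abs(cur - x0) > 1e-9]
        gains <- abs(cur[changed] - x0[changed]) /
          (scales %||% setNames(rep(1, length(x0)), names(x0)))[changed]
        for (f in changed[order(-gains)]) {
          cand <- cur
          cand[[f]] <- x0[[f]]
          cand <- fix_cand(cand)
          p <- predict1(cand)
          evals <- evals + 1L
          if (p < threshold - margin / 2) {
            cur <- cand; cur_p <- p; improved <- TRUE
          }
          if (evals >= steps_per_candidate %/% 2L) break
        }
      }
      accepted[[length(accepted) + 1L]] <- list(
        candidate = cur, probability = cur_p,
        proximity = cf_proximity(x0, cur, scales),
        n_changed = sum(abs(cur - x0) > 1e-9))
    }
  })
  if (!length(accepted)) {
    return(structure(list(candidates = list(), diversity = NA_real_,
                          act_before_hour = x0[["currentHour"]] + 12,
                          diagnostic = "no valid counterfactual within budget"),
                     class = "cf_set"))
  }
  ord <- order(vapply(accepted, `[[`, numeric(1), "proximity"))
  accepted <- accepted[ord]
  structure(list(
    candidates = lapply(accepted, function(a) a[c("candidate", "probability",
                                                  "proximity", "n_changed")]),
    diversity = cf_diversity(lapply(accepted, `[[`, "candidate"), scales),
    act_before_hour = x0[["currentHour"]] + 12,
    diagnostic = NULL), class = "cf_set")
}

#' Rule-based second-round screening of counterfactuals
#'
#' Drops candidates violating any rule. Built-in rules: (a) every current
#' organ sub-score equals the score of its governing raw aggregate(s) under
#' the table (so e.g. a GCS minimum of 6 or less forces a neurologic
#' sub-score of 4); (b) every 24-h rolling sub-score is at least its current
#' sub-score; (c) min <= mean <= max per clinical variable. Additional
#' predicates over the feature vector may be supplied.
#'
#' @param candidates List of named feature vectors (or a `cf_set`).
#' @param table Score table for rule (a).
#' @param rules Optional list of `function(x) TRUE/FALSE` extra predicates.
#' @return The surviving candidates (same type as the input).
#' @export
rule_screen <- function(candidates, table = default_score_table(), rules = list()) {
  is_set <- inherits(candidates, "cf_set")
  vecs <- if (is_set) lapply(candidates$candidates, `[[`, "candidate") else candidates
  ok <- vapply(vecs, function(x) {
    passes_rules(x, table) && all(vapply(rules, function(r) isTRUE(r(x)), logical(1)))
  }, logical(1))
  if (is_set) {
    candidates$candidates <- candidates$candidates[ok]
    candidates
  } else {
    candidates[ok]
  }
}

passes_rules <- function(x, table) {
  derived <- derive_subscores(x, table)
  for (sub in names(organ_feature_map())) {
    if (abs(x[[sub]] - derived[[sub]]) > 1e-9) return(FALSE)
  }
  roll <- rolling_of_current()
  for (cur in names(roll)) {
    if (x[[roll[[cur]]]] < x[[cur]] - 1e-9) return(FALSE)
  }
  for (v in unname(variable_stem())) {
    mn <- paste0("currentMin", v); me <- paste0("currentMean", v)
    mx <- paste0("currentMax", v)
    if (!all(c(mn, me, mx) %in% names(x))) next
    if (x[[mn]] > x[[me]] + 1e-9 || x[[me]] > x[[mx]] + 1e-9) return(FALSE)
  }
  TRUE
}

#' Tabulate a counterfactual set against its instance
#'
#' @param cf_set A `cf_set` from [generate_counterfactuals()].
#' @param instance The original feature vector.
#' @return data.frame `candidate`, `feature`, `original`, `counterfactual`,
#'   `probability`, `proximity` — one row per changed feature.
#' @export
cf_report <- function(cf_set, instance) {
  rows <- list()
  for (i in seq_along(cf_set$candidates)) {
    c_i <- cf_set$candidates[[i]]
    changed <- names(instance)[abs(c_i$candidate - instance) > 1e-9]
    if (!length(changed)) next
    rows[[i]] <- data.frame(candidate = i, feature = changed,
                            original = unname(instance[changed]),
                            counterfactual = unname(c_i$candidate[changed]),
                            probability = c_i$probability,
                            proximity = c_i$proximity,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(candidate = integer(), feature = character(),
                      original = numeric(), counterfactual = numeric(),
                      probability = numeric(), proximity = numeric()))
  }
  do.call(rbind, rows)
}
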