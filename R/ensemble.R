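#' Built-in stacked-ensemble topologies
#'
#' `"superlearner"`: two layers, base_1..base_8 feeding one meta learner
#' whose input features are the eight base predicted probabilities.
#' `"subsuperlearner"`: three layers — base1_1,base1_2 -> meta1_1;
#' base1_3,base1_4 -> meta1_2; meta2 fed by meta1_1, meta1_2, base2_1 and
#' base2_2. Every slot's algorithm is drawn from the nine-member catalog.
#'
#' @param name `"superlearner"` or `"subsuperlearner"`.
#' @return A `stack_topology`: list with `slots` (data.frame `slot_id`,
#'   `layer`) and `inputs` (named list: meta slot -> input slot ids; base
#'   slots consume the raw features).
#' @export
build_topology <- function(name = c("superlearner", "subsuperlearner")) {
  name <- match.arg(name)
  if (name == "superlearner") {
    base <- paste0("base_", 1:8)
    slots <- data.frame(slot_id = c(base, "meta"),
                        layer = c(rep(1L, 8), 2L), stringsAsFactors = FALSE)
    inputs <- list(meta = base)
  } else {
    base <- c(paste0("base1_", 1:4), "base2_1", "base2_2")
    slots <- data.frame(
      slot_id = c(base, "meta1_1", "meta1_2", "meta2"),
      layer = c(rep(1L, 6), 2L, 2L, 3L), stringsAsFactors = FALSE)
    inputs <- list(meta1_1 = c("base1_1", "base1_2"),
                   meta1_2 = c("base1_3", "base1_4"),
                   meta2 = c("meta1_1", "meta1_2", "base2_1", "base2_2"))
  }
  structure(list(name = name, slots = slots, inputs = inputs),
            class = "stack_topology")
}

#' Size of the composition search space
#'
#' @param topology A [build_topology()] result (or anything with a `slots`
#'   data.frame).
#' @param catalog Algorithm ids (default the nine-member catalog).
#' @return `|catalog| ^ |slots|` (for both built-in topologies with the full
#'   catalog: 9^9 = 387,420,489).
#' @export
config_space_size <- function(topology, catalog = learner_catalog()) {
  length(catalog)^nrow(topology$slots)
}

#' Assemble a stacked ensemble from cached out-of-fold columns
#'
#' Meta learners are fitted layer by layer on their input slots' probability
#' columns (out-of-fold for base inputs, to avoid leakage into the metas);
#' prediction on new data runs the base models then the metas along the
#' topology.
#'
#' @param topology A `stack_topology`.
#' @param assignment Named character vector slot_id -> algorithm id covering
#'   every slot.
#' @param oof_columns Named list: algorithm id -> out-of-fold probability
#'   column on the training entries (one shared column per algorithm).
#' @param y Training labels aligned with the columns.
#' @param base_models Named list: algorithm id -> fitted full-data learner
#'   handle (used at prediction time).
#' @param weights Optional sample weights for the meta fits.
#' @param meta_seed Seed for meta-learner fitting.
#' @param meta_hyper Named list: algorithm id -> hyperparameter overrides for
#'   meta fits (e.g. a lighter DWNN schedule).
#' @return A `modsew_ensemble` handle supporting [predict_proba()].
#' @export
assemble <- function(topology, assignment, oof_columns, y, base_models = NULL,
                     weights = NULL, meta_seed = 1L, meta_hyper = list()) {
  slots <- topology$slots
  missing_slots <- setdiff(slots$slot_id, names(assignment))
  if (length(missing_slots)) stopf("assignment misses slot '%s'", missing_slots[[1]])
  base_ids <- slots$slot_id[!slots$slot_id %in% names(topology$inputs)]
  for (sl in base_ids) {
    if (is.null(oof_columns[[assignment[[sl]]]])) {
      stopf("missing cached OOF column for algorithm '%s' (slot %s)",
            assignment[[sl]], sl)
    }
  }
  # training-side columns per slot: base slots use shared per-algorithm OOF
  cols <- list()
  for (sl in base_ids) cols[[sl]] <- oof_columns[[assignment[[sl]]]]
  metas <- list()
  meta_ids <- slots$slot_id[slots$slot_id %in% names(topology$inputs)]
  meta_ids <- meta_ids[order(slots$layer[match(meta_ids, slots$slot_id)])]
  for (sl in meta_ids) {
    Xm <- do.call(cbind, cols[topology$inputs[[sl]]])
    colnames(Xm) <- topology$inputs[[sl]]
    alg <- assignment[[sl]]
    spec <- learner_spec(alg, meta_hyper[[alg]] %||% list(), seed = meta_seed)
    metas[[sl]] <- fit_learner(spec, Xm, y, weights = weights)
    cols[[sl]] <- predict_proba(metas[[sl]], Xm)
  }
  structure(list(topology = topology, assignment = assignment,
                 metas = metas, base_models = base_models,
                 terminal = meta_ids[[length(meta_ids)]]),
            class = "modsew_ensemble")
}

#' @export
predict_proba.modsew_ensemble <- function(object, X, ...) {
  if (is.null(object$base_models)) {
    stopf("ensemble was assembled without base models; cannot predict on raw features")
  }
  slots <- object$topology$slots
  base_ids <- slots$slot_id[!slots$slot_id %in% names(object$topology$inputs)]
  used <- unique(unname(object$assignment[base_ids]))
  by_alg <- lapply(setNames(used, used), function(alg) {
    predict_proba(object$base_models[[alg]], X)
  })
  ensemble_predict_cols(object, by_alg)
}

# run the meta chain given per-algorithm base probability columns
ensemble_predict_cols <- function(object, by_alg) {
  slots <- object$topology$slots
  base_ids <- slots$slot_id[!slots$slot_id %in% names(object$topology$inputs)]
  cols <- list()
  for (sl in base_ids) cols[[sl]] <- by_alg[[object$assignment[[sl]]]]
  for (sl in names(object$metas)) {
    Xm <- do.call(cbind, cols[object$topology$inputs[[sl]]])
    colnames(Xm) <- object$topology$inputs[[sl]]
    cols[[sl]] <- predict_proba(object$metas[[sl]], Xm)
  }
  cols[[object$terminal]]
}

#' Q-learning configuration
#'
#' Defaults are the published search settings: learning rate 0.1, discount
#' 0.85, exploration probability 0.9 (held fixed; a linear decay to 0.05 is
#' available), 5000 episodes.
#'
#' @param alpha Learning rate in (0,1].
#' @param gamma Discount in \[0,1).
#' @param epsilon Exploration probability in \[0,1\].
#' @param episodes Training episodes.
#' @param seed Integer seed.
#' @param epsilon_decay Linearly decay epsilon to 0.05 over the run
#'   (default FALSE).
#' @param reward_subsample Optional entry count used by reward evaluation in
#'   [compose_stack()].
#' @return A `qlearn_config`.
#' @export
qlearn_config <- function(alpha = 0.1, gamma = 0.85, epsilon = 0.9,
                          episodes = 5000L, seed = 1L, epsilon_decay = FALSE,
                          reward_subsample = NULL) {
  if (alpha <= 0 || alpha > 1) stopf("invalid qlearn config: alpha must be in (0,1]")
  if (gamma < 0 || gamma >= 1) stopf("invalid qlearn config: gamma must be in [0,1)")
  if (epsilon < 0 || epsilon > 1) stopf("invalid qlearn config: epsilon must be in [0,1]")
  if (episodes < 1) stopf("invalid qlearn config: episodes must be >= 1")
  structure(list(alpha = alpha, gamma = gamma, epsilon = epsilon,
                 episodes = as.integer(episodes), seed = as.integer(seed),
                 epsilon_decay = isTRUE(epsilon_decay),
                 reward_subsample = reward_subsample),
            class = "qlearn_config")
}

#' Per-row argmax readout of a Q-table
#'
#' @param qtable Matrix, rows = slots, columns = catalog algorithms.
#' @return Named character vector slot_id -> algorithm; ties broken by the
#'   lowest catalog index.
#' @export
readout <- function(qtable) {
  if (!all(is.finite(qtable))) stopf("Q-table must be finite")
  setNames(colnames(qtable)[apply(qtable, 1, which.max)], rownames(qtable))
}

#' Compose a stacked ensemble by tabular Q-learning
#'
#' States are the slot indices (matching the published slot-by-algorithm
#' Q-table), actions are catalog algorithms. Each episode fills the slots
#' sequentially with an epsilon-greedy choice and receives the terminal
#' reward `reward_fn(assignment)` (intermediate rewards are 0); rewards are
#' memoized per assignment — the search therefore sees a deterministic
#' reward — so the number of `reward_fn` calls is bounded by the number of
#' distinct assignments visited.
#'
#' Because the state deliberately omits the already-chosen prefix (the
#' published artifact is exactly a slots-by-algorithms table), a plain
#' expectation-tracking TD update cannot assign credit to any slot but the
#' last. The default `update = "optimistic"` therefore applies
#' `Q(s_i, a_i) <- Q + alpha (gamma^(S-i) r - Q)` only when the discounted
#' episode return exceeds the current estimate: with deterministic rewards
#' each entry converges from below to the best discounted return achievable
#' with that slot-action, and the per-row argmax readout coincides with the
#' exhaustive-search argmax. `update = "td"` keeps the literal terminal-only
#' rule `Q(s,a) <- Q(s,a) + alpha (r + gamma max Q(s',.) - Q(s,a))` for
#' reference. Either way all entries stay within \[0, 1\] for rewards in
#' \[0, 1\] and gamma < 1.
#'
#' @param topology A `stack_topology`.
#' @param catalog Algorithm ids (Q-table column order).
#' @param reward_fn Function(assignment) -> reward in \[0,1\].
#' @param qcfg A [qlearn_config()].
#' @param update `"optimistic"` (default) or `"td"`, see Details.
#' @return List `qtable` (slots x catalog), `assignment` (argmax readout),
#'   `n_reward_calls`, `best_reward` (largest memoized reward).
#' @export
qlearn_compose <- function(topology, catalog, reward_fn, qcfg = qlearn_config(),
                           update = c("optimistic", "td")) {
  update <- match.arg(update)
  stopifnot(inherits(qcfg, "qlearn_config"))
  slots <- topology$slots$slot_id
  S <- length(slots); A <- length(catalog)
  Q <- matrix(0, S, A, dimnames = list(slots, catalog))
  memo <- new.env(parent = emptyenv())
  n_calls <- 0L
  with_seed(qcfg$seed, {
    for (ep in seq_len(qcfg$episodes)) {
      eps <- if (qcfg$epsilon_decay) {
        qcfg$epsilon + (0.05 - qcfg$epsilon) * (ep - 1) / max(qcfg$episodes - 1, 1)
      } else qcfg$epsilon
      acts <- integer(S)
      for (i in seq_len(S)) {
        acts[i] <- if (runif(1) < eps) sample.int(A, 1) else which.max(Q[i, ])
      }
      key <- paste(acts, collapse = ",")
      r <- memo[[key]]
      if (is.null(r)) {
        r <- reward_fn(setNames(catalog[acts], slots))
        n_calls <- n_calls + 1L
        memo[[key]] <- r
      }
      for (i in seq_len(S)) {
        if (update == "optimistic") {
          target <- qcfg$gamma^(S - i) * r
          if (target > Q[i, acts[i]]) {
            Q[i, acts[i]] <- Q[i, acts[i]] + qcfg$alpha * (target - Q[i, acts[i]])
          }
        } else {
          target <- if (i < S) qcfg$gamma * max(Q[i + 1, ]) else r
          Q[i, acts[i]] <- Q[i, acts[i]] + qcfg$alpha * (target - Q[i, acts[i]])
        }
      }
    }
  })
  list(qtable = Q, assignment = readout(Q), n_reward_calls = n_calls,
       best_reward = if (n_calls) max(unlist(as.list(memo))) else NA_real_)
}

#' End-to-end stacked-ensemble composition on an entries table
#'
#' Splits entries by patient, computes one out-of-fold column and one
#' fitted full-data model per catalog algorithm on the training side (so
#' total base fits stay bounded by the catalog size regardless of episode
#' count), then runs [qlearn_compose()] with reward = validation AUC
#' (Youden index or utility score selectable) of the assembled candidate.
#'
#' @param entries Normalized entries data.frame (see [featurize_cohort()]).
#' @param topology A `stack_topology`.
#' @param catalog Algorithm ids.
#' @param qcfg A [qlearn_config()]; `reward_subsample` caps the number of
#'   training entries used (the published run subsampled its training pool
#'   for reward evaluation).
#' @param reward `"auc"` (default), `"yi"` or `"utility"`.
#' @param truth Truth table (needed for `reward = "utility"`).
#' @param base_hyper,meta_hyper Per-algorithm hyperparameter overrides.
#' @param use_class_weights Apply inverse-frequency class weights
#'   (default TRUE).
#' @param stacking `"oof"` (default: metas are trained on out-of-fold base
#'   columns, avoiding leakage) or `"refit"` (the stacking-tool default the
#'   original study used: metas trained on the base models' in-sample
#'   predictions — viable at database scale but prone to leakage-driven
#'   meta overfit on desk-scale cohorts).
#' @return List with `qtable`, `assignment`, `ensemble` (refit on the full
#'   training side), `val_auc`, `base_val_auc` (per-algorithm single-model
#'   validation AUCs), plus the `train`/`validation` split.
#' @export
compose_stack <- function(entries, topology = build_topology("superlearner"),
                          catalog = learner_catalog(),
                          qcfg = qlearn_config(), reward = c("auc", "yi", "utility"),
                          truth = NULL, base_hyper = list(), meta_hyper = list(),
                          use_class_weights = TRUE,
                          stacking = c("oof", "refit")) {
  reward <- match.arg(reward)
  stacking <- match.arg(stacking)
  sp <- split_by_patient(entries, 0.8, seed = child_seed(qcfg$seed, 11L))
  train <- sp$train
  if (!is.null(qcfg$reward_subsample) && nrow(train) > qcfg$reward_subsample) {
    keep <- with_seed(child_seed(qcfg$seed, 12L),
                      sample.int(nrow(train), qcfg$reward_subsample))
    train <- train[sort(keep), , drop = FALSE]
  }
  val <- sp$validation
  feats <- feature_names()
  Xtr <- as.matrix(train[, feats]); ytr <- train$label
  Xva <- as.matrix(val[, feats]); yva <- val$label
  w <- if (use_class_weights) unname(class_weights(ytr)[as.character(ytr)]) else NULL

  oof_cols <- list(); base_models <- list(); base_val <- list()
  for (alg in catalog) {
    spec <- learner_spec(alg, base_hyper[[alg]] %||% list(),
                         seed = child_seed(qcfg$seed, 13L))
    base_models[[alg]] <- fit_learner(spec, Xtr, ytr, weights = w)
    oof_cols[[alg]] <- if (stacking == "oof") {
      oof_predictions(spec, Xtr, ytr, k = 5L,
                      seed = child_seed(qcfg$seed, 14L),
                      groups = train$patient_id, weights = w)
    } else {
      predict_proba(base_models[[alg]], Xtr)
    }
    base_val[[alg]] <- auc(yva, predict_proba(base_models[[alg]], Xva))
  }

  # validation-side base columns are assignment-independent: cache them once
  val_cols <- lapply(base_models, function(bm) predict_proba(bm, Xva))

  reward_fn <- function(assignment) {
    ens <- assemble(topology, assignment, oof_cols, ytr,
                    base_models = base_models, weights = w,
                    meta_seed = child_seed(qcfg$seed, 15L),
                    meta_hyper = meta_hyper)
    pv <- ensemble_predict_cols(ens, val_cols)
    switch(reward,
           auc = auc(yva, pv),
           yi = max(binary_metrics(yva, pv)$yi, 0),
           utility = {
             pred <- data.frame(patient_id = val$patient_id, hour = val$hour,
                                probability = pv)
             max(utility_score(per_patient_alarms(pred, truth)), 0)
           })
  }
  qres <- qlearn_compose(topology, catalog, reward_fn, qcfg)
  ens <- assemble(topology, qres$assignment, oof_cols, ytr,
                  base_models = base_models, weights = w,
                  meta_seed = child_seed(qcfg$seed, 15L),
                  meta_hyper = meta_hyper)
  list(qtable = qres$qtable, assignment = qres$assignment, ensemble = ens,
       n_reward_calls = qres$n_reward_calls, best_reward = qres$best_reward,
       val_auc = auc(yva, predict_proba(ens, Xva)),
       base_val_auc = unlist(base_val), train = train, validation = val)
}

#' Export a Q-table as CSV (rows = slots, columns = algorithms)
#' @param qtable Q-table matrix.
#' @param path Output path.
#' @export
write_qtable <- function(qtable, path) {
  df <- data.frame(slot = rownames(qtable), qtable, check.names = FALSE)
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}
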