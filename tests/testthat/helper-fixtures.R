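# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; no data files.

.fixture_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# 40-patient synthetic cohort with entries (raw and normalized)
fx_cohort <- function() {
  fixture("cohort", function() {
    cohort <- simulate_cohort(sim_config(40, mean_los_hours = 60, seed = 3))
    entries <- featurize_cohort(filter_cohort(cohort)$included)
    norm <- fit_normalizer(entries)
    list(cohort = cohort, entries = entries, norm = norm,
         entries_norm = apply_normalizer(entries, norm))
  })
}

# quick 2-feature linearly separable classification set
fx_separable <- function(n = 500, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
    y <- as.integer(X[, 1] + X[, 2] + rnorm(n, 0, 0.3) > 0)
    list(X = X, y = y)
  })
}

# boosted-tree risk model over the cohort entries, reused by SHAP and
# counterfactual tests
fx_risk_model <- function() {
  fixture("risk_model", function() {
    fx <- fx_cohort()
    X <- as.matrix(fx$entries[, feature_names()])
    y <- fx$entries$label
    w <- unname(class_weights(y)[as.character(y)])
    fit <- fit_learner(learner_spec("gradient_boosting_xgb", seed = 1), X, y, w)
    list(fit = fit, model_fn = function(M) predict_proba(fit, M),
         X = X, y = y, entries = fx$entries)
  })
}

# random organ-score sequence for detect_mods property tests
random_score_matrix <- function(n_hours, p_sick = 0.15) {
  matrix(sample(0:4, n_hours * 6, replace = TRUE,
                prob = c(1 - p_sick, rep(p_sick / 4, 4))),
         n_hours, 6, dimnames = list(NULL, organ_systems()))
}
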