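test_that("proximity is a scaled L1 over shared features", {
  x <- c(a = 1, b = 2, c = 3)
  expect_equal(cf_proximity(x, x), 0)
  cf <- c(a = 2, b = 2, c = 1)
  scales <- c(a = 1, b = 1, c = 2)
  expect_equal(cf_proximity(x, cf, scales), 1 + 0 + 1)  # one MAD each -> 2
  expect_equal(cf_proximity(x, cf, scales), cf_proximity(cf, x, scales))
  expect_error(cf_proximity(x, c(a = 1, z = 2, c = 3)), "mismatch")
  # zero-scale features fall back to 1
  expect_equal(cf_proximity(x, cf, c(a = 0, b = 1, c = 2)), 2)
})

test_that("diversity is the determinant of the proximity kernel", {
  x1 <- c(a = 0, b = 0)
  expect_equal(cf_diversity(list(x1)), 1)               # 1x1 kernel
  expect_equal(cf_diversity(list(x1, x1)), 0)           # duplicate -> singular
  x2 <- c(a = 1, b = 0)                                 # proximity 1 apart
  expect_equal(cf_diversity(list(x1, x2)), 1 - 0.25)    # det of [[1,.5],[.5,1]]
  expect_error(cf_diversity(list()), "at least one")
})

test_that("generated counterfactuals flip, preserve immutables, pass rules", {
  rm <- fx_risk_model()
  pv <- rm$model_fn(rm$X)
  x <- unlist(rm$entries[which.max(pv), feature_names()])
  scales <- mad_scales(rm$entries)
  q <- cf_query(x, k = 3, seed = 4)
  cfs <- generate_counterfactuals(rm$model_fn, q, scales = scales,
                                  budget = 2000, reference_data = rm$entries)
  expect_s3_class(cfs, "cf_set")
  expect_gte(length(cfs$candidates), 2L)
  prox <- vapply(cfs$candidates, `[[`, numeric(1), "proximity")
  expect_identical(order(prox), seq_along(prox))        # sorted by proximity
  for (cc in cfs$candidates) {
    expect_lt(cc$probability, 0.5)                      # validity
    expect_identical(cc$candidate[["currentHour"]], x[["currentHour"]])
    expect_true(modsew:::passes_rules(cc$candidate, default_score_table()))
  }
  # repair makes the screen a no-op on emitted candidates
  expect_length(rule_screen(cfs)$candidates, length(cfs$candidates))
  # diversity: the emitted set beats a duplicated single candidate (det 0)
  if (length(cfs$candidates) >= 2) expect_gt(cfs$diversity, 0)
  # determinism
  cfs2 <- generate_counterfactuals(rm$model_fn, q, scales = scales,
                                   budget = 2000, reference_data = rm$entries)
  expect_identical(cfs2$candidates[[1]]$candidate, cfs$candidates[[1]]$candidate)
  # act-before field surfaces the warning horizon
  expect_equal(cfs$act_before_hour, x[["currentHour"]] + 12, ignore_attr = TRUE)
  # a negative instance is rejected
  xneg <- unlist(rm$entries[which.min(pv), feature_names()])
  expect_error(generate_counterfactuals(rm$model_fn, cf_query(xneg, seed = 1)),
               "already on the desired side")
})

test_that("the rule screen drops inconsistent candidates", {
  x <- unlist(fx_cohort()$entries[1, feature_names()])
  tb <- default_score_table()
  ok <- modsew:::repair_candidate(x, tb)
  expect_length(rule_screen(list(ok)), 1L)

  # rule (a): sub-score contradicting its governing aggregate
  bad_a <- ok
  bad_a[["currentMinGcs"]] <- 5        # forces a neurologic sub-score of 4
  bad_a[["currentGcsMods"]] <- 2
  bad_a[["currentMeanGcs"]] <- 5; bad_a[["currentMaxGcs"]] <- 6
  bad_a[["gcs24HoursMods"]] <- 4
  expect_length(rule_screen(list(bad_a)), 0L)

  # rule (b): rolling sub-score below the current one
  bad_b <- ok
  bad_b[["gcs24HoursMods"]] <- max(0, ok[["currentGcsMods"]] - 1)
  if (ok[["currentGcsMods"]] > 0) expect_length(rule_screen(list(bad_b)), 0L)

  # rule (c): aggregate ordering violated
  bad_c <- ok
  bad_c[["currentMinHr"]] <- bad_c[["currentMaxHr"]] + 10
  expect_length(rule_screen(list(bad_c)), 0L)

  # custom predicates participate in the screen
  expect_length(rule_screen(list(ok), rules = list(function(z) FALSE)), 0L)
})

test_that("screen soundness: screened sub-scores re-derive exactly", {
  tb <- default_score_table()
  fx <- fx_cohort()
  rows <- withr::with_seed(3, sample(nrow(fx$entries), 20))
  cands <- lapply(rows, function(i) {
    modsew:::repair_candidate(unlist(fx$entries[i, feature_names()]), tb)
  })
  kept <- rule_screen(cands, tb)
  expect_length(kept, length(cands))
  for (cand in kept) {
    re <- modsew:::derive_subscores(cand, tb)
    for (sub in names(modsew:::organ_feature_map())) {
      expect_identical(cand[[sub]], re[[sub]])
    }
  }
})

test_that("cf_report tabulates changed features per candidate", {
  x <- c(setNames(rep(1, 37), feature_names()))
  cand <- x; cand[["currentMinGcs"]] <- 15; cand[["currentGcsMods"]] <- 0
  cfs <- structure(list(candidates = list(list(candidate = cand,
                                               probability = 0.1,
                                               proximity = 2,
                                               n_changed = 2)),
                        diversity = 1), class = "cf_set")
  rep <- cf_report(cfs, x)
  expect_setequal(rep$feature, c("currentMinGcs", "currentGcsMods"))
  expect_identical(rep$probability, rep(0.1, 2))
})
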