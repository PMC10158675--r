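test_that("score_variable matches the default band table", {
  tb <- default_score_table()
  # spot checks across bands and directions
  cases <- list(
    list("gcs", 15, 0), list("gcs", 3, 4), list("gcs", 13, 1),
    list("gcs", 10, 2), list("gcs", 7, 3), list("gcs", 6, 4),
    list("creatinine", 90, 0), list("creatinine", 100, 0),
    list("creatinine", 150, 1), list("creatinine", 501, 4),
    list("oxygenation_index", 250, 1), list("oxygenation_index", 75, 4),
    list("oxygenation_index", 301, 0),
    list("platelets", 120, 1), list("platelets", 121, 0), list("platelets", 20, 4),
    list("dopamine", 0, 0), list("dopamine", 5, 1), list("dopamine", 16, 4),
    list("lactate", 2, 0), list("lactate", 3.6, 2), list("lactate", 9, 4),
    list("heart_rate", 100, 0), list("heart_rate", 161, 4),
    list("bilirubin", 20, 0), list("bilirubin", 61, 2))
  for (cs in cases) {
    expect_identical(score_variable(cs[[2]], cs[[1]], tb), as.integer(cs[[3]]),
                     label = sprintf("%s=%s", cs[[1]], cs[[2]]))
  }
  expect_error(score_variable(1, "troponin", tb), "unknown")
  expect_error(score_variable(NaN, "gcs", tb), "non-finite")
})

test_that("score_variable is monotone along the severity direction", {
  tb <- default_score_table()
  withr::with_seed(11, {
    for (v in names(tb)) {
      lo <- if (tb[[v]]$direction == "higher") 0 else 1
      hi <- max(tb[[v]]$cuts) * 2 + 20
      vals <- sort(runif(200, lo, hi))
      sc <- score_variable(vals, v, tb)
      if (tb[[v]]$direction == "higher") {
        expect_true(all(diff(sc) >= 0), label = v)
      } else {
        expect_true(all(diff(sc) <= 0), label = v)
      }
      expect_true(all(sc >= 0 & sc <= 4), label = v)
    }
  })
})

test_that("organ_scores applies the cardiovascular max-rule and single maps", {
  tb <- default_score_table()
  agg <- list(max_dopamine = 3, max_lactate = 1.5, max_heart_rate = 130,
              min_oxygenation_index = 250, max_creatinine = 90, min_gcs = 15,
              max_bilirubin = 10, min_platelets = 250)
  os <- organ_scores(agg, tb)
  # dopamine->1, lactate->0, HR->2: cardiovascular = max = 2
  expect_identical(unname(os[["cardiovascular"]]), 2L)
  expect_identical(unname(os[["respiratory"]]), 1L)  # OI 250 in 226-300 band
  expect_identical(unname(os[["renal"]]), 0L)
  # all healthy -> all zero
  healthy <- list(max_dopamine = 0, max_lactate = 1, max_heart_rate = 80,
                  min_oxygenation_index = 400, max_creatinine = 80,
                  min_gcs = 15, max_bilirubin = 10, min_platelets = 250)
  expect_true(all(organ_scores(healthy, tb) == 0L))
  expect_error(organ_scores(healthy[-1], tb), "max_dopamine")
})

test_that("organ_scores never decreases when one input worsens a band", {
  tb <- default_score_table()
  base <- list(max_dopamine = 3, max_lactate = 2.5, max_heart_rate = 110,
               min_oxygenation_index = 200, max_creatinine = 150, min_gcs = 12,
               max_bilirubin = 70, min_platelets = 90)
  os0 <- organ_scores(base, tb)
  worse <- list(max_dopamine = 7, max_lactate = 4, max_heart_rate = 130,
                min_oxygenation_index = 120, max_creatinine = 250, min_gcs = 8,
                max_bilirubin = 150, min_platelets = 40)
  for (nm in names(worse)) {
    agg <- base
    agg[[nm]] <- worse[[nm]]
    expect_true(all(organ_scores(agg, tb) >= os0), label = nm)
  }
})

test_that("detect_mods equals a brute-force scan on random sequences", {
  brute <- function(m, thr = 2L, need = 2L) {
    for (h in seq_len(nrow(m))) {
      if (sum(m[h, ] >= thr) >= need) return(h)
    }
    NA_integer_
  }
  withr::with_seed(21, {
    for (rep in 1:1000) {
      m <- random_score_matrix(sample(1:60, 1))
      expect_identical(detect_mods(m), as.integer(brute(m)))
    }
  })
})

test_that("detect_mods honours the criterion and rejects bad input", {
  m <- matrix(0L, 10, 6, dimnames = list(NULL, organ_systems()))
  expect_identical(detect_mods(m), NA_integer_)            # all-zero
  m2 <- m; m2[, 1] <- 4L
  expect_identical(detect_mods(m2), NA_integer_)           # one organ only
  expect_identical(detect_mods(m2, organs_required = 1L), 1L)
  m3 <- m; m3[5:10, 1:2] <- 2L
  expect_identical(detect_mods(m3), 5L)
  expect_identical(detect_mods(m3, dysfunction_threshold = 3L), NA_integer_)
  expect_error(detect_mods(m[0, , drop = FALSE]), "non-empty")
})

test_that("score tables round-trip through JSON and validate", {
  tb <- default_score_table()
  path <- withr::local_tempfile(fileext = ".json")
  write_score_table(tb, path)
  tb2 <- read_score_table(path)
  for (v in names(tb)) {
    expect_identical(tb2[[v]]$cuts, tb[[v]]$cuts)
    expect_identical(tb2[[v]]$direction, tb[[v]]$direction)
  }
  bad <- unclass(tb)
  bad$gcs$cuts <- c(14, 12, 12, 6)
  expect_error(modsew:::validate_score_table(bad), "strictly ordered")
})
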