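test_that("impute_clinical applies forward-then-backward fill", {
  expect_identical(impute_clinical(c(NA, 7, NA)), c(7, 7, 7))
  expect_identical(impute_clinical(c(1, NA, 3)), c(1, 1, 3))   # ffill precedence
  expect_identical(impute_clinical(c(NA_real_, NA, NA)), c(NA_real_, NA, NA))
})

test_that("feature schema has exactly 37 stable names on every entry", {
  fx <- fx_cohort()
  expect_length(feature_names(), 37L)
  expect_identical(anyDuplicated(feature_names()), 0L)
  expect_identical(colnames(fx$entries), c("patient_id", "hour", "label",
                                           feature_names()))
  expect_false(anyNA(fx$entries[, feature_names()]))
  # min <= mean <= max for every variable on every entry
  for (v in c("Hr", "Gcs", "Creatinine", "Platelet")) {
    expect_true(all(fx$entries[[paste0("currentMin", v)]] <=
                      fx$entries[[paste0("currentMean", v)]] + 1e-9))
    expect_true(all(fx$entries[[paste0("currentMean", v)]] <=
                      fx$entries[[paste0("currentMax", v)]] + 1e-9))
  }
})

test_that("extract_features returns the matching single-hour vector", {
  stay <- fx_cohort()$cohort$stays[[1]]
  fv <- extract_features(stay, 5L)
  expect_length(fv, 37L)
  expect_identical(names(fv), feature_names())
  expect_identical(unname(fv[["currentHour"]]), 5)
  expect_error(extract_features(stay, 10000L), "outside")
})

test_that("rolling sub-scores are the trailing 24-window running max", {
  fx <- fx_cohort()
  roll_names <- grep("24HoursMods$", feature_names(), value = TRUE)
  cur_names <- grep("^current.*Mods$", feature_names(), value = TRUE)
  by_pat <- split(fx$entries, fx$entries$patient_id)
  for (d in by_pat[1:10]) {
    d <- d[order(d$hour), ]
    for (j in seq_along(cur_names)) {
      cur <- d[[cur_names[j]]]
      roll <- d[[roll_names[j]]]
      brute <- vapply(seq_along(cur), function(h) {
        max(cur[max(1, h - 23):h])
      }, numeric(1))
      expect_identical(roll, brute)
    }
  }
  # hour 1 rolling equals current; rolling never below current
  h1 <- fx$entries[fx$entries$hour == 1, ]
  expect_identical(as.matrix(h1[, roll_names]) * 1, as.matrix(h1[, cur_names]) * 1,
                   ignore_attr = TRUE)
  expect_true(all(fx$entries[, roll_names] >= fx$entries[, cur_names]))
})

test_that("labels follow the 12-h look-ahead horizon", {
  # positive entry at hour 60 for onset at 72; negative far from onset
  expect_identical(label_entries(60L, 72L), 1L)
  expect_identical(label_entries(229L, NA_integer_), 0L)
  expect_identical(label_entries(60L, 100L), 0L)
  expect_identical(label_entries(59L, 72L), 0L)       # horizon boundary
  expect_identical(label_entries(80L, 72L), 1L)       # post-onset positive
  expect_identical(label_entries(80L, 72L, truncate_at_onset = TRUE), NA_integer_)
  expect_error(label_entries(1L, 5L, horizon = 0L), "horizon")

  # earliest positive entry of every synthetic stay is at max(1, onset - 12)
  fx <- fx_cohort()
  truth <- fx$cohort$truth
  for (id in truth$patient_id[!is.na(truth$onset_hour)]) {
    d <- fx$entries[fx$entries$patient_id == id, ]
    if (!nrow(d)) next
    onset <- truth$onset_hour[truth$patient_id == id]
    expect_identical(min(d$hour[d$label == 1]), max(1L, onset - 12L), label = id)
  }
})

test_that("cohort filtering logs one reason per excluded stay", {
  mk_stay <- function(id, age, los, first = TRUE, vars = clinical_variables()) {
    obs <- do.call(rbind, lapply(vars, function(v) {
      data.frame(time_offset = seq(0.5, los - 0.5, by = 1), variable = v,
                 value = 10)
    }))
    structure(list(patient_id = id, age = age, first_icu_stay = first,
                   los_hours = los, observations = obs,
                   true_onset = NA_integer_), class = "icu_stay")
  }
  cohort <- structure(list(stays = list(
    ok = mk_stay("ok", 70, 48),
    young = mk_stay("young", 64, 48),
    short = mk_stay("short", 70, 20),
    gappy = mk_stay("gappy", 70, 48, vars = clinical_variables()[1:5]),
    readmit = mk_stay("readmit", 70, 48, first = FALSE)),
    truth = data.frame(patient_id = c("ok", "young", "short", "gappy", "readmit"),
                       onset_hour = NA_integer_)), class = "icu_cohort")
  res <- filter_cohort(cohort)
  expect_identical(names(res$included$stays), "ok")
  excl <- setNames(res$exclusions$reason, res$exclusions$patient_id)
  expect_identical(unname(excl[["young"]]), "age")
  expect_identical(unname(excl[["short"]]), "length of stay")
  expect_identical(unname(excl[["gappy"]]), "missingness")  # 3/8 = 0.375 >= 0.3
  expect_identical(unname(excl[["readmit"]]), "readmission")
})

test_that("normalization is a train-fitted z-score with sigma-zero passthrough", {
  fx <- fx_cohort()
  normed <- fx$entries_norm
  mus <- colMeans(as.matrix(normed[, feature_names()]))
  sds <- apply(as.matrix(normed[, feature_names()]), 2,
               function(c) sqrt(mean((c - mean(c))^2)))
  expect_true(all(abs(mus) < 1e-9))
  nonconst <- fx$norm$sigma > 0
  expect_true(all(abs(sds[nonconst] - 1) < 1e-9))

  # sigma = 0 feature passes through centred only
  ent <- fx$entries[1:50, ]
  ent$currentMeanHr <- 42
  nr <- fit_normalizer(ent)
  out <- apply_normalizer(ent, nr)
  expect_true(all(out$currentMeanHr == 0))

  # features shifted by +c normalize to mean c / sigma
  shift <- fx$entries
  shift$currentMeanHr <- shift$currentMeanHr + 5
  out2 <- apply_normalizer(shift, fx$norm)
  expect_equal(mean(out2$currentMeanHr),
               5 / fx$norm$sigma[["currentMeanHr"]], tolerance = 1e-9)

  bad <- fx$entries
  names(bad)[names(bad) == "currentMeanHr"] <- "meanHeart"
  expect_error(apply_normalizer(bad, fx$norm), "mismatch")

  # JSON round-trip
  path <- withr::local_tempfile(fileext = ".json")
  write_normalizer(fx$norm, path)
  back <- read_normalizer(path)
  expect_equal(back$mu, fx$norm$mu, tolerance = 1e-12)
  expect_equal(back$sigma, fx$norm$sigma, tolerance = 1e-12)
})

test_that("patient-level split is leak-free, sized, and deterministic", {
  fx <- fx_cohort()
  sp <- split_by_patient(fx$entries, 0.8, seed = 1)
  tr_ids <- unique(sp$train$patient_id)
  va_ids <- unique(sp$validation$patient_id)
  expect_length(intersect(tr_ids, va_ids), 0)
  n <- length(unique(fx$entries$patient_id))
  expect_identical(length(tr_ids), as.integer(round(0.8 * n)))
  sp2 <- split_by_patient(fx$entries, 0.8, seed = 1)
  expect_identical(sp2$train$patient_id, sp$train$patient_id)

  ten <- fx$entries[fx$entries$patient_id %in%
                      unique(fx$entries$patient_id)[1:10], ]
  sp10 <- split_by_patient(ten, 0.8, seed = 1)
  expect_length(unique(sp10$train$patient_id), 8)
  expect_length(unique(sp10$validation$patient_id), 2)
  one <- fx$entries[fx$entries$patient_id == fx$entries$patient_id[1], ]
  expect_error(split_by_patient(one), "at least 2")
})
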