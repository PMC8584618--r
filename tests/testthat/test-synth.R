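test_that("score categorizers reproduce the clinical bins", {
  # FINDRISK: every bin boundary and its 10-year risk percentage
  cases <- data.frame(
    score = c(0, 6, 7, 11, 12, 13, 14, 15, 20, 21, 26),
    label = c("low risk", "low risk", "slightly increased",
              "slightly increased", "medium risk", "medium risk",
              "medium risk", "high risk", "high risk", "very high",
              "very high"),
    pct = c(1, 1, 4, 4, 17, 17, 17, 33, 33, 50, 50))
  got <- categorize_risk(cases$score)
  expect_equal(as.character(got$label), cases$label)
  expect_equal(got$risk_percent, cases$pct)
  expect_error(categorize_risk(-1), "non-negative")

  # TDI: anosmia < 16.5 <= hyposmia <= 30.5 < normosmia
  expect_equal(categorize_tdi(c(1, 16, 16.5, 25, 30.5, 31, 48)),
               c("anosmia", "anosmia", "hyposmia", "hyposmia", "hyposmia",
                 "normosmia", "normosmia"))
  expect_error(categorize_tdi(0), "\\[1, 48\\]")
  expect_error(categorize_tdi(49), "\\[1, 48\\]")
})

test_that("category map invariants hold", {
  map <- default_category_map()
  expect_true(all(diff(map$risk_bins$risk_percent) > 0))
  # bins tile the score range without gap or overlap
  expect_equal(map$risk_bins$lower[-1], map$risk_bins$upper[-5])
  expect_equal(map$tdi_bins$lower[-1], map$tdi_bins$upper[-3])
})

test_that("generator is deterministic and respects structural invariants", {
  cfg <- generator_config(n = 120, seed = 42)
  ct1 <- generate_cohort(cfg)
  ct2 <- generate_cohort(cfg)
  expect_identical(ct1, ct2)

  d <- ct1$data
  cc <- complete.cases(d[, c("threshold", "discrimination", "identification", "tdi")])
  expect_true(all(abs(d$threshold + d$discrimination + d$identification -
                        d$tdi)[cc] < 1e-9))
  expect_true(all(d$tdi >= 1 & d$tdi <= 48))
  expect_true(all(d$findrisk >= 0 & d$findrisk == round(d$findrisk)))
  metab_roles <- ct1$roles[ct1$roles %in% c("metabolomic_baseline",
                                            "metabolomic_delta")]
  expect_length(metab_roles, 15)
  expect_equal(sum(metab_roles == "metabolomic_baseline"), 10)
  expect_equal(sum(is.na(d)), cfg$n_missing)
})

test_that("empty and invalid configurations are handled", {
  ct <- generate_cohort(generator_config(n = 0))
  expect_equal(nrow(ct$data), 0)
  expect_true(all(names(ct$roles) %in% names(ct$data)))
  expect_error(generator_config(tdi_mixture = list(means = c(0, 1),
                                                   sds = c(1, 1),
                                                   weights = c(0.9, 0.4))),
               "sum to 1")
  expect_error(generator_config(tdi_mixture = list(means = c(0, 1),
                                                   sds = c(1, -1),
                                                   weights = c(0.5, 0.5))),
               "positive")
})

test_that("lower TDI mode is occupied at the configured weight", {
  # long-run mode-1 fraction ~ 0.167 across seeds (binomial tolerance)
  fr <- vapply(1:50, function(s) {
    mean(generate_cohort(generator_config(seed = s))$truth$mode == 1)
  }, numeric(1))
  w1 <- 0.167 / (0.167 + 0.83)
  expect_lt(abs(mean(fr) - w1), 3 * sqrt(w1 * (1 - w1) / (163 * 50)))
})

test_that("null configuration leaves TDI independent of the risk score", {
  ct <- generate_cohort(generator_config(n = 10000, seed = 3,
                                         n_missing = 0, n_outliers = 0))
  expect_lt(abs(cor(ct$data$tdi, ct$data$findrisk)), 0.05)
})

test_that("TDI modes are independent of metabolomics clusters under the null", {
  pvals <- vapply(1:100, function(s) {
    ct <- generate_cohort(generator_config(seed = s, n_missing = 0,
                                           n_outliers = 0))
    suppressWarnings(chisq.test(table(ct$truth$mode, ct$truth$cluster))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.90)
})

test_that("injected outliers exceed the configured z magnitude", {
  cfg <- generator_config(seed = 11, outlier_magnitude = 6)
  clean <- generate_cohort(generator_config(seed = 11, n_outliers = 0,
                                            n_missing = 0))
  ct <- generate_cohort(cfg)
  oc <- ct$truth$outlier_cells
  expect_equal(nrow(oc), cfg$n_outliers)
  for (j in seq_len(nrow(oc))) {
    v <- clean$data[[oc$column[j]]]
    z <- abs(ct$data[oc$row[j], oc$column[j]] - mean(v)) / sd(v)
    expect_gt(z, 6 * 0.9)  # injected on pre-injection moments
  }
})

test_that("cohort CSV + manifest round-trips", {
  ct <- generate_cohort(generator_config(n = 25, seed = 5))
  prefix <- file.path(withr::local_tempdir(), "cohort")
  write_cohort(ct, prefix)
  back <- read_cohort(prefix)
  expect_equal(back$roles[names(ct$roles)], ct$roles)
  expect_equal(back$data$tdi, ct$data$tdi, tolerance = 1e-12)
  expect_equal(sum(is.na(back$data)), sum(is.na(ct$data)))
})

test_that("implanted olfaction association induces a TDI-risk correlation", {
  ct <- generate_cohort(generator_config(n = 2000, seed = 9,
                                         olfaction_association = TRUE,
                                         n_missing = 0, n_outliers = 0))
  expect_lt(cor(ct$data$tdi, ct$data$findrisk), -0.2)
})
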