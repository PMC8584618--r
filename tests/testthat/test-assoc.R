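test_that("chi-squared crosstab reproduces hand-computed statistics", {
  # 2x2 with expected counts all 15: chi2 = 4 * (5^2/15) = 20/3
  a <- rep(c("x", "y"), c(30, 30))
  b <- c(rep(c("p", "q"), c(10, 20)), rep(c("p", "q"), c(20, 10)))
  res <- crosstab_chi2(a, b)
  expect_equal(res$chi2, 20 / 3, tolerance = 1e-3)
  expect_equal(res$df, 1)

  # residual-sum identity: sum of squared Pearson residuals = chi2
  expect_equal(sum(res$residuals^2), res$chi2, tolerance = 1e-9)

  # 5 risk x 3 olfactory categories give df = 8
  withr::with_seed(1, {
    r5 <- sample(paste("cat", 1:5), 300, replace = TRUE)
    o3 <- sample(c("anosmia", "hyposmia", "normosmia"), 300, replace = TRUE)
  })
  expect_equal(crosstab_chi2(r5, o3)$df, 8)

  # perfectly proportional table: no signal at all
  a2 <- rep(c("x", "y"), c(40, 80))
  b2 <- c(rep(c("p", "q"), c(10, 30)), rep(c("p", "q"), c(20, 60)))
  res2 <- crosstab_chi2(a2, b2)
  expect_equal(res2$chi2, 0, tolerance = 1e-12)
  expect_true(all(abs(res2$residuals) < 1e-9))
})

test_that("residual-sum identity holds on random tables", {
  for (s in 1:20) {
    withr::with_seed(s, {
      a <- sample(letters[1:4], 200, replace = TRUE)
      b <- sample(LETTERS[1:3], 200, replace = TRUE)
    })
    res <- crosstab_chi2(a, b)
    expect_equal(sum(res$residuals^2), res$chi2, tolerance = 1e-9)
    expect_equal(rowSums(res$expected), rowSums(res$observed + 0),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("correlation matrix matches manual arithmetic and Bonferroni scope", {
  X <- cbind(a = c(1, 2, 3, 4, 7), b = c(2, 4, 6, 8, 14), c = c(5, 3, 8, 1, 2))
  cm <- corr_matrix(X)
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  expect_equal(cm$r["a", "b"], 1, tolerance = 1e-12)   # exact linearity
  manual_r <- sum((X[, 1] - mean(X[, 1])) * (X[, 3] - mean(X[, 3]))) /
    sqrt(sum((X[, 1] - mean(X[, 1]))^2) * sum((X[, 3] - mean(X[, 3]))^2))
  expect_equal(cm$r["a", "c"], manual_r, tolerance = 1e-9)
  expect_equal(cm$m, 3)  # all unique off-diagonal pairs

  # constant column: its pairs are marked, not silently numeric
  Xc <- cbind(X, d = rep(2, 5))
  cmc <- suppressWarnings(corr_matrix(Xc))
  expect_true(all(is.na(cmc$r["d", c("a", "b", "c")])))
})

test_that("mixed rm-ANOVA matches the aov split-plot decomposition", {
  withr::with_seed(2, {
    d <- expand.grid(subject = 1:12, within = c("t", "d", "i"))
    d$between <- rep(rep(c("g1", "g2"), each = 6), 3)
    d$value <- rnorm(36) + as.numeric(d$within) * 0.5
  })
  res <- rm_anova(d)
  d$subject <- factor(d$subject)
  ref <- summary(aov(value ~ between * within + Error(subject / within),
                     data = d))
  ref_between <- ref[["Error: subject"]][[1]]
  ref_within <- ref[["Error: subject:within"]][[1]]
  f_of <- function(tab, term) tab[trimws(rownames(tab)) == term, "F value"]
  expect_equal(res$table$F[res$table$effect == "between"],
               f_of(ref_between, "between"), tolerance = 1e-6)
  expect_equal(res$table$F[res$table$effect == "within"],
               f_of(ref_within, "within"), tolerance = 1e-6)
  expect_equal(res$table$F[res$table$effect == "interaction"],
               f_of(ref_within, "between:within"), tolerance = 1e-6)
  expect_equal(res$table$df1, c(1, 2, 2))
  expect_true(res$gg_epsilon > 1 / 2 && res$gg_epsilon <= 1)
})

test_that("rm-ANOVA Greenhouse-Geisser correction matches car", {
  skip_if_not_installed("car")
  withr::with_seed(4, {
    d <- expand.grid(subject = 1:15, within = c("w1", "w2", "w3"))
    d$between <- rep(rep(c("g1", "g2", "g3"), each = 5), 3)
    d$value <- rnorm(45) + rep(c(0, 0.8, 0.3), each = 15)
  })
  res <- rm_anova(d)
  Y <- sapply(c("w1", "w2", "w3"), function(w) d$value[d$within == w])
  grp <- factor(rep(c("g1", "g2", "g3"), each = 5))
  aa <- suppressWarnings(
    summary(car::Anova(lm(Y ~ grp),
                       idata = data.frame(w = factor(c("w1", "w2", "w3"))),
                       idesign = ~w, type = 3),
            multivariate = FALSE))
  expect_equal(res$gg_epsilon, unname(aa$pval.adjustments["w", "GG eps"]),
               tolerance = 1e-6)
})

test_that("rm-ANOVA validates the design and nulls out flat data", {
  d <- expand.grid(subject = 1:6, within = c("a", "b"))
  d$between <- "g1"
  d$value <- 1
  d2 <- rbind(d, data.frame(subject = 7, within = "a", between = "g2",
                            value = 2))
  expect_error(rm_anova(d2), "incomplete within-subject")

  # identical group means: between F ~ 0
  withr::with_seed(5, {
    dd <- expand.grid(subject = 1:10, within = c("a", "b", "c"))
    dd$between <- rep(rep(c("g1", "g2"), 5), 3)
    base <- rnorm(10, sd = 0.5)
    dd$value <- base[dd$subject] + as.numeric(dd$within)
    # force exactly equal group means of subject averages
    dd$value[dd$between == "g2"] <- dd$value[dd$between == "g2"] -
      (mean(base[seq(2, 10, 2)]) - mean(base[seq(1, 9, 2)]))
  })
  res <- rm_anova(dd)
  expect_lt(res$table$F[res$table$effect == "between"], 1e-20)
})

test_that("Welch t matches manual arithmetic and its invariances", {
  x <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6)
  y <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2)
  # hand Welch: t = (mx - my) / sqrt(sx2/nx + sy2/ny)
  se2 <- var(x) / 10 + var(y) / 10
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 10)^2 / 9 + (var(y) / 10)^2 / 9)
  res <- welch_t(x, y)
  expect_equal(res$t, t_hand, tolerance = 1e-9)
  expect_equal(res$df, df_hand, tolerance = 1e-9)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-9)

  expect_equal(welch_t(x, x)$t, 0)
  aff <- welch_t(3 + 2 * x, 3 + 2 * y)
  expect_equal(aff$t, res$t, tolerance = 1e-9)

  z <- rep(5, 4)
  expect_equal(welch_t(z, z), list(t = 0, df = 6, p = 1))
})

test_that("mode x risk crosstab is calibrated under the null", {
  # type-I rate of the chi2 at alpha = 0.05 across null cohorts
  reject <- vapply(1:200, function(s) {
    ct <- generate_cohort(generator_config(seed = s, n_missing = 0,
                                           n_outliers = 0))
    risk2 <- binarize_risk(ct$data$findrisk)
    p <- suppressWarnings(chisq.test(table(ct$truth$mode, risk2),
                                     correct = FALSE)$p.value)
    p < 0.05
  }, logical(1))
  expect_lt(abs(mean(!reject) - 0.95), 0.04)
})
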