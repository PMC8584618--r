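test_that("shadow-test thresholds equal closed-form binomial quantiles", {
  for (iters in c(10, 25, 60)) {
    thr <- boruta_thresholds(iters, alpha = 0.01)
    # oracle: enumerate all hit counts, find the two-sided decision regions
    p2 <- vapply(0:iters, function(h)
      min(1, 2 * min(pbinom(h, iters, 0.5),
                     pbinom(h - 1, iters, 0.5, lower.tail = FALSE))),
      numeric(1))
    conf_set <- which(p2 < 0.01 & (0:iters) > iters / 2) - 1
    rej_set <- which(p2 < 0.01 & (0:iters) < iters / 2) - 1
    expect_equal(thr$confirm,
                 if (length(conf_set)) min(conf_set) else NA_integer_)
    expect_equal(thr$reject,
                 if (length(rej_set)) max(rej_set) else NA_integer_)
  }
})

test_that("shadow-feature selection confirms signal and ignores noise", {
  confirmed_noise <- numeric(20)
  hit_signal <- logical(20)
  for (s in 1:20) {
    withr::with_seed(s, {
      X <- as.data.frame(matrix(rnorm(150 * 15), 150, 15))
      names(X) <- paste0("x", 1:15)
      y_sig <- X$x1 + rnorm(150, 0.3)
      y_noise <- rnorm(150)
    })
    bs <- boruta_select(X, y_sig, max_iter = 50)
    hit_signal[s] <- "x1" %in% bs$confirmed
    bn <- boruta_select(X, y_noise, max_iter = 50)
    confirmed_noise[s] <- length(bn$confirmed)
  }
  expect_gte(mean(hit_signal), 0.95)
  expect_lt(mean(confirmed_noise), 0.5)
})

test_that("LASSO selects the dominant predictor and prunes pure noise", {
  strong <- logical(20); null_sizes <- numeric(20)
  for (s in 1:20) {
    withr::with_seed(s, {
      X <- matrix(rnorm(200 * 8), 200, 8,
                  dimnames = list(NULL, paste0("x", 1:8)))
      y <- X[, "x1"] + rnorm(200, 0, 0.5)
      y0 <- rnorm(200)
    })
    strong[s] <- "x1" %in% lasso_select(X, y)
    null_sizes[s] <- length(lasso_select(X, y0))
  }
  expect_gte(mean(strong), 0.95)
  expect_lte(median(null_sizes), 2)
})

test_that("LMG importances decompose R2 exactly", {
  withr::with_seed(3, {
    n <- 150
    X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
    y <- X[, 1] + 0.5 * X[, 2] + rnorm(n)
  })
  imp <- lmg_importance(X, y)
  r2 <- summary(lm(y ~ X))$r.squared
  expect_true(all(imp >= -1e-12))
  expect_equal(sum(imp), r2, tolerance = 1e-6)

  # orthogonal predictors: importance = marginal R2
  withr::with_seed(4, {
    Q <- qr.Q(qr(matrix(rnorm(100 * 3), 100, 3)))
    colnames(Q) <- paste0("q", 1:3)
    yq <- Q %*% c(2, 1, 0) + rnorm(100, 0, 0.2)
  })
  impq <- lmg_importance(Q, yq)
  marg <- vapply(1:3, function(j) summary(lm(yq ~ Q[, j]))$r.squared,
                 numeric(1))
  expect_equal(unname(impq), marg, tolerance = 0.02)
})

test_that("LMG matches the all-orderings enumeration at small dimension", {
  withr::with_seed(5, {
    X <- matrix(rnorm(120 * 3), 120, 3, dimnames = list(NULL, c("a", "b", "c")))
    X[, 2] <- X[, 1] * 0.7 + X[, 2] * 0.5   # correlated pair
    y <- X[, 1] + X[, 2] + rnorm(120)
  })
  # oracle: average R2 increments over all 3! orderings via lm()
  r2 <- function(cols) if (!length(cols)) 0 else
    summary(lm(y ~ X[, cols, drop = FALSE]))$r.squared
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  acc <- numeric(3)
  for (p in perms) {
    prev <- 0
    for (i in seq_along(p)) {
      cur <- r2(p[seq_len(i)])
      acc[p[i]] <- acc[p[i]] + (cur - prev)
      prev <- cur
    }
  }
  oracle <- acc / length(perms)
  expect_equal(unname(lmg_importance(X, y)), oracle, tolerance = 1e-9)
})

test_that("ABC analysis isolates the important few", {
  res <- abc_analysis(c(big = 100, a = 1, b = 1, c = 1, d = 1))
  expect_equal(res$A, "big")

  # uniform values: partition stays ordered and exhaustive
  resu <- abc_analysis(setNames(rep(2, 6), letters[1:6]))
  expect_gte(res$ab_limit, 1)
  expect_setequal(unlist(resu[c("A", "B", "C")]), letters[1:6])

  # ordering property and positive-rescaling invariance on random inputs
  for (s in 1:10) {
    v <- withr::with_seed(s, setNames(rexp(12) + 0.01, paste0("f", 1:12)))
    r1 <- abc_analysis(v)
    vals <- function(set) v[set]
    if (length(r1$A) && length(r1$B))
      expect_gte(min(vals(r1$A)), max(vals(r1$B)))
    if (length(r1$B) && length(r1$C))
      expect_gte(min(vals(r1$B)), max(vals(r1$C)))
    r2 <- abc_analysis(v * 37.5)
    expect_identical(r1$set, r2$set)
  }
  expect_error(abc_analysis(c(1, 0, 2)), "positive")
})

test_that("resampled selection counts strong features and stays reproducible", {
  withr::with_seed(9, {
    X <- as.data.frame(matrix(rnorm(180 * 6), 180, 6))
    names(X) <- paste0("x", 1:6)
    y <- 2 * X$x1 + rnorm(180, 0, 0.5)
  })
  rs <- resampled_selection("lasso", X, y, runs = 50, seed = 4)
  expect_gte(rs$counts[["x1"]], 48)
  expect_true(all(rs$counts <= 50))
  # subsample size is floor(2n/3)
  expect_identical(rs, resampled_selection("lasso", X, y, runs = 50, seed = 4))

  rl <- resampled_selection("lmg", X, y, runs = 20, seed = 4)
  expect_gte(rl$counts[["x1"]], 19)
})

test_that("final set aggregation follows the modal-size and ABC rules", {
  counts <- c(a = 100, b = 98, c = 97, d = 5, e = 2, f = 0)
  sizes <- c(rep(3, 60), rep(4, 30), rep(2, 10))
  rep_ <- final_feature_set(counts, sizes)
  expect_equal(rep_$modal_size, 3)
  expect_setequal(rep_$final_set, c("a", "b", "c"))
  expect_equal(unname(rep_$abc_set[["f"]]), "C")

  # identical sets across runs reproduce that set
  counts2 <- c(a = 50, b = 50, c = 0)
  rep2 <- final_feature_set(counts2, rep(2, 50))
  expect_setequal(rep2$final_set, c("a", "b"))

  # disagreement flag when ABC-A and modal size differ
  counts3 <- c(a = 100, b = 10, c = 9, d = 8)
  rep3 <- final_feature_set(counts3, rep(3, 40))
  expect_true(rep3$disagreement)

  # all-zero counts: empty, flagged
  rep0 <- final_feature_set(c(a = 0, b = 0), integer(0))
  expect_length(rep0$final_set, 0)
  expect_true(rep0$empty)
})

test_that("synthetic 3-signal + 12-noise recovers the informative set", {
  wins <- vapply(1:5, function(s) {
    withr::with_seed(s, {
      X <- as.data.frame(matrix(rnorm(120 * 15), 120, 15))
      names(X) <- paste0("x", 1:15)
      y <- X$x1 + X$x2 + X$x3 + rnorm(120, 0, 0.5)
    })
    rs <- resampled_selection("boruta", X, y, runs = 10, seed = s,
                              max_iter = 20, num_trees = 50)
    rep_ <- final_feature_set(rs$counts, rs$set_sizes)
    setequal(rep_$final_set, c("x1", "x2", "x3")) && rep_$modal_size == 3
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
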