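test_that("Pareto density integrates to one and finds the normal peak", {
  withr::with_seed(3, x <- rnorm(2000))
  pde <- pareto_density(x)
  expect_true(all(pde$density >= 0))
  integral <- sum(diff(pde$grid) * (head(pde$density, -1) + tail(pde$density, -1)) / 2)
  expect_lt(abs(integral - 1), 0.02)
  peak <- pde$grid[which.max(pde$density)]
  expect_lt(abs(peak - 0), 0.1)
  expect_lt(abs(max(pde$density) - dnorm(0)), 0.05)
  expect_error(pareto_density(rep(1, 20)), "constant")
})

test_that("Pareto density tracks the printed TDI mixture's shape", {
  # The true density of the printed mixture is unimodal with a shoulder
  # at the lower component (the minor mode never rises above the valley),
  # so the estimate is checked against the true curve, not a mode count.
  withr::with_seed(11, x <- rgmm(printed_mixture(), 2000))
  pde <- pareto_density(x)
  truth <- function(t) {
    w <- c(0.167, 0.83) / 0.997
    w[1] * dnorm(t, 24.9, 3.42) + w[2] * dnorm(t, 34.32, 3.2)
  }
  inside <- pde$grid > 18 & pde$grid < 42
  expect_lt(max(abs(pde$density[inside] - truth(pde$grid[inside]))), 0.012)
  expect_lt(abs(pde$grid[which.max(pde$density)] - 34.32), 1)
  # the lower component is clearly visible as elevated density
  expect_gt(pde$density[which.min(abs(pde$grid - 24.9))],
            5 * pde$density[which.min(abs(pde$grid - 17))])
})

test_that("single-component fit equals the closed-form ML solution", {
  withr::with_seed(5, x <- rnorm(400, 10, 2))
  fit <- fit_gmm(x, 1)
  expect_equal(fit$means, mean(x), tolerance = 1e-6)
  expect_equal(fit$sds, sqrt(mean((x - mean(x))^2)), tolerance = 1e-6)
  expect_equal(fit$weights, 1)
  # BIC identity from the stored log-likelihood
  expect_equal(fit$bic, -2 * fit$log_likelihood + 2 * log(length(x)),
               tolerance = 1e-9)
})

test_that("well-separated point masses recover their mixing weights", {
  x <- c(rnorm(300, 0, 0.01), rnorm(700, 100, 0.01))
  fit <- fit_gmm(x, 2, seed = 4)
  expect_equal(fit$weights, c(0.3, 0.7), tolerance = 0.01)
  expect_equal(fit$means, c(0, 100), tolerance = 0.1)
})

test_that("EM recovers the printed mixture on average at the cohort size", {
  lower_means <- vapply(1:20, function(s) {
    x <- withr::with_seed(s, rgmm(printed_mixture(), 163))
    fit_gmm(x, 2, seed = s)$means[1]
  }, numeric(1))
  expect_lt(abs(mean(lower_means) - 24.9), 1.0)
})

test_that("BIC table obeys its defining identity and selects honestly", {
  withr::with_seed(8, x <- rgmm(printed_mixture(), 300))
  sel <- select_mode_count(x, M_max = 3, seed = 8)
  n <- length(x)
  expect_equal(sel$bic_table$bic,
               -2 * sel$bic_table$log_likelihood +
                 (3 * sel$bic_table$M - 1) * log(n),
               tolerance = 1e-9)
  expect_equal(sel$chosen_M, sel$bic_table$M[which.min(sel$bic_table$bic)])
})

test_that("mode-count selection finds no structure in single Gaussians", {
  chosen <- vapply(1:20, function(s) {
    x <- withr::with_seed(s, rnorm(500))
    select_mode_count(x, M_max = 3, seed = s, n_starts = 4)$chosen_M
  }, numeric(1))
  expect_equal(as.integer(names(which.max(table(chosen)))), 1L)
})

test_that("mode-count selection supports bimodality at the cohort size", {
  chosen <- vapply(1:20, function(s) {
    x <- withr::with_seed(s, rgmm(printed_mixture(), 163))
    select_mode_count(x, M_max = 5, seed = s, n_starts = 6)$chosen_M
  }, numeric(1))
  expect_equal(as.integer(names(which.max(table(chosen)))), 2L)
})

test_that("the printed mixture's Bayes boundary is 27.85", {
  b <- bayes_boundaries(printed_mixture())
  expect_lt(abs(b - 27.85), 0.05)
})

test_that("equal-weight equal-sd components split at the midpoint", {
  fit <- structure(list(means = c(-2, 6), sds = c(1.5, 1.5),
                        weights = c(0.5, 0.5), M = 2L), class = "gmm_fit")
  expect_equal(bayes_boundaries(fit), 2, tolerance = 1e-6)
})

test_that("boundaries agree with a dense-grid posterior search", {
  for (s in 1:5) {
    fit <- withr::with_seed(s, {
      m <- sort(runif(2, 0, 20)); m[2] <- m[2] + 3
      structure(list(means = m, sds = runif(2, 0.5, 2),
                     weights = {w <- runif(2, 0.2, 0.8); w / sum(w)},
                     M = 2L), class = "gmm_fit")
    })
    b <- bayes_boundaries(fit)
    if (is.na(b)) next
    grid <- seq(fit$means[1], fit$means[2], by = 1e-4)
    post <- gmm_posterior(fit, grid)
    expect_lt(abs(b - grid[which.min(abs(post[, 1] - post[, 2]))]), 1e-3)
  }
})

test_that("posterior assignment is consistent with the decision boundary", {
  fit <- printed_mixture()
  expect_equal(assign_modes(fit, c(24.9, 27, 28.5, 34.32)), c(1L, 1L, 2L, 2L))
  withr::with_seed(13, {
    x <- runif(1000, 10, 45)
    lab <- assign_modes(fit, x)
    expect_equal(lab, ifelse(x < bayes_boundaries(fit), 1L, 2L))
  })
})

test_that("absent boundaries are reported, not fabricated", {
  # extreme weight imbalance: the dominant component wins everywhere
  fit <- structure(list(means = c(0, 0.5), sds = c(5, 0.01),
                        weights = c(0.999, 0.001), M = 2L),
                   class = "gmm_fit")
  post <- gmm_posterior(fit, seq(0, 0.5, length.out = 1000))
  expect_true(all(post[, 2] < 0.5))   # the minor component never wins
  expect_true(is.na(bayes_boundaries(fit)))
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(requireNamespace("mclust"))
  # Mclust resolves helper functions from its own attached namespace
  suppressMessages(attachNamespace("mclust"))
  withr::defer(detach("package:mclust", character.only = TRUE))
  x <- withr::with_seed(21, rgmm(printed_mixture(), 1000))
  fit <- fit_gmm(x, 2, seed = 21)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$means, as.numeric(mc$parameters$mean), tolerance = 0.1)
  expect_equal(fit$log_likelihood, mc$loglik, tolerance = 0.01)
})
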