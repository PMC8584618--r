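#' Closed-form decision thresholds of the shadow-feature hit test
#'
#' After `iters` shadow comparisons a feature is confirmed when its hit
#' count is improbably high and rejected when improbably low under a
#' two-sided binomial test with success probability 0.5 at level `alpha`.
#'
#' @param iters Number of completed iterations.
#' @param alpha Significance level (default 0.01).
#' @return List with `confirm` (smallest confirming hit count) and
#'   `reject` (largest rejecting hit count); `NA` when unreachable.
#' @export
boruta_thresholds <- function(iters, alpha = 0.01) {
  # two-sided p for h hits: doubled smaller tail
  p_two <- function(h) {
    min(1, 2 * min(stats::pbinom(h, iters, 0.5),
                   stats::pbinom(h - 1, iters, 0.5, lower.tail = FALSE)))
  }
  confirm <- NA_integer_
  for (h in iters:0) {
    if (p_two(h) < alpha && h > iters / 2) confirm <- h else break
  }
  reject <- NA_integer_
  for (h in 0:iters) {
    if (p_two(h) < alpha && h < iters / 2) reject <- h else break
  }
  list(confirm = confirm, reject = reject)
}

#' Shadow-feature all-relevant selection (Boruta-style)
#'
#' Each iteration appends a permuted "shadow" copy of every candidate
#' feature, fits a random forest (regression mode), and credits a feature
#' with a hit when its importance exceeds the maximum shadow importance.
#' Features whose hit counts become improbably high under a two-sided
#' binomial test (p < `alpha`) are confirmed; improbably low counts are
#' rejected and dropped from later iterations. Features still undecided
#' after `max_iter` iterations are not selected. The test level is
#' Bonferroni-adjusted over the initial feature count (`mc_adjust`),
#' which keeps chance-correlated noise features from being confirmed.
#'
#' @param X Feature data.frame or matrix (>= 2 features).
#' @param y Numeric outcome.
#' @param alpha Significance level of the binomial decision (default 0.01).
#' @param max_iter Maximum iterations (default 100).
#' @param num_trees Trees per forest (default 100).
#' @param mc_adjust Bonferroni-adjust the decision level over the feature
#'   count (default TRUE).
#' @return A list of class `boruta_result`: `confirmed`, `rejected`,
#'   `undecided` (feature names), `hits`, `iterations`.
#' @export
boruta_select <- function(X, y, alpha = 0.01, max_iter = 100L,
                          num_trees = 100L, mc_adjust = TRUE) {
  X <- as.data.frame(X)
  stop_if_not(ncol(X) >= 2, "need at least 2 features")
  stop_if_not(stats::sd(y) > 0, "constant outcome")
  if (mc_adjust) alpha <- alpha / ncol(X)
  features <- colnames(X)
  hits <- stats::setNames(integer(length(features)), features)
  iters <- stats::setNames(integer(length(features)), features)
  confirmed <- character(0); rejected <- character(0)
  active <- features

  for (it in seq_len(max_iter)) {
    if (length(active) == 0) break
    sh <- as.data.frame(lapply(X[active], sample))
    names(sh) <- paste0(".shadow_", active)
    df <- cbind(X[active], sh, .y = y)
    # permutation importance (mean decrease accuracy), as in the published
    # shadow-feature algorithm
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = num_trees, importance = "permutation",
                          num.threads = 1L)
    imp <- fit$variable.importance
    shadow_max <- max(imp[names(sh)])
    hit <- imp[active] > shadow_max
    hits[active] <- hits[active] + hit
    iters[active] <- iters[active] + 1L
    thr <- boruta_thresholds(it, alpha)
    newly_conf <- active[!is.na(thr$confirm) & hits[active] >= thr$confirm]
    newly_rej <- active[!is.na(thr$reject) & hits[active] <= thr$reject]
    confirmed <- c(confirmed, newly_conf)
    rejected <- c(rejected, newly_rej)
    active <- setdiff(active, c(newly_conf, newly_rej))
  }
  structure(list(confirmed = confirmed, rejected = rejected,
                 undecided = active, hits = hits, iterations = iters),
            class = "boruta_result")
}

#' LASSO feature selection
#'
#' L1-penalized linear regression over a penalty path; the penalty is
#' chosen by cross-validation under the one-standard-error rule (the
#' largest penalty whose CV error is within one SE of the minimum — the
#' penalized fit's own default for coefficient extraction) and the
#' selected features are those with nonzero coefficients at that penalty.
#' `rule = "min"` switches to the minimum-CV-error penalty.
#'
#' @param X Feature matrix or data.frame (standardized internally by the
#'   penalized fit).
#' @param y Numeric outcome.
#' @param folds Cross-validation folds (default 10; `n` must exceed it).
#' @param rule Penalty rule, `"1se"` (default) or `"min"`.
#' @return Character vector of selected feature names.
#' @export
lasso_select <- function(X, y, folds = 10L, rule = c("1se", "min")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  stop_if_not(nrow(X) > folds, "need more observations than folds")
  cv <- glmnet::cv.glmnet(X, y, alpha = 1, nfolds = folds,
                          standardize = TRUE)
  s <- if (rule == "1se") "lambda.1se" else "lambda.min"
  cf <- as.matrix(stats::coef(cv, s = s))[-1, 1]
  names(cf)[cf != 0]
}

# R^2 of the regression of y on the columns in `set`, from the joint
# covariance (empty set -> 0).
.r2_from_cov <- function(Sxx, sxy, syy, set) {
  if (!length(set)) return(0)
  b <- solve(Sxx[set, set, drop = FALSE], sxy[set])
  as.numeric(crossprod(sxy[set], b) / syy)
}

#' LMG relative importance (Shapley decomposition of R-squared)
#'
#' Each feature's importance is its average increment to the model
#' R-squared over orderings of feature entry. For up to 12 features all
#' subsets are enumerated exactly (with the closed-form ordering weights
#' `|S|! (p - |S| - 1)! / p!`); for more features the average is taken
#' over Monte-Carlo random orderings. Importances are non-negative and
#' sum to the full-model R-squared.
#'
#' @param X Feature matrix or data.frame.
#' @param y Numeric outcome (`n > p + 2`).
#' @param n_orderings Random orderings for the sampled variant
#'   (default 200).
#' @param seed Seed for the sampled variant.
#' @return Named numeric vector of importances (same order as columns).
#' @export
lmg_importance <- function(X, y, n_orderings = 200L, seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X); n <- nrow(X)
  stop_if_not(n > p + 2, "need n > number of features + 2")
  Sxx <- stats::cov(X); sxy <- stats::cov(X, y)[, 1]; syy <- stats::var(y)
  if (inherits(try(solve(Sxx), silent = TRUE), "try-error"))
    stop("singular design", call. = FALSE)
  vars <- colnames(X) %||% paste0("x", seq_len(p))
  names(sxy) <- rownames(Sxx) <- colnames(Sxx) <- vars

  imp <- stats::setNames(numeric(p), vars)
  if (p <= 12) {
    # exact: R^2 of every subset, then weighted increments
    subsets <- lapply(0:(2^p - 1), function(code) vars[bitwAnd(code, 2^(seq_len(p) - 1)) > 0])
    r2v <- vapply(subsets, function(s) .r2_from_cov(Sxx, sxy, syy, s), numeric(1))
    skey <- function(s) paste0("|", paste(sort(s), collapse = ","))
    r2map <- stats::setNames(r2v, vapply(subsets, skey, character(1)))
    fact <- factorial(0:p)
    for (ci in seq_along(subsets)) {
      s <- subsets[[ci]]
      w <- fact[length(s) + 1] * fact[p - length(s)] / fact[p + 1]
      base <- r2map[[skey(s)]]
      for (v in setdiff(vars, s)) {
        imp[v] <- imp[v] + w * (r2map[[skey(c(s, v))]] - base)
      }
    }
  } else {
    imp <- with_seed(seed, {
      acc <- stats::setNames(numeric(p), vars)
      for (o in seq_len(n_orderings)) {
        ord <- sample(vars)
        prev <- 0
        for (i in seq_along(ord)) {
          cur <- .r2_from_cov(Sxx, sxy, syy, ord[seq_len(i)])
          acc[ord[i]] <- acc[ord[i]] + (cur - prev)
          prev <- cur
        }
      }
      acc / n_orderings
    })
  }
  imp
}

#' Computed ABC analysis
#'
#' Divides a set of positive numbers into the "important few" (A), the
#' intermediate (B) and the "trivial many" (C) from the geometry of the
#' cumulative-contribution curve: items are sorted descending; the curve
#' plots cumulative value share against cumulative item fraction; the A|B
#' limit is the curve point nearest the ideal point (0, 1); the B|C limit
#' is the break-even point where the curve's slope (item value / mean
#' value) falls to 1. If the nearest-to-ideal point falls beyond the
#' break-even point, the A|B limit is moved to the break-even point. The
#' partition is invariant to positive rescaling of the input.
#'
#' @param values Named positive numbers (zeros must be excluded first).
#' @return A list of class `abc_result`: `A`, `B`, `C` (names per set),
#'   `set` (per-item label in input order), `ab_limit`, `bc_limit`
#'   (indices into the descending order).
#' @export
abc_analysis <- function(values) {
  stop_if_not(length(values) > 0, "empty input")
  stop_if_not(all(values > 0), "values must be positive (exclude zeros first)")
  nm <- names(values) %||% as.character(seq_along(values))
  ord <- order(values, decreasing = TRUE)
  v <- values[ord]
  n <- length(v)
  xs <- seq_len(n) / n
  ys <- cumsum(v) / sum(v)
  ab <- which.min(xs^2 + (1 - ys)^2)
  slope <- v / mean(v)                 # curve derivative at each item
  be <- if (any(slope >= 1 - 1e-12)) max(which(slope >= 1 - 1e-12)) else 1L
  if (ab > be) ab <- be
  lab <- rep("C", n)
  lab[seq_len(be)] <- "B"
  lab[seq_len(ab)] <- "A"
  set <- stats::setNames(character(length(values)), nm)
  set[ord] <- lab
  structure(list(A = nm[ord][lab == "A"], B = nm[ord][lab == "B"],
                 C = nm[ord][lab == "C"], set = set,
                 ab_limit = ab, bc_limit = be),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat("ABC analysis: A =", length(x$A), "| B =", length(x$B),
      "| C =", length(x$C), "items\n")
  cat("A:", paste(x$A, collapse = ", "), "\n")
  invisible(x)
}

#' Resampled feature selection
#'
#' Repeats a selector on Monte-Carlo subsamples (without replacement) of
#' `subsample_fraction` of the subjects and accumulates how often each
#' feature is selected. For the `"lmg"` selector a run's selected set is
#' the ABC set A of that run's importances (the reduction of a
#' relative-importance profile to a feature set).
#'
#' @param selector One of `"boruta"`, `"lasso"`, `"lmg"`.
#' @param X Feature data.frame.
#' @param y Numeric outcome.
#' @param runs Number of resampling runs (default 1000).
#' @param subsample_fraction Fraction of subjects per run (default 2/3).
#' @param seed Integer seed.
#' @param ... Passed to the selector.
#' @return A list of class `selection_counts`: `counts` (per feature),
#'   `set_sizes` (per run), `runs`, `n_failed`.
#' @export
resampled_selection <- function(selector = c("boruta", "lasso", "lmg"),
                                X, y, runs = 1000L, subsample_fraction = 2 / 3,
                                seed = 1L, ...) {
  selector <- match.arg(selector)
  X <- as.data.frame(X)
  n <- nrow(X)
  m <- floor(n * subsample_fraction)
  counts <- stats::setNames(integer(ncol(X)), colnames(X))
  set_sizes <- integer(0)
  n_failed <- 0L
  with_seed(seed, {
    for (r in seq_len(runs)) {
      idx <- sample.int(n, m)
      sel <- tryCatch(switch(selector,
        boruta = boruta_select(X[idx, , drop = FALSE], y[idx], ...)$confirmed,
        lasso = lasso_select(X[idx, , drop = FALSE], y[idx], ...),
        lmg = {
          imp <- lmg_importance(X[idx, , drop = FALSE], y[idx], ...)
          pos <- imp[imp > 0]
          if (length(pos)) abc_analysis(pos)$A else character(0)
        }), error = function(e) NULL)
      if (is.null(sel)) { n_failed <- n_failed + 1L; next }
      counts[sel] <- counts[sel] + 1L
      set_sizes <- c(set_sizes, length(sel))
    }
  })
  structure(list(counts = counts, set_sizes = set_sizes,
                 runs = as.integer(runs), n_failed = n_failed,
                 selector = selector),
            class = "selection_counts")
}

#' Aggregate resampled selection counts into a final feature set
#'
#' Applies ABC analysis to the positive selection counts and takes the
#' final set as the top-`f` features by count, where `f` is the modal
#' per-run selected-set size. Features with zero counts are labelled C.
#' When counts tie at the cut boundary all tied features are included and
#' the disagreement flag is raised; the flag is also raised whenever the
#' ABC set A differs from the modal-size set (the two aggregation rules
#' are both reported).
#'
#' @param counts Named per-feature selection counts.
#' @param set_sizes Per-run selected-set sizes.
#' @return A list of class `feature_report`: `counts`, `abc_set` (A/B/C
#'   per feature), `modal_size`, `final_set`, `abc_A`, `disagreement`.
#' @export
final_feature_set <- function(counts, set_sizes) {
  stop_if_not(length(set_sizes) > 0 || all(counts == 0), "no runs recorded")
  abc_set <- stats::setNames(rep("C", length(counts)), names(counts))
  abc_A <- character(0)
  if (any(counts > 0)) {
    abc <- abc_analysis(counts[counts > 0])
    abc_set[names(abc$set)] <- abc$set
    abc_A <- abc$A
  }
  if (all(counts == 0) || length(set_sizes) == 0) {
    return(structure(list(counts = counts, abc_set = abc_set,
                          modal_size = 0L, final_set = character(0),
                          abc_A = abc_A, disagreement = TRUE,
                          empty = TRUE),
                     class = "feature_report"))
  }
  size_tab <- table(set_sizes)
  modal <- min(as.integer(names(size_tab)[size_tab == max(size_tab)]))
  ordc <- sort(counts, decreasing = TRUE)
  final <- character(0); tie_flag <- FALSE
  if (modal > 0) {
    cut_val <- ordc[min(modal, length(ordc))]
    final <- names(counts)[counts >= cut_val & counts > 0]
    tie_flag <- length(final) > modal
  }
  disagreement <- tie_flag || !setequal(final, abc_A)
  structure(list(counts = counts, abc_set = abc_set, modal_size = modal,
                 final_set = final, abc_A = abc_A,
                 disagreement = disagreement, empty = FALSE),
            class = "feature_report")
}

#' @export
print.feature_report <- function(x, ...) {
  cat("Final feature set (modal size", x$modal_size, "):",
      paste(x$final_set, collapse = ", "), "\n")
  cat("ABC set A:", paste(x$abc_A, collapse = ", "),
      if (x$disagreement) " [rules disagree]" else "", "\n")
  invisible(x)
}
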