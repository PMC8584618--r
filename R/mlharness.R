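#' Binarize the FINDRISK score
#'
#' Collapses the five ordinal risk categories into a two-class problem:
#' `low` for scores at or below the breakpoint, `high` above it. The
#' default breakpoint 11 combines risk categories 1-2 versus 3-5; the
#' alternative breakpoint 9 follows the score's original validation.
#'
#' @param score Non-negative integer score(s).
#' @param breakpoint Score threshold (default 11).
#' @return Factor with levels `low`, `high`.
#' @export
binarize_risk <- function(score, breakpoint = 11) {
  stop_if_not(all(score >= 0, na.rm = TRUE), "scores must be non-negative")
  factor(ifelse(score <= breakpoint, "low", "high"), levels = c("low", "high"))
}

#' Class-proportional Monte-Carlo cross-validation splits
#'
#' Draws `runs` independent random splits of the subjects into disjoint
#' train / test sets, sampling each class separately so every training set
#' carries the original class proportions (to within one subject).
#'
#' @param labels Class labels (every class needs >= 3 members).
#' @param runs Number of splits (default 1000).
#' @param train_fraction Training fraction per class (default 2/3).
#' @param seed Integer seed; the plan is reproducible from it.
#' @return A list of class `split_plan`: `runs`, `train` / `test` (lists
#'   of index vectors), `labels`, `train_fraction`, `seed`.
#' @export
stratified_mc_splits <- function(labels, runs = 1000L, train_fraction = 2 / 3,
                                 seed = 1L) {
  labels <- as.factor(labels)
  cls <- split(seq_along(labels), labels)
  stop_if_not(all(lengths(cls) >= 3), "every class needs at least 3 members")
  n_train <- pmax(pmin(round(lengths(cls) * train_fraction),
                       lengths(cls) - 1L), 1L)
  train <- with_seed(seed, {
    lapply(seq_len(runs), function(r)
      sort(unlist(lapply(seq_along(cls),
                         function(i) sample(cls[[i]], n_train[i])),
                  use.names = FALSE)))
  })
  test <- lapply(train, function(tr) setdiff(seq_along(labels), tr))
  structure(list(runs = as.integer(runs), train = train, test = test,
                 labels = labels, train_fraction = train_fraction,
                 seed = seed),
            class = "split_plan")
}

#' Confusion-matrix and ranking metrics for a two-class prediction
#'
#' Sensitivity, specificity, positive and negative predictive values, F1,
#' balanced accuracy (the mean of sensitivity and specificity) and
#' ROC-AUC, all in percent. AUC uses the rank (Mann-Whitney) formulation
#' with mid-ranks for ties. Metrics that are undefined on a given split
#' (e.g., PPV with no positive predictions, or a single-class truth) are
#' returned as `NaN`, never silently zeroed.
#'
#' @param truth Factor of true classes.
#' @param predicted Factor of predicted classes.
#' @param scores Optional numeric scores for the positive class (for AUC).
#' @param positive The positive (clinically adverse) class label; defaults
#'   to the last level of `truth`.
#' @return Named numeric vector (percent): `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `f1`, `balanced_accuracy`, `auc`.
#' @export
confusion_metrics <- function(truth, predicted, scores = NULL,
                              positive = NULL) {
  truth <- as.factor(truth)
  if (is.null(positive)) positive <- levels(truth)[nlevels(truth)]
  t_pos <- truth == positive
  p_pos <- as.character(predicted) == positive
  tp <- sum(t_pos & p_pos); fn <- sum(t_pos & !p_pos)
  fp <- sum(!t_pos & p_pos); tn <- sum(!t_pos & !p_pos)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  f1 <- if (is.nan(ppv) || is.nan(sens) || (ppv + sens) == 0) NaN else
    2 * ppv * sens / (ppv + sens)
  bal <- (sens + spec) / 2
  auc <- NaN
  if (!is.null(scores) && any(t_pos) && any(!t_pos) && !anyNA(scores)) {
    rk <- rank(scores)
    n1 <- sum(t_pos); n0 <- sum(!t_pos)
    auc <- (sum(rk[t_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  100 * c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
          f1 = f1, balanced_accuracy = bal, auc = auc)
}

# ---- classifier backends ---------------------------------------------------
# Each backend fits on a training frame and returns predicted classes and
# positive-class scores on the test frame. Hyperparameters default to the
# printed settings: random forest 500 trees / max 7 terminal nodes,
# boosting depth 5 / eta 0.25 / 5 parallel trees.

#' Available classifier families
#'
#' `"rf"` random forest (500 trees, at most 7 terminal nodes, `mtry =
#' round(sqrt(p))` or chosen from `mtry_grid` by OOB error); `"xgb"`
#' gradient-boosted trees (depth 5, eta 0.25, 5 parallel trees);
#' `"tree"` an information-gain decision tree with extractable rules
#' (standing in for a non-hierarchical rule inducer); `"logistic"`
#' logistic regression; `"svm"` a radial-kernel support vector machine.
#'
#' @return Character vector of family names.
#' @export
classifier_families <- function() c("rf", "xgb", "tree", "logistic", "svm")

fit_predict <- function(classifier, Xtr, ytr, Xte, positive, params = list()) {
  neg <- setdiff(levels(ytr), positive)
  switch(classifier,
    rf = {
      p <- ncol(Xtr)
      grid <- params$mtry_grid %||% round(sqrt(p))
      grid <- unique(pmax(pmin(grid, p), 1))
      mtry <- if (length(grid) > 1) {
        oob <- vapply(grid, function(m)
          randomForest::randomForest(Xtr, ytr, ntree = 100L, maxnodes = 7L,
                                     mtry = m)$err.rate[100L, "OOB"],
          numeric(1))
        grid[which.min(oob)]
      } else grid
      fit <- randomForest::randomForest(Xtr, ytr,
                                        ntree = params$ntree %||% 500L,
                                        maxnodes = params$maxnodes %||% 7L,
                                        mtry = mtry)
      sc <- predict(fit, Xte, type = "prob")[, positive]
      list(class = predict(fit, Xte), score = sc)
    },
    xgb = {
      dtr <- xgboost::xgb.DMatrix(as.matrix(Xtr),
                                  label = as.numeric(ytr == positive))
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth %||% 5L,
                      eta = params$eta %||% 0.25,
                      num_parallel_tree = params$num_parallel_tree %||% 5L,
                      nthread = 1L),
        data = dtr, nrounds = params$nrounds %||% 20L, verbose = 0)
      sc <- predict(fit, as.matrix(Xte))
      list(class = factor(ifelse(sc > 0.5, positive, neg),
                          levels = levels(ytr)), score = sc)
    },
    tree = {
      df <- data.frame(Xtr, .y = ytr, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = "information"))
      sc <- predict(fit, data.frame(Xte, check.names = FALSE))[, positive]
      list(class = factor(ifelse(sc > 0.5, positive, neg),
                          levels = levels(ytr)), score = sc)
    },
    logistic = {
      df <- data.frame(Xtr, .y = as.numeric(ytr == positive),
                       check.names = FALSE)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                         family = stats::binomial()))
      sc <- suppressWarnings(
        stats::predict(fit, data.frame(Xte, check.names = FALSE),
                       type = "response"))
      list(class = factor(ifelse(sc > 0.5, positive, neg),
                          levels = levels(ytr)), score = sc)
    },
    svm = {
      fit <- e1071::svm(Xtr, ytr, probability = TRUE, kernel = "radial")
      pr <- predict(fit, Xte, probability = TRUE)
      sc <- attr(pr, "probabilities")[, positive]
      list(class = pr, score = sc)
    },
    stop("unknown classifier: ", classifier, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the decision rules of a fitted classification tree
#'
#' Fits the `"tree"` backend on the full data and renders each leaf as a
#' human-readable rule (conjunction of split conditions and the class
#' assigned).
#'
#' @param X Feature data.frame.
#' @param y Two-level factor outcome.
#' @return Character vector, one rule per leaf.
#' @export
tree_rules <- function(X, y) {
  df <- data.frame(X, .y = as.factor(y), check.names = FALSE)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "information"))
  fr <- fit$frame
  leaves <- as.integer(rownames(fr)[fr$var == "<leaf>"])
  paths <- rpart::path.rpart(fit, nodes = leaves, print.it = FALSE)
  vapply(seq_along(leaves), function(i) {
    cls <- attr(fit, "ylevels")[fr$yval[fr$var == "<leaf>"][i]]
    cond <- paste(paths[[i]][-1], collapse = " & ")
    if (cond == "") cond <- "TRUE"
    paste0("IF ", cond, " THEN ", cls)
  }, character(1))
}

#' Run a Monte-Carlo cross-validated classification experiment
#'
#' For each split of the plan the classifier is fitted on the training
#' set and evaluated on the held-out set with [confusion_metrics()].
#' Under `condition = "permuted"` the training labels are freshly permuted
#' before each fit (the negative control: any performance above chance
#' then indicates overfitting or leakage — test labels are untouched).
#' Runs whose training split degenerates to a single class are skipped
#' and counted. Medians and 2.5-97.5 percentile intervals are computed
#' per metric with `NaN` runs excluded (and their count reported).
#'
#' @param X Feature data.frame (numeric columns).
#' @param y Two-level factor outcome (same length as `nrow(X)`).
#' @param classifier One of [classifier_families()].
#' @param plan A [stratified_mc_splits()] plan built on `y`.
#' @param condition `"original"` or `"permuted"`.
#' @param positive Positive class (default: the last level of `y`).
#' @param params Optional hyperparameter overrides for the backend.
#' @param feature_set Label carried into the summary (e.g. "metabolomics").
#' @return A list of class `performance_summary`: `classifier`,
#'   `feature_set`, `condition`, `summary` (per-metric median / lo / hi /
#'   `n_nan`), `per_run` (runs x metrics matrix), `n_skipped`.
#' @export
run_cv <- function(X, y, classifier, plan, condition = c("original", "permuted"),
                   positive = NULL, params = list(), feature_set = "features") {
  condition <- match.arg(condition)
  classifier <- match.arg(classifier, classifier_families())
  y <- as.factor(y)
  stop_if_not(nlevels(y) == 2, "run_cv expects a two-class outcome")
  stop_if_not(nrow(X) == length(y), "X and y sizes differ")
  if (is.null(positive)) positive <- levels(y)[2]
  X <- as.data.frame(X)

  metric_names <- c("sensitivity", "specificity", "ppv", "npv", "f1",
                    "balanced_accuracy", "auc")
  per_run <- matrix(NA_real_, plan$runs, length(metric_names),
                    dimnames = list(NULL, metric_names))
  n_skipped <- 0L
  with_seed(derive_seed(plan$seed, 17L), {
    for (r in seq_len(plan$runs)) {
      tr <- plan$train[[r]]; te <- plan$test[[r]]
      ytr <- y[tr]
      if (condition == "permuted") ytr <- sample(ytr)
      if (nlevels(droplevels(ytr)) < 2) { n_skipped <- n_skipped + 1L; next }
      pred <- fit_predict(classifier, X[tr, , drop = FALSE], ytr,
                          X[te, , drop = FALSE], positive, params)
      per_run[r, ] <- confusion_metrics(y[te], pred$class, pred$score,
                                        positive = positive)
    }
  })
  summarise_runs(per_run, classifier, feature_set, condition, n_skipped)
}

summarise_runs <- function(per_run, classifier, feature_set, condition,
                           n_skipped) {
  smry <- do.call(rbind, lapply(colnames(per_run), function(m) {
    v <- per_run[, m]
    v <- v[!is.na(v)]           # skipped runs
    n_nan <- sum(is.nan(v))
    v <- v[!is.nan(v)]
    if (!length(v)) return(data.frame(metric = m, median = NaN, lo = NaN,
                                      hi = NaN, n_nan = n_nan))
    q <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(metric = m, median = q[2], lo = q[1], hi = q[3], n_nan = n_nan)
  }))
  structure(list(classifier = classifier, feature_set = feature_set,
                 condition = condition, summary = smry, per_run = per_run,
                 n_skipped = n_skipped),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("%s | %s | %s (%d runs, %d skipped)\n", x$classifier,
              x$feature_set, x$condition, nrow(x$per_run), x$n_skipped))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    if (is.nan(s$median[i])) {
      cat(sprintf("  %-18s undefined (%d runs)\n", s$metric[i], s$n_nan[i]))
    } else {
      cat(sprintf("  %-18s %5.1f (%5.1f-%5.1f)%s\n", s$metric[i], s$median[i],
                  s$lo[i], s$hi[i],
                  if (s$n_nan[i] > 0) sprintf("  [%d undefined]", s$n_nan[i])
                  else ""))
    }
  }
  invisible(x)
}
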