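#' Select a normalizing transform by Kolmogorov-Smirnov testing
#'
#' Tests a variable for normality untransformed and after log, square-root
#' and reciprocal transformation (candidates requiring positivity are
#' skipped for non-positive data). Each candidate is compared against a
#' normal distribution with moment-estimated mean and standard deviation.
#' If the untransformed data are already non-significant the variable is
#' left alone; otherwise the candidate with the largest KS p-value among
#' the non-significant candidates is chosen, and `"none"` is recorded if
#' every candidate stays significant.
#'
#' @param x Numeric vector (NAs ignored); needs at least 8 observed values.
#' @param alpha Significance level (default 0.05).
#' @param variable Optional variable name carried into the report.
#' @return A list of class `transform_report`: `variable`, `candidates`
#'   (per-candidate KS p-value), `chosen`, `all_significant`.
#' @export
select_transform <- function(x, alpha = 0.05, variable = NA_character_) {
  x <- x[!is.na(x)]
  stop_if_not(length(x) >= 8, "need at least 8 non-missing values")
  if (stats::sd(x) == 0) stop("zero-variance input", call. = FALSE)

  cand <- list(none = identity)
  if (all(x > 0)) {
    cand$log <- log
    cand$reciprocal <- function(z) 1 / z
  }
  if (all(x >= 0)) cand$sqrt <- sqrt

  ks_p <- vapply(cand, function(f) {
    y <- f(x)
    if (stats::sd(y) == 0) return(0)
    suppressWarnings(stats::ks.test(y, "pnorm", mean(y), stats::sd(y))$p.value)
  }, numeric(1))

  if (ks_p[["none"]] > alpha) {
    chosen <- "none"; all_sig <- FALSE
  } else {
    ok <- ks_p[names(ks_p) != "none"]
    ok <- ok[ok > alpha]
    if (length(ok)) {
      chosen <- names(ok)[which.max(ok)]; all_sig <- FALSE
    } else {
      chosen <- "none"; all_sig <- TRUE
    }
  }
  structure(list(variable = variable, candidates = ks_p, chosen = chosen,
                 all_significant = all_sig, alpha = alpha),
            class = "transform_report")
}

#' Apply a chosen transform to a vector
#'
#' @param x Numeric vector.
#' @param transform One of `"none"`, `"log"`, `"sqrt"`, `"reciprocal"`.
#' @return The transformed vector.
#' @export
apply_transform <- function(x, transform) {
  switch(match.arg(transform, c("none", "log", "sqrt", "reciprocal")),
         none = x, log = log(x), sqrt = sqrt(x), reciprocal = 1 / x)
}

# Two-sided Grubbs critical value at level alpha for sample size n.
grubbs_critical <- function(n, alpha) {
  t2 <- stats::qt(1 - alpha / (2 * n), n - 2)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Iterative Grubbs outlier removal
#'
#' Repeatedly applies a two-sided Grubbs test: the statistic
#' `G = max |x_i - mean(x)| / sd(x)` is compared against the t-based
#' critical value; while significant, the maximal-deviation point is
#' replaced with `NA` and the test repeated on the remaining values, until
#' non-significance or fewer than 3 values remain. One point is removed
#' per iteration.
#'
#' @param x Numeric vector (may contain NAs); needs >= 3 observed values.
#' @param alpha Significance level per test (default 0.05).
#' @param variable Optional variable name carried into the report.
#' @return A list of class `outlier_report`: `x` (input with outliers
#'   blanked), `removed` (indices into the original vector, in removal
#'   order), `iterations` (data.frame of per-iteration `n`, `G`,
#'   `critical`, `significant`).
#' @export
grubbs_iterative <- function(x, alpha = 0.05, variable = NA_character_) {
  stop_if_not(sum(!is.na(x)) >= 3, "need at least 3 non-missing values")
  removed <- integer(0)
  iters <- data.frame(n = integer(0), G = numeric(0), critical = numeric(0),
                      significant = logical(0))
  repeat {
    obs <- which(!is.na(x))
    n <- length(obs)
    if (n < 3) break
    v <- x[obs]
    s <- stats::sd(v)
    if (s == 0) {
      iters <- rbind(iters, data.frame(n = n, G = 0,
                                       critical = grubbs_critical(n, alpha),
                                       significant = FALSE))
      break
    }
    dev <- abs(v - mean(v))
    G <- max(dev) / s
    crit <- grubbs_critical(n, alpha)
    sig <- G > crit
    iters <- rbind(iters, data.frame(n = n, G = G, critical = crit,
                                     significant = sig))
    if (!sig) break
    worst <- obs[which.max(dev)]
    x[worst] <- NA_real_
    removed <- c(removed, worst)
  }
  structure(list(variable = variable, x = x, removed = removed,
                 iterations = iters, alpha = alpha),
            class = "outlier_report")
}

#' k-nearest-neighbour imputation
#'
#' Fills each missing cell with the inverse-distance-weighted mean of the
#' values of the `k` nearest rows observed on that column. Distances are
#' Euclidean on standardized columns, averaged over the pairwise-complete
#' columns of each row pair (so rows with different missingness patterns
#' remain comparable). When a neighbour lies at zero distance a Gaussian
#' kernel (`exp(-d^2)`) replaces the inverse-distance weights. Observed
#' cells are never modified.
#'
#' @param x A data.frame or matrix of numeric columns, or a `cohort_table`
#'   (whose numeric role-tagged columns are imputed in place).
#' @param k Number of neighbours (default 3).
#' @return Object of the same shape with no remaining missing values.
#' @export
knn_impute <- function(x, k = 3L) {
  UseMethod("knn_impute")
}

#' @export
knn_impute.cohort_table <- function(x, k = 3L) {
  num_cols <- names(x$roles)
  x$data[num_cols] <- knn_impute(x$data[num_cols], k = k)
  x
}

#' @export
knn_impute.data.frame <- function(x, k = 3L) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  out <- knn_impute_matrix(m, k)
  res <- x
  res[] <- as.data.frame(out)
  res
}

#' @export
knn_impute.matrix <- function(x, k = 3L) knn_impute_matrix(x, k)

knn_impute_matrix <- function(m, k) {
  stop_if_not(k >= 1, "k must be >= 1")
  if (!anyNA(m)) return(m)
  all_na <- colSums(!is.na(m)) == 0
  if (any(all_na))
    stop("column(s) missing in all rows: ",
         paste(colnames(m)[all_na], collapse = ", "), call. = FALSE)
  if (any(rowSums(!is.na(m)) == 0))
    stop("a row has no observed values", call. = FALSE)

  mu <- colMeans(m, na.rm = TRUE)
  sdv <- apply(m, 2, stats::sd, na.rm = TRUE)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(m, 2, mu), 2, sdv, `/`)

  out <- m
  miss <- which(is.na(m), arr.ind = TRUE)
  for (idx in seq_len(nrow(miss))) {
    i <- miss[idx, 1]; j <- miss[idx, 2]
    donors <- which(!is.na(m[, j]))
    # mean squared difference over shared observed columns
    d <- vapply(donors, function(r) {
      shared <- !is.na(z[i, ]) & !is.na(z[r, ])
      if (!any(shared)) return(NA_real_)
      sqrt(mean((z[i, shared] - z[r, shared])^2))
    }, numeric(1))
    donors <- donors[!is.na(d)]; d <- d[!is.na(d)]
    stop_if_not(length(donors) >= 1, "no comparable donor rows for imputation")
    ord <- order(d)[seq_len(min(k, length(d)))]
    dk <- d[ord]
    w <- if (any(dk < 1e-12)) exp(-dk^2) else 1 / dk
    out[i, j] <- sum(w * m[donors[ord], j]) / sum(w)
  }
  out
}

#' Preprocess the metabolomic block of a cohort
#'
#' Runs the three preprocessing stages in order on every metabolomic
#' column: transform selection ([select_transform()]), iterative Grubbs
#' outlier removal ([grubbs_iterative()]; removed points become missing),
#' then kNN imputation ([knn_impute()]) of all missing cells.
#'
#' @param ct A `cohort_table`.
#' @param alpha Significance level for the KS and Grubbs tests.
#' @param k Imputation neighbour count.
#' @return A list of class `preprocess_result`: `cohort` (imputed, with
#'   transformed metabolomic columns), `transforms` (list of
#'   `transform_report`), `outliers` (list of `outlier_report`),
#'   `n_outliers_removed`.
#' @export
preprocess_cohort <- function(ct, alpha = 0.05, k = 3L) {
  validate_cohort(ct)
  metab <- names(ct$roles)[ct$roles %in% c("metabolomic_baseline",
                                           "metabolomic_delta")]
  transforms <- list(); outliers <- list()
  for (v in metab) {
    tr <- select_transform(ct$data[[v]], alpha = alpha, variable = v)
    transforms[[v]] <- tr
    y <- apply_transform(ct$data[[v]], tr$chosen)
    orp <- grubbs_iterative(y, alpha = alpha, variable = v)
    outliers[[v]] <- orp
    ct$data[[v]] <- orp$x
  }
  ct$data[metab] <- knn_impute(ct$data[metab], k = k)
  structure(list(cohort = ct, transforms = transforms, outliers = outliers,
                 n_outliers_removed = sum(vapply(outliers,
                                                 function(o) length(o$removed),
                                                 integer(1)))),
            class = "preprocess_result")
}
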