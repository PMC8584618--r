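#' Chi-squared crosstab with Pearson residuals
#'
#' Pearson chi-squared test of independence (no continuity correction)
#' between two categorical vectors, with per-cell Pearson residuals
#' `(O - E) / sqrt(E)` so significant tests can be traced to the cells
#' driving them. Levels with a zero total are dropped with a warning.
#'
#' @param a,b Categorical vectors of equal length (>= 2 levels each after
#'   dropping empty levels).
#' @return A list of class `crosstab_result`: `observed`, `expected`,
#'   `chi2`, `df`, `p`, `residuals`, `low_expected` (flag, any expected
#'   count below 5).
#' @export
crosstab_chi2 <- function(a, b) {
  stop_if_not(length(a) == length(b), "vectors must have equal length")
  tab <- table(a, b)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("dropping empty level(s)")
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  }
  stop_if_not(nrow(tab) >= 2 && ncol(tab) >= 2,
              "need at least 2 non-empty levels per variable")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(observed = tab, expected = ct$expected,
                 chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, residuals = ct$residuals,
                 low_expected = any(ct$expected < 5)),
            class = "crosstab_result")
}

#' @export
print.crosstab_result <- function(x, ...) {
  cat(sprintf("chi2 = %.4g, df = %d, p = %.4g%s\n", x$chi2, x$df, x$p,
              if (x$low_expected) "  (expected count < 5 present)" else ""))
  cat("Pearson residuals:\n")
  print(round(x$residuals, 2))
  invisible(x)
}

#' Pearson correlation matrix with Bonferroni control
#'
#' Pairwise Pearson correlations (pairwise-complete observations) with
#' two-sided t-based p-values. Significance flags are Bonferroni-corrected
#' over all unique off-diagonal pairs. Pairs involving a constant column
#' are returned as `NA` and marked.
#'
#' @param X Numeric matrix or data.frame.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A list of class `corr_matrix`: `r`, `p`, `n_pairs`,
#'   `significant` (logical, after Bonferroni), `m` (number of tested
#'   pairs), `alpha`.
#' @export
corr_matrix <- function(X, alpha = 0.05) {
  X <- as.matrix(X)
  d <- ncol(X)
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  npair <- crossprod(!is.na(X))
  stop_if_not(all(npair[upper.tri(npair)] >= 3),
              "need >= 3 complete pairs per cell")
  tstat <- r * sqrt((npair - 2) / pmax(1 - r^2, 1e-12))
  p <- 2 * stats::pt(-abs(tstat), df = npair - 2)
  diag(p) <- 0
  m <- d * (d - 1) / 2
  sig <- p < alpha / m
  diag(sig) <- NA
  sig[is.na(r)] <- NA
  structure(list(r = r, p = p, n_pairs = npair, significant = sig,
                 m = m, alpha = alpha),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("Pearson correlation matrix (%d pairs, Bonferroni alpha = %g)\n",
              x$m, x$alpha))
  print(round(x$r, 2))
  invisible(x)
}

#' Mixed repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Split-plot ANOVA with one within-subject factor (e.g., olfactory
#' subtest) and one between-subjects factor (e.g., risk category), for a
#' complete within-subject design. The Greenhouse-Geisser epsilon is
#' computed from the pooled within-group covariance of the repeated
#' measures and applied to the degrees of freedom of the within and
#' interaction effects.
#'
#' @param data Long-format data.frame.
#' @param subject,within,between,value Column names of the subject id,
#'   within-subject level, between-subjects group, and response.
#' @return A list of class `rm_anova_result`: `table` (per-effect F,
#'   uncorrected and GG-corrected df and p), `gg_epsilon`.
#' @export
rm_anova <- function(data, subject = "subject", within = "within",
                     between = "between", value = "value") {
  d <- data.frame(s = factor(data[[subject]]), w = factor(data[[within]]),
                  g = factor(data[[between]]), y = data[[value]])
  stop_if_not(!anyNA(d$y), "missing response values")
  tab <- table(d$s, d$w)
  bad <- rownames(tab)[rowSums(tab != 1) > 0]
  if (length(bad))
    stop("incomplete within-subject design for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)

  p <- nlevels(d$w); subjects <- levels(d$s)
  n <- length(subjects); g <- nlevels(d$g)
  # wide response matrix and group per subject
  Y <- matrix(NA_real_, n, p, dimnames = list(subjects, levels(d$w)))
  Y[cbind(match(d$s, subjects), match(d$w, levels(d$w)))] <- d$y
  grp <- d$g[match(subjects, d$s)]
  ng <- as.numeric(table(grp))

  grand <- mean(Y)
  m_subj <- rowMeans(Y)
  m_grp <- tapply(m_subj, grp, mean)
  m_lvl <- colMeans(Y)
  m_cell <- t(vapply(levels(grp), function(l)
    colMeans(Y[grp == l, , drop = FALSE]), numeric(p)))  # g x p

  ss_between <- p * sum(ng * (m_grp - grand)^2)
  ss_subj <- p * sum((m_subj - m_grp[grp])^2)
  ss_within <- n * sum((m_lvl - grand)^2)
  ss_inter <- sum(ng * sweep(sweep(m_cell, 1, m_grp - grand), 2, m_lvl)^2)
  gidx <- match(grp, levels(grp))
  fitted <- matrix(m_cell[cbind(gidx[as.vector(row(Y))], as.vector(col(Y)))],
                   n, p) + as.numeric(m_subj - m_grp[grp])
  ss_err <- sum((Y - fitted)^2)

  df_b <- g - 1; df_s <- n - g
  df_w <- p - 1; df_i <- (g - 1) * (p - 1); df_e <- (n - g) * (p - 1)

  # Greenhouse-Geisser epsilon from the pooled within-group covariance
  S <- Reduce(`+`, lapply(levels(grp), function(l) {
    sub <- Y[grp == l, , drop = FALSE]
    if (nrow(sub) < 2) matrix(0, p, p) else (nrow(sub) - 1) * stats::cov(sub)
  })) / (n - g)
  C <- diag(p) - 1 / p
  Sd <- C %*% S %*% C
  eps <- sum(diag(Sd))^2 / ((p - 1) * sum(Sd * Sd))
  eps <- min(max(eps, 1 / (p - 1)), 1)

  f_b <- (ss_between / df_b) / (ss_subj / df_s)
  f_w <- (ss_within / df_w) / (ss_err / df_e)
  f_i <- (ss_inter / df_i) / (ss_err / df_e)

  table_ <- data.frame(
    effect = c("between", "within", "interaction"),
    ss = c(ss_between, ss_within, ss_inter),
    df1 = c(df_b, df_w, df_i), df2 = c(df_s, df_e, df_e),
    F = c(f_b, f_w, f_i),
    df1_gg = c(df_b, df_w * eps, df_i * eps),
    df2_gg = c(df_s, df_e * eps, df_e * eps))
  table_$p <- stats::pf(table_$F, table_$df1, table_$df2, lower.tail = FALSE)
  table_$p_gg <- stats::pf(table_$F, table_$df1_gg, table_$df2_gg,
                           lower.tail = FALSE)
  structure(list(table = table_, gg_epsilon = eps), class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("Mixed rm-ANOVA (Greenhouse-Geisser epsilon = %.3f)\n",
              x$gg_epsilon))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Welch statistic with Satterthwaite degrees of freedom, two-sided.
#' When both groups are constant with equal means the result is `t = 0`,
#' `p = 1` rather than an error.
#'
#' @param x,y Numeric vectors, >= 2 values each.
#' @return A list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stop_if_not(length(x) >= 2 && length(y) >= 2, "need >= 2 values per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    return(list(t = Inf * sign(mean(x) - mean(y)),
                df = length(x) + length(y) - 2, p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
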