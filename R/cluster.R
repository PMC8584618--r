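#' Correlation-matrix PCA with Kaiser retention
#'
#' Principal component analysis on scaled, centered data (i.e., an
#' eigendecomposition of the correlation matrix). Components with
#' eigenvalues above 1 are retained for clustering (Kaiser rule).
#'
#' @param X Numeric matrix or data.frame, no missing values, >= 2
#'   non-constant columns.
#' @return A list of class `pca_result`: `eigenvalues` (descending),
#'   `scores` (subjects x components), `loadings`, `contributions`
#'   (per-variable squared-loading share of each component, in %),
#'   `retained` (count of eigenvalues > 1).
#' @export
pca_project <- function(X) {
  X <- as.matrix(X)
  stop_if_not(ncol(X) >= 2, "need at least 2 columns")
  stop_if_not(!anyNA(X), "PCA input must be complete")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  eig <- pr$sdev^2
  contrib <- sweep(pr$rotation^2, 2, colSums(pr$rotation^2), `/`) * 100
  structure(list(eigenvalues = eig, scores = pr$x, loadings = pr$rotation,
                 contributions = contrib, retained = sum(eig > 1)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("Correlation PCA:", length(x$eigenvalues), "components;",
      x$retained, "retained (eigenvalue > 1)\n")
  cat("Eigenvalues:", paste(round(x$eigenvalues, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Retained-component scores of a PCA
#'
#' @param pca A `pca_result`.
#' @return Score matrix restricted to the Kaiser-retained components.
#' @export
retained_scores <- function(pca) {
  pca$scores[, seq_len(max(pca$retained, 1L)), drop = FALSE]
}

# Total within-cluster sum of squares of a labelled partition.
partition_wss <- function(X, labels) {
  sum(vapply(unique(labels), function(l) {
    sub <- X[labels == l, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1)))
}

#' Ward hierarchical clustering consolidated by k-means
#'
#' Builds a Ward tree (Lance-Williams Ward criterion on Euclidean
#' distances, `hclust` method `"ward.D2"`), cuts it at `k`, then runs a
#' single k-means (Lloyd iterations) initialized at the cut partition's
#' centroids to consolidate the partition. Consolidation can only lower
#' the total within-cluster sum of squares.
#'
#' @param scores Numeric matrix of (typically PCA) coordinates.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return A list of class `cluster_solution`: `k`, `labels`,
#'   `labels_ward` (pre-consolidation), `wss`, `wss_ward`,
#'   `avg_silhouette` (NA for `k = 1`), `changed` (labels moved by
#'   consolidation).
#' @export
ward_kmeans <- function(scores, k) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stop_if_not(k >= 1 && k <= n, "k must lie in [1, n]")
  if (k == 1) {
    labels <- rep(1L, n)
    wss <- partition_wss(scores, labels)
    return(structure(list(k = 1L, labels = labels, labels_ward = labels,
                          wss = wss, wss_ward = wss, avg_silhouette = NA_real_,
                          changed = 0L),
                     class = "cluster_solution"))
  }
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  lw <- stats::cutree(hc, k = k)
  centers <- do.call(rbind, lapply(seq_len(k), function(l)
    colMeans(scores[lw == l, , drop = FALSE])))
  km <- tryCatch(
    suppressWarnings(stats::kmeans(scores, centers = centers,
                                   iter.max = 100L, algorithm = "Lloyd")),
    error = function(e) NULL)
  labels <- if (is.null(km) || length(unique(km$cluster)) < k) lw else km$cluster
  structure(list(k = as.integer(k), labels = as.integer(labels),
                 labels_ward = as.integer(lw),
                 wss = partition_wss(scores, labels),
                 wss_ward = partition_wss(scores, lw),
                 avg_silhouette = avg_silhouette(labels, scores),
                 changed = sum(labels != lw)),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Cluster solution: k = %d, sizes %s\n", x$k,
              paste(table(x$labels), collapse = "/")))
  cat(sprintf("WSS = %.3f (Ward cut %.3f, %d labels moved); silhouette = %s\n",
              x$wss, x$wss_ward, x$changed,
              ifelse(is.na(x$avg_silhouette), "-",
                     sprintf("%.3f", x$avg_silhouette))))
  invisible(x)
}

#' Average silhouette width
#'
#' Standard silhouette `s(i) = (b - a) / max(a, b)` with `a` the mean
#' distance of point `i` to its own cluster and `b` the smallest mean
#' distance to another cluster, averaged over all points. Members of
#' singleton clusters contribute 0.
#'
#' @param labels Cluster labels (>= 2 non-empty clusters).
#' @param scores Coordinate matrix.
#' @return Average silhouette width in `[-1, 1]`.
#' @export
avg_silhouette <- function(labels, scores) {
  scores <- as.matrix(scores)
  cl <- unique(labels)
  stop_if_not(length(cl) >= 2, "silhouette needs at least 2 clusters")
  D <- as.matrix(stats::dist(scores))
  n <- length(labels)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(cl, labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# ---- cluster-number index panel -------------------------------------------
# Each index maps the WSS/solution profile over k to a proposed k.
# Conventions follow the classical definitions; `sol` is a list of
# cluster_solution indexed by as.character(k) over an extended k range.

index_panel_votes <- function(scores, sol, k_range, seed = 1L) {
  n <- nrow(scores); d <- ncol(scores)
  ks <- k_range
  wss <- vapply(as.character(ks), function(k) sol[[k]]$wss, numeric(1))
  wss_ext <- function(k) {
    if (as.character(k) %in% names(sol)) sol[[as.character(k)]]$wss else NA_real_
  }
  D <- as.matrix(stats::dist(scores))

  per_k <- function(f) vapply(ks, f, numeric(1))

  # silhouette: maximise
  sil <- per_k(function(k) sol[[as.character(k)]]$avg_silhouette)
  # Calinski-Harabasz: maximise ((TSS-WSS)/(k-1)) / (WSS/(n-k))
  tss <- partition_wss(scores, rep(1L, n))
  ch <- per_k(function(k) ((tss - wss_ext(k)) / (k - 1)) / (wss_ext(k) / (n - k)))
  # Davies-Bouldin: minimise
  db <- per_k(function(k) {
    lab <- sol[[as.character(k)]]$labels
    cent <- do.call(rbind, lapply(seq_len(k), function(l)
      colMeans(scores[lab == l, , drop = FALSE])))
    sbar <- vapply(seq_len(k), function(l)
      mean(sqrt(rowSums(sweep(scores[lab == l, , drop = FALSE], 2,
                              cent[l, ])^2))), numeric(1))
    mean(vapply(seq_len(k), function(l) {
      others <- setdiff(seq_len(k), l)
      max((sbar[l] + sbar[others]) /
            sqrt(rowSums(sweep(cent[others, , drop = FALSE], 2, cent[l, ])^2)))
    }, numeric(1)))
  })
  # Hartigan: smallest k with H(k) <= 10, H(k) = (W_k/W_{k+1} - 1)(n - k - 1)
  hart <- vapply(ks, function(k) {
    w1 <- wss_ext(k + 1)
    if (is.na(w1) || w1 == 0) return(NA_real_)
    (wss_ext(k) / w1 - 1) * (n - k - 1)
  }, numeric(1))
  # Krzanowski-Lai: maximise |DIFF_k / DIFF_{k+1}|
  diffk <- function(k) {
    w0 <- wss_ext(k - 1); w1 <- wss_ext(k)
    if (is.na(w0) || is.na(w1)) return(NA_real_)
    (k - 1)^(2 / d) * w0 - k^(2 / d) * w1
  }
  kl <- vapply(ks, function(k) {
    dk <- diffk(k); dk1 <- diffk(k + 1)
    if (is.na(dk) || is.na(dk1) || dk1 == 0) return(NA_real_)
    abs(dk / dk1)
  }, numeric(1))
  # Dunn: maximise min-between / max-within distance
  dunn <- per_k(function(k) {
    lab <- sol[[as.character(k)]]$labels
    within_max <- max(vapply(unique(lab), function(l) {
      idx <- which(lab == l)
      if (length(idx) < 2) 0 else max(D[idx, idx])
    }, numeric(1)))
    between_min <- min(vapply(utils::combn(unique(lab), 2, simplify = FALSE),
                              function(pr) min(D[lab == pr[1], lab == pr[2]]),
                              numeric(1)))
    if (within_max == 0) NA_real_ else between_min / within_max
  })
  # C-index: minimise (S - Smin)/(Smax - Smin) over within-cluster pair sums
  dv <- sort(D[upper.tri(D)])
  cind <- per_k(function(k) {
    lab <- sol[[as.character(k)]]$labels
    within <- outer(lab, lab, "==") & upper.tri(D)
    nw <- sum(within)
    S <- sum(D[within])
    smin <- sum(dv[seq_len(nw)]); smax <- sum(rev(dv)[seq_len(nw)])
    if (smax == smin) NA_real_ else (S - smin) / (smax - smin)
  })
  # McClain-Rao: minimise mean-within / mean-between distance
  mcr <- per_k(function(k) {
    lab <- sol[[as.character(k)]]$labels
    same <- outer(lab, lab, "==") & upper.tri(D)
    diffm <- (!outer(lab, lab, "==")) & upper.tri(D)
    mean(D[same]) / mean(D[diffm])
  })
  # Ball-Hall: maximise the drop in W_k / k between successive k
  bh_val <- vapply(c(ks[1] - 1, ks), function(k) {
    w <- wss_ext(k); if (is.na(w)) NA_real_ else w / k
  }, numeric(1))
  bh <- -diff(bh_val)  # drop from k-1 to k, aligned with ks
  # Gap statistic (uniform reference over the bounding box, B references):
  # smallest k with Gap(k) >= Gap(k+1) - s_{k+1}
  B <- 10L
  rng <- apply(scores, 2, range)
  ks_gap <- c(ks, max(ks) + 1L)
  log_w_ref <- with_seed(seed, {
    vapply(ks_gap, function(k) {
      refs <- vapply(seq_len(B), function(b) {
        ref <- apply(rng, 2, function(r) stats::runif(n, r[1], r[2]))
        km <- suppressWarnings(stats::kmeans(ref, centers = k, nstart = 3,
                                             iter.max = 50))
        log(max(km$tot.withinss, 1e-300))
      }, numeric(1))
      c(mean(refs), stats::sd(refs) * sqrt(1 + 1 / B))
    }, numeric(2))
  })
  gap <- log_w_ref[1, ] - log(vapply(ks_gap, wss_ext, numeric(1)))
  sk <- log_w_ref[2, ]
  gap_choice <- NA_integer_
  for (i in seq_along(ks)) {
    if (!is.na(gap[i]) && !is.na(gap[i + 1]) &&
        gap[i] >= gap[i + 1] - sk[i + 1]) { gap_choice <- ks[i]; break }
  }
  if (is.na(gap_choice)) gap_choice <- ks[length(ks)]

  pick <- function(vals, maximise = TRUE) {
    if (all(is.na(vals))) return(NA_integer_)
    ks[if (maximise) which.max(vals) else which.min(vals)]
  }
  hart_choice <- {
    ok <- which(!is.na(hart) & hart <= 10)
    if (length(ok)) ks[min(ok)] else ks[which.min(hart)]
  }
  c(silhouette = pick(sil), calinski_harabasz = pick(ch),
    davies_bouldin = pick(db, FALSE), hartigan = hart_choice,
    krzanowski_lai = pick(kl), dunn = pick(dunn),
    c_index = pick(cind, FALSE), mcclain_rao = pick(mcr, FALSE),
    ball_hall = pick(bh), gap = gap_choice)
}

#' Choose the cluster count by index majority vote
#'
#' Evaluates a panel of ten cluster-number indices (average silhouette,
#' Calinski-Harabasz, Davies-Bouldin, Hartigan, Krzanowski-Lai, Dunn,
#' C-index, McClain-Rao, Ball-Hall, gap statistic) over Ward + k-means
#' solutions for each `k` in `k_range`. The cluster count proposed by the
#' largest number of indices wins; ties break toward the smaller `k`.
#'
#' @param scores Coordinate matrix (typically retained PCA scores).
#' @param k_range Candidate counts, a subset of `[2, n - 1]`.
#' @param seed Seed for the gap statistic's reference draws.
#' @return A list of class `k_selection`: `k`, `votes` (per-index
#'   proposal), `tally`, `solutions` (per-k `cluster_solution`).
#' @export
choose_k <- function(scores, k_range = 2:8, seed = 1L) {
  scores <- as.matrix(scores)
  stop_if_not(length(k_range) >= 1, "empty k_range")
  k_range <- sort(unique(as.integer(k_range)))
  stop_if_not(min(k_range) >= 2 && max(k_range) <= nrow(scores) - 1,
              "k_range must lie within [2, n - 1]")
  ext <- (min(k_range) - 1L):min(max(k_range) + 1L, nrow(scores))
  sol <- stats::setNames(lapply(ext, function(k) ward_kmeans(scores, k)),
                         as.character(ext))
  votes <- index_panel_votes(scores, sol, k_range, seed = seed)
  tally <- table(factor(votes[!is.na(votes)], levels = k_range))
  k <- as.integer(names(tally)[which.max(tally)])  # ties -> smaller k
  structure(list(k = k, votes = votes, tally = tally,
                 solutions = sol[as.character(k_range)]),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Cluster-count majority vote: k =", x$k, "\n")
  print(x$votes)
  invisible(x)
}
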