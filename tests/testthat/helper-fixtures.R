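# Shared fixtures, built in code at test time.

# The mixture parameters printed for the cohort's TDI distribution.
printed_mixture <- function() {
  structure(list(means = c(24.9, 34.32), sds = c(3.42, 3.2),
                 weights = c(0.167, 0.83) / sum(c(0.167, 0.83)), M = 2L),
            class = "gmm_fit")
}

# k Gaussian blobs in d dimensions, centres `sep` apart along each axis.
make_blobs <- function(n_per, centres, d = 2, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centres)), function(i) {
      matrix(rnorm(n_per * d, sd = sd), n_per, d) +
        matrix(centres[i, ], n_per, d, byrow = TRUE)
    }))
    list(X = X, labels = rep(seq_len(nrow(centres)), each = n_per))
  })
}

# Best label agreement over the two possible 2-cluster permutations.
two_cluster_agreement <- function(a, b) {
  max(mean(a == b), mean(a == (3 - b)))
}

null_cohort <- function(seed, n = 163) {
  generate_cohort(generator_config(n = n, seed = seed))
}

# All permutations of 1..n (tiny n only), for ordering-enumeration oracles.
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(combinat_perms(n - 1), function(p) c(i, p + (p >= i)))
  }))
}
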