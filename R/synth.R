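#' Column roles recognised in a cohort table
#'
#' @format Character vector of the role tags a cohort manifest may use.
#' @export
cohort_roles <- c(
  "olfactory_subtest", "olfactory_total", "risk_score",
  "metabolomic_baseline", "metabolomic_delta", "demographic", "confounder"
)

.metab_baseline_vars <- c(
  "triglycerides", "cholesterol", "ldl", "hdl", "hba1c",
  "glucose", "ffa", "proinsulin", "cpeptide", "insulin"
)
.metab_delta_vars <- c("d_glucose", "d_ffa", "d_proinsulin", "d_cpeptide", "d_insulin")

# Loosely realistic clinical units per metabolomic variable (mean, sd);
# the generator works on the z scale and maps to units at the end.
.metab_units <- rbind(
  triglycerides = c(130, 60), cholesterol = c(200, 35), ldl = c(125, 30),
  hdl = c(55, 14), hba1c = c(5.6, 0.5), glucose = c(95, 12),
  ffa = c(0.55, 0.2), proinsulin = c(8, 4), cpeptide = c(2.0, 0.8),
  insulin = c(10, 5), d_glucose = c(45, 25), d_ffa = c(-0.3, 0.15),
  d_proinsulin = c(12, 8), d_cpeptide = c(2.5, 1.2), d_insulin = c(40, 25)
)

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the statistical structure the analysis pipeline
#' assumes: a bimodal olfactory TDI score (two-component Gaussian mixture
#' with means 24.9 and 34.32, standard deviations 3.42 and 3.2, and weights
#' 0.167 and 0.83), a unimodal integer FINDRISK diabetes-risk score, and a
#' 15-variable metabolomics block (10 baseline markers + 5 post-glucose
#' challenge deltas) carrying an implanted two-cluster structure that is
#' correlated with the risk score but — by default — independent of
#' olfaction (the null configuration).
#'
#' @param n Number of subjects.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param tdi_mixture List with `means`, `sds`, `weights` of the TDI mixture.
#' @param risk_mean,risk_sd Gaussian parameters of the latent FINDRISK score
#'   before rounding and clipping to `[0, 26]`.
#' @param cluster_shift Mean offset (in pre-shift SD units) between the two
#'   latent metabolomics clusters, applied to `cluster_vars`. The default
#'   2.0 keeps the implanted structure recoverable by the
#'   PCA-Ward-k-means pipeline (roughly 96% Bayes-optimal assignment
#'   accuracy given the within-block correlation).
#' @param cluster_vars Names of metabolomic variables carrying the shift.
#' @param risk_metabolome_slope Strength of the linear link between the
#'   latent risk score and every metabolomic variable (HDL gets a negative
#'   sign, all other variables a positive one).
#' @param risk_cluster_link Logistic slope tying cluster membership to the
#'   latent risk score, so the clusters are unequally represented across
#'   risk categories.
#' @param block_cor Within-block correlation of the metabolomics variables
#'   before shifts are applied.
#' @param olfaction_association Logical; implant a TDI–risk/metabolome
#'   dependence (default `FALSE` = the null configuration).
#' @param olfaction_effect Effect size in TDI points per SD of latent risk,
#'   used only when `olfaction_association` is `TRUE`.
#' @param n_missing Number of cells blanked in the metabolomic delta columns.
#' @param n_outliers Number of extreme values injected into metabolomic
#'   columns.
#' @param outlier_magnitude Outlier distance from the column mean, in
#'   column SD multiples.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n = 163L, seed = 1L,
                             tdi_mixture = list(means = c(24.9, 34.32),
                                                sds = c(3.42, 3.2),
                                                weights = c(0.167, 0.83)),
                             risk_mean = 11.5, risk_sd = 4,
                             cluster_shift = 2.0,
                             cluster_vars = c("glucose", "hba1c", "insulin",
                                              "proinsulin", "cpeptide",
                                              "triglycerides", "d_glucose",
                                              "d_insulin"),
                             risk_metabolome_slope = 0.3,
                             risk_cluster_link = 1.0,
                             block_cor = 0.3,
                             olfaction_association = FALSE,
                             olfaction_effect = 3,
                             n_missing = 6L, n_outliers = 12L,
                             outlier_magnitude = 8) {
  cfg <- list(n = as.integer(n), seed = seed, tdi_mixture = tdi_mixture,
              risk_mean = risk_mean, risk_sd = risk_sd,
              cluster_shift = cluster_shift, cluster_vars = cluster_vars,
              risk_metabolome_slope = risk_metabolome_slope,
              risk_cluster_link = risk_cluster_link, block_cor = block_cor,
              olfaction_association = isTRUE(olfaction_association),
              olfaction_effect = olfaction_effect,
              n_missing = as.integer(n_missing),
              n_outliers = as.integer(n_outliers),
              outlier_magnitude = outlier_magnitude)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  mx <- cfg$tdi_mixture
  stop_if_not(length(mx$means) == length(mx$sds) &&
              length(mx$sds) == length(mx$weights),
              "tdi_mixture components must have equal lengths")
  # printed mixture weights are rounded; renormalise small discrepancies
  if (abs(sum(mx$weights) - 1) > 0.01)
    stop("tdi_mixture weights must sum to 1", call. = FALSE)
  cfg$tdi_mixture$weights <- mx$weights / sum(mx$weights)
  if (any(mx$sds <= 0)) stop("tdi_mixture sds must be positive", call. = FALSE)
  stop_if_not(cfg$n >= 0, "n must be non-negative")
  stop_if_not(cfg$risk_sd > 0, "risk_sd must be positive")
  n_cells <- cfg$n * (length(.metab_baseline_vars) + length(.metab_delta_vars))
  if (cfg$n > 0 && cfg$n_missing + cfg$n_outliers >= n_cells)
    stop("n_missing + n_outliers must be smaller than the metabolomic cell count",
         call. = FALSE)
  invisible(cfg)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort with the structure described in [generator_config()]:
#' the TDI olfactory total is sampled from the configured Gaussian mixture
#' and decomposed into threshold / discrimination / identification subtests
#' (sum identity preserved exactly); the FINDRISK score is unimodal,
#' rounded and clipped to `[0, 26]`, and correlated with age and BMI; the
#' metabolomics block carries two latent clusters linked to the risk score;
#' age is negatively correlated with odor identification. Outliers and
#' missing values are injected into the metabolomic columns last.
#'
#' @param config A [generator_config()].
#' @return A list of class `cohort_table` with elements `data` (one row per
#'   subject), `roles` (named character vector mapping column to role), and
#'   `truth` (latent mode / cluster labels and injected cell positions —
#'   a sidecar for oracles, never part of the analysis-facing table).
#' @export
generate_cohort <- function(config = generator_config()) {
  config <- validate_generator_config(config)
  n <- config$n
  metab_vars <- c(.metab_baseline_vars, .metab_delta_vars)
  col_order <- c("threshold", "discrimination", "identification", "tdi",
                 "findrisk", metab_vars, "age", "bmi", "sex", "smoker")
  roles <- c(threshold = "olfactory_subtest", discrimination = "olfactory_subtest",
             identification = "olfactory_subtest", tdi = "olfactory_total",
             findrisk = "risk_score",
             stats::setNames(rep("metabolomic_baseline", 10), .metab_baseline_vars),
             stats::setNames(rep("metabolomic_delta", 5), .metab_delta_vars),
             age = "demographic", bmi = "demographic", sex = "demographic",
             smoker = "confounder")
  roles <- roles[col_order]

  if (n == 0L) {
    data <- as.data.frame(stats::setNames(
      c(list(character(0)), rep(list(numeric(0)), length(col_order))),
      c("subject_id", col_order)))
    out <- list(data = data, roles = roles,
                truth = list(mode = integer(0), cluster = integer(0),
                             outlier_cells = data.frame(row = integer(0),
                                                        column = character(0)),
                             missing_cells = data.frame(row = integer(0),
                                                        column = character(0))))
    class(out) <- "cohort_table"
    return(out)
  }

  with_seed(config$seed, {
    mx <- config$tdi_mixture
    M <- length(mx$means)

    # demographics and latent risk
    z_age <- stats::rnorm(n)
    z_bmi <- 0.2 * z_age + sqrt(1 - 0.2^2) * stats::rnorm(n)
    e_r <- stats::rnorm(n)
    # age and BMI enter the risk score with moderate weights
    # (r_age,risk ~ 0.41); the residual variance keeps z_risk at unit
    # variance analytically
    a_w <- 0.35; b_w <- 0.30
    v <- a_w^2 + b_w^2 + 2 * a_w * b_w * 0.2
    z_risk <- a_w * z_age + b_w * z_bmi + sqrt(1 - v) * e_r
    findrisk <- pmin(pmax(round(config$risk_mean + config$risk_sd * z_risk), 0), 26)
    age <- round(pmin(pmax(52.9 + 12.7 * z_age, 18), 80))
    bmi <- round(27 + 4.5 * z_bmi, 1)
    sex <- stats::rbinom(n, 1, 0.5)
    smoker <- stats::rbinom(n, 1, 0.25)

    # olfactory total from the mixture, optional implanted risk dependence
    mode <- sample.int(M, n, replace = TRUE, prob = mx$weights)
    tdi <- stats::rnorm(n, mx$means[mode], mx$sds[mode])
    if (config$olfaction_association)
      tdi <- tdi - config$olfaction_effect * z_risk
    tdi <- pmin(pmax(tdi, 1), 48)

    # decompose TDI into subtests; identification share declines with age
    # (r_age,ident ~ -0.25). The tilt acts through age itself, so
    # identification carries no partial effect on the risk score once age
    # is accounted for, and the indirect identification-risk correlation
    # (r_age,ident x r_age,risk ~ -0.10) stays below reliable
    # detectability at the cohort size - the control-correlation pattern
    # of an olfaction-null cohort.
    w_t <- 0.25 * exp(stats::rnorm(n, 0, 0.12))
    w_d <- 0.375 * exp(stats::rnorm(n, 0, 0.12))
    w_i <- 0.375 * exp(stats::rnorm(n, 0, 0.12) - 0.07 * z_age)
    tot <- w_t + w_d + w_i
    disc <- pmin(pmax(round(tdi * w_d / tot), 0), 16)
    iden <- pmin(pmax(round(tdi * w_i / tot), 0), 16)
    thr <- tdi - disc - iden
    # keep the threshold subtest within its instrument range, sum preserved
    over <- thr > 16
    if (any(over)) {
      shift <- ceiling(thr[over] - 16)
      disc[over] <- pmin(disc[over] + shift, 16)
      thr[over] <- tdi[over] - disc[over] - iden[over]
    }
    under <- thr < 0
    if (any(under)) {
      take <- pmin(ceiling(-thr[under]), disc[under])
      disc[under] <- disc[under] - take
      thr[under] <- tdi[under] - disc[under] - iden[under]
    }

    # metabolomics: block-correlated z, risk slope, then cluster shift
    cluster <- 1L + stats::rbinom(n, 1, stats::plogis(-config$risk_cluster_link * z_risk))
    # cluster 1 sits on the high-risk side, cluster 2 on the low-risk side
    f_base <- stats::rnorm(n)
    f_delta <- stats::rnorm(n)
    slope <- config$risk_metabolome_slope
    Z <- sapply(metab_vars, function(v) {
      blk <- if (v %in% .metab_baseline_vars) f_base else f_delta
      sgn <- if (v == "hdl") -1 else 1
      z <- sqrt(config$block_cor) * blk +
        sqrt(1 - config$block_cor) * stats::rnorm(n) + slope * sgn * z_risk
      z / sqrt(1 + slope^2)
    })
    shift_dir <- ifelse(cluster == 1L, 0.5, -0.5)
    for (v in intersect(config$cluster_vars, metab_vars))
      Z[, v] <- Z[, v] + config$cluster_shift * shift_dir
    metab <- sweep(sweep(Z, 2, .metab_units[metab_vars, 2], `*`),
                   2, .metab_units[metab_vars, 1], `+`)

    data <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                       threshold = thr, discrimination = disc,
                       identification = iden, tdi = tdi, findrisk = findrisk,
                       metab, age = age, bmi = bmi, sex = sex,
                       smoker = smoker, check.names = FALSE)

    # inject outliers first (positions recorded), then missingness,
    # on disjoint metabolomic cells
    n_cells <- n * length(metab_vars)
    n_inj <- config$n_outliers + config$n_missing
    outlier_cells <- data.frame(row = integer(0), column = character(0))
    missing_cells <- data.frame(row = integer(0), column = character(0))
    if (config$n_outliers > 0) {
      cells <- sample.int(n_cells, config$n_outliers)
      rows <- ((cells - 1L) %% n) + 1L
      cols <- metab_vars[((cells - 1L) %/% n) + 1L]
      for (j in seq_along(cells)) {
        v <- cols[j]
        mu <- mean(data[[v]]); sdv <- stats::sd(data[[v]])
        data[rows[j], v] <- mu + sample(c(-1, 1), 1) *
          (config$outlier_magnitude + 0.5) * sdv
      }
      outlier_cells <- data.frame(row = rows, column = cols)
    }
    if (config$n_missing > 0) {
      # missing values emulate unmeasured post-challenge assays
      delta_cells <- as.matrix(expand.grid(row = seq_len(n),
                                           column = seq_along(.metab_delta_vars)))
      taken <- paste(outlier_cells$row, outlier_cells$column)
      avail <- !(paste(delta_cells[, 1], .metab_delta_vars[delta_cells[, 2]]) %in% taken)
      pick <- delta_cells[sample(which(avail), config$n_missing), , drop = FALSE]
      for (j in seq_len(nrow(pick)))
        data[pick[j, 1], .metab_delta_vars[pick[j, 2]]] <- NA_real_
      missing_cells <- data.frame(row = pick[, 1],
                                  column = .metab_delta_vars[pick[, 2]])
    }

    out <- list(data = data, roles = roles,
                truth = list(mode = mode, cluster = cluster,
                             z_risk = z_risk,
                             outlier_cells = outlier_cells,
                             missing_cells = missing_cells))
    class(out) <- "cohort_table"
    validate_cohort(out)
    out
  })
}

#' Validate a cohort table's structural invariants
#'
#' Checks the olfactory sum identity (TDI = threshold + discrimination +
#' identification on complete rows), score ranges, and role consistency.
#'
#' @param ct A `cohort_table`.
#' @return The cohort, invisibly; errors on violation.
#' @export
validate_cohort <- function(ct) {
  stop_if_not(inherits(ct, "cohort_table"), "not a cohort_table")
  stop_if_not(all(ct$roles %in% cohort_roles), "unknown column role")
  stop_if_not(all(names(ct$roles) %in% names(ct$data)),
              "manifest names a column absent from the data")
  d <- ct$data
  if (nrow(d) > 0) {
    sub <- names(ct$roles)[ct$roles == "olfactory_subtest"]
    tot <- names(ct$roles)[ct$roles == "olfactory_total"]
    if (length(sub) == 3 && length(tot) == 1) {
      cc <- stats::complete.cases(d[, c(sub, tot)])
      if (any(cc) &&
          max(abs(rowSums(d[cc, sub, drop = FALSE]) - d[cc, tot])) > 1e-9)
        stop("olfactory subtests do not sum to the total score", call. = FALSE)
      if (any(d[cc, tot] < 1 | d[cc, tot] > 48))
        stop("olfactory total outside [1, 48]", call. = FALSE)
    }
    rs <- names(ct$roles)[ct$roles == "risk_score"]
    if (length(rs) == 1) {
      v <- d[[rs]][!is.na(d[[rs]])]
      if (any(v < 0) || any(v != round(v)))
        stop("risk score must be a non-negative integer", call. = FALSE)
    }
  }
  invisible(ct)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$data), "subjects,",
      length(x$roles), "role-tagged variables\n")
  cat("Roles:", paste(sprintf("%s (%d)", names(table(x$roles)),
                              table(x$roles)), collapse = ", "), "\n")
  n_miss <- sum(is.na(x$data[names(x$roles)]))
  cat("Missing cells:", n_miss, "\n")
  invisible(x)
}

#' Extract role-tagged columns from a cohort
#'
#' @param ct A `cohort_table`.
#' @param roles Roles to select (see [cohort_roles]).
#' @return A data.frame of the matching columns, in manifest order.
#' @export
cohort_columns <- function(ct, roles) {
  stop_if_not(all(roles %in% cohort_roles), "unknown role requested")
  ct$data[, names(ct$roles)[ct$roles %in% roles], drop = FALSE]
}

#' Write / read a cohort as CSV plus JSON role manifest
#'
#' The CSV has one row per subject and an empty cell for missing values;
#' the JSON sidecar maps each column to its role.
#'
#' @param ct A `cohort_table`.
#' @param prefix Path prefix; writes `<prefix>.csv` and `<prefix>_roles.json`.
#' @return `write_cohort`: the prefix, invisibly. `read_cohort`: a
#'   `cohort_table` (without the latent-truth sidecar).
#' @export
write_cohort <- function(ct, prefix) {
  utils::write.csv(ct$data, paste0(prefix, ".csv"), row.names = FALSE, na = "")
  jsonlite::write_json(as.list(ct$roles), paste0(prefix, "_roles.json"),
                       auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(prefix) {
  data <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE,
                          na.strings = "")
  roles <- unlist(jsonlite::read_json(paste0(prefix, "_roles.json")))
  out <- list(data = data, roles = roles, truth = NULL)
  class(out) <- "cohort_table"
  validate_cohort(out)
}

#' Clinical category maps for the FINDRISK and TDI scores
#'
#' FINDRISK scores map to five ordinal diabetes-risk categories with
#' 10-year risk percentages 1 / 4 / 17 / 33 / 50 (score bins `< 7`,
#' `7–11`, `12–14`, `15–20`, `> 20`); TDI maps to functional anosmia
#' (`< 16.5`), hyposmia (`16.5–30.5`) and normosmia (`> 30.5`).
#'
#' @return A list of class `category_map` with `risk_bins` and `tdi_bins`.
#' @export
default_category_map <- function() {
  map <- list(
    risk_bins = data.frame(
      lower = c(0, 7, 12, 15, 21), upper = c(7, 12, 15, 21, Inf),
      label = c("low risk", "slightly increased", "medium risk",
                "high risk", "very high"),
      risk_percent = c(1, 4, 17, 33, 50)),
    tdi_bins = data.frame(
      lower = c(1, 16.5, 30.5), upper = c(16.5, 30.5, 48),
      label = c("anosmia", "hyposmia", "normosmia"))
  )
  class(map) <- "category_map"
  validate_category_map(map)
  map
}

validate_category_map <- function(map) {
  rb <- map$risk_bins; tb <- map$tdi_bins
  stop_if_not(all(rb$lower[-1] == rb$upper[-nrow(rb)]),
              "risk bins must partition the score range")
  stop_if_not(all(diff(rb$risk_percent) > 0),
              "risk percentages must be strictly increasing")
  stop_if_not(all(tb$lower[-1] == tb$upper[-nrow(tb)]),
              "TDI bins must partition the score range")
  invisible(map)
}

#' Categorize a FINDRISK score
#'
#' @param score Non-negative integer score(s).
#' @param map A [default_category_map()].
#' @return A data.frame with `label` and `risk_percent` (10-year risk, %).
#' @examples
#' categorize_risk(13)  # medium risk, 17%
#' @export
categorize_risk <- function(score, map = default_category_map()) {
  if (any(is.na(score)) || any(score < 0))
    stop("risk score must be non-negative", call. = FALSE)
  rb <- map$risk_bins
  idx <- findInterval(score, rb$lower)
  data.frame(label = rb$label[idx], risk_percent = rb$risk_percent[idx])
}

#' Categorize a TDI olfactory score
#'
#' Scores below 16.5 are functional anosmia, 16.5–30.5 hyposmia, above
#' 30.5 normosmia.
#'
#' @param tdi TDI score(s) in `[1, 48]`.
#' @param map A [default_category_map()].
#' @return Character vector of category labels.
#' @examples
#' categorize_tdi(c(16, 25, 31))
#' @export
categorize_tdi <- function(tdi, map = default_category_map()) {
  if (any(is.na(tdi)) || any(tdi < 1 | tdi > 48))
    stop("TDI must lie in [1, 48]", call. = FALSE)
  tb <- map$tdi_bins
  # the hyposmia band is closed: scores exactly at 16.5 or 30.5 are hyposmic
  idx <- ifelse(tdi < 16.5, 1L, ifelse(tdi <= 30.5, 2L, 3L))
  tb$label[idx]
}
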