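#' Greedy LD clumping of summary statistics
#'
#' Visits variants by ascending P value (ties broken by chromosome then
#' position) and keeps each one unless its squared dosage correlation with
#' an already-kept variant on the same chromosome within `window_kb`
#' exceeds `r2_threshold` — the clumping step of a clumping + thresholding
#' polygenic score.
#'
#' @param sumstats Summary-statistics tibble (needs `snv_id`, `chrom`,
#'   `pos`, `p`).
#' @param reference Source of LD: a [genotype_cohort()] or a reference panel
#'   from [simulate_reference()] (anything with `$dosages`/`$genotypes` and
#'   matching variant ids).
#' @param r2_threshold Squared-correlation cutoff (default 0.1).
#' @param window_kb Physical window half-width in kilobases (default 250).
#' @param keep_unmatched Keep variants missing from the reference,
#'   unclumped (`TRUE`), or drop them (default `FALSE`). More than 5%
#'   missing triggers a warning either way.
#' @return The retained rows of `sumstats`, in the input order.
#' @export
clump_snvs <- function(sumstats, reference, r2_threshold = 0.1,
                       window_kb = 250, keep_unmatched = FALSE) {
  ref <- reference_dosages(reference)
  idx_ref <- match(sumstats$snv_id, ref$snv_id)
  missing <- is.na(idx_ref)
  if (mean(missing) > 0.05) {
    warn(sprintf("reference panel is missing %d/%d variants (%.1f%%)",
                 sum(missing), length(missing), 100 * mean(missing)))
  }

  ord <- order(sumstats$p, sumstats$chrom, sumstats$pos)
  ord <- ord[!missing[ord]]
  keep <- logical(nrow(sumstats))
  window <- window_kb * 1000
  D <- ref$dosages
  kept_by_chrom <- split(integer(0), character(0))
  for (i in ord) {
    chr <- sumstats$chrom[i]
    prior <- kept_by_chrom[[chr]]
    ok <- TRUE
    if (length(prior) > 0) {
      near <- prior[abs(sumstats$pos[prior] - sumstats$pos[i]) <= window]
      if (length(near) > 0) {
        r2 <- suppressWarnings(
          cor(D[, idx_ref[i]], D[, idx_ref[near], drop = FALSE])^2
        )
        if (any(r2 > r2_threshold, na.rm = TRUE)) ok <- FALSE
      }
    }
    if (ok) {
      keep[i] <- TRUE
      kept_by_chrom[[chr]] <- c(prior, i)
    }
  }
  if (keep_unmatched) keep[missing] <- TRUE
  sumstats[keep, ]
}

reference_dosages <- function(reference) {
  if (inherits(reference, "genotype_cohort")) {
    return(list(dosages = reference$dosages, snv_id = reference$snvs$snv_id))
  }
  if (is.list(reference) && !is.null(reference$genotypes) &&
      !is.null(reference$snvs)) {
    return(list(dosages = reference$genotypes, snv_id = reference$snvs$snv_id))
  }
  stop_gwasdiff("unsupported reference type for LD lookup",
                "gwasdiff_error_schema")
}

#' Score individuals with per-variant weights
#'
#' Computes the weighted allele sum `S_i = sum_j beta_j g_ij` over the
#' weight variants with `p <= threshold`. Weights are first aligned to the
#' cohort's effect alleles with the same swap/flip rules as
#' [harmonize_sumstats()]; variants whose alleles cannot be reconciled (or
#' that are absent from the cohort) are dropped with a message. Missing
#' dosages are mean-imputed per variant.
#'
#' @param cohort A [genotype_cohort()].
#' @param weights Tibble with `snv_id`, `effect_allele`, `other_allele`,
#'   `beta` and (if thresholding is wanted) `p` — e.g. a summary-statistics
#'   table.
#' @param threshold P-value cutoff for inclusion (default 1: all variants).
#' @return A tibble with columns `id`, `raw` and `z` (the score standardized
#'   to zero mean and unit variance across the cohort).
#' @export
prs_score <- function(cohort, weights, threshold = 1) {
  if ("p" %in% names(weights)) {
    weights <- dplyr::filter(weights, .data$p <= threshold)
  }
  if (nrow(weights) == 0) {
    stop_gwasdiff("no variants pass the threshold", "gwasdiff_error_empty")
  }
  snvs <- cohort$snvs
  j <- match(weights$snv_id, snvs$snv_id)
  present <- !is.na(j)

  action <- rep(NA_character_, nrow(weights))
  wa1 <- weights$effect_allele[present]
  wa2 <- weights$other_allele[present]
  ca1 <- snvs$effect_allele[j[present]]
  ca2 <- snvs$other_allele[j[present]]
  cwa1 <- complement_base(wa1)
  cwa2 <- complement_base(wa2)
  act <- rep(NA_character_, sum(present))
  act[wa1 == ca1 & wa2 == ca2] <- "identity"
  act[is.na(act) & wa1 == ca2 & wa2 == ca1] <- "swap"
  act[is.na(act) & cwa1 == ca1 & cwa2 == ca2] <- "flip"
  act[is.na(act) & cwa1 == ca2 & cwa2 == ca1] <- "swap_flip"
  action[present] <- act

  usable <- !is.na(action)
  if (!all(usable)) {
    inform(sprintf("dropping %d weight variant(s) unmatched in the cohort",
                   sum(!usable)))
  }
  if (!any(usable)) {
    stop_gwasdiff("no weight variants usable in this cohort",
                  "gwasdiff_error_empty")
  }
  beta <- ifelse(action[usable] %in% c("swap", "swap_flip"),
                 -weights$beta[usable], weights$beta[usable])
  cols <- j[usable]
  D <- cohort$dosages[, cols, drop = FALSE]
  if (anyNA(D)) D <- impute_col_mean(D)
  raw <- drop(D %*% beta)
  s <- sd(raw)
  tibble::tibble(
    id = cohort$samples$id,
    raw = raw,
    z = if (s > 0) (raw - mean(raw)) / s else raw * 0
  )
}

#' Logistic association of a polygenic score with a binary phenotype
#'
#' Fits `phenotype ~ standardized PRS + covariates` by logistic regression
#' (iteratively reweighted least squares via [stats::glm()]) and reports the
#' Wald estimate for the PRS term: log-OR per standard deviation of score,
#' its standard error, two-sided P, and the OR with a 95% Wald interval.
#' Perfect separation is detected and raised as an error rather than
#' reported as an unstable estimate.
#'
#' @param prs Output of [prs_score()] (its `z` column is used), or a numeric
#'   vector of scores.
#' @param phenotype Binary vector (0/1 or logical), one per individual.
#' @param covariates Optional numeric matrix or data frame of covariates.
#' @return An object of class `prs_fit`: `beta`, `se`, `z`, `p`, `or`,
#'   `or_lower`, `or_upper`, `n`, `n_cases`, `ll_null` (covariates-only
#'   model), `ll_full`, `r2_nagelkerke`, `auc`.
#' @export
associate_prs <- function(prs, phenotype, covariates = NULL) {
  score <- if (is.data.frame(prs)) prs$z else as.numeric(prs)
  y <- as.integer(phenotype)
  if (length(score) != length(y)) {
    stop_gwasdiff("score and phenotype lengths differ", "gwasdiff_error_schema")
  }
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2) {
    stop_gwasdiff("phenotype must be binary with both classes present",
                  "gwasdiff_error_domain")
  }
  dat <- data.frame(y = y, prs = score)
  rhs_null <- "1"
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (qr(cbind(1, covariates))$rank < ncol(covariates) + 1) {
      stop_gwasdiff("covariate matrix is rank deficient",
                    "gwasdiff_error_domain")
    }
    colnames(covariates) <- paste0("C", seq_len(ncol(covariates)))
    dat <- cbind(dat, covariates)
    rhs_null <- paste(colnames(covariates), collapse = " + ")
  }
  fit <- withCallingHandlers(
    glm(stats::as.formula(paste("y ~ prs +", rhs_null)),
        data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- summary(fit)$coefficients
  if (separation_suspected(fit)) {
    stop_gwasdiff(
      "perfect (or quasi-perfect) separation: the PRS determines the phenotype; no stable estimate exists",
      "gwasdiff_error_separation"
    )
  }
  null_fit <- glm(stats::as.formula(paste("y ~", rhs_null)),
                  data = dat, family = binomial())
  beta <- cf["prs", "Estimate"]
  se <- cf["prs", "Std. Error"]
  ll_null <- as.numeric(logLik(null_fit))
  ll_full <- as.numeric(logLik(fit))
  structure(
    list(
      beta = beta, se = se, z = beta / se,
      p = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
      or = exp(beta),
      or_lower = exp(beta - 1.96 * se), or_upper = exp(beta + 1.96 * se),
      n = length(y), n_cases = sum(y),
      ll_null = ll_null, ll_full = ll_full,
      r2_nagelkerke = r2_nagelkerke(ll_null, ll_full, length(y)),
      auc = auc_mann_whitney(score, y),
      converged = fit$converged
    ),
    class = "prs_fit"
  )
}

separation_suspected <- function(fit) {
  eps <- 1e-8
  mu <- fit$fitted.values
  all(mu < eps | mu > 1 - eps) ||
    (!fit$converged && any(abs(coef(fit)) > 10, na.rm = TRUE)) ||
    any(abs(coef(fit)["prs"]) > 20, na.rm = TRUE)
}

# Area under the ROC curve via the rank-sum statistic.
auc_mann_whitney <- function(score, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  w <- suppressWarnings(
    wilcox.test(score[y == 1], score[y == 0], exact = FALSE)
  )
  as.numeric(w$statistic) / (n1 * n0)
}

#' @export
print.prs_fit <- function(x, ...) {
  cat(sprintf(
    "<prs_fit> OR per SD = %.3f (95%% CI %.3f-%.3f), p = %.3g, Nagelkerke R2 = %.4f, n = %d\n",
    x$or, x$or_lower, x$or_upper, x$p, x$r2_nagelkerke, x$n
  ))
  invisible(x)
}

#' Nagelkerke's pseudo-R2
#'
#' `(1 - exp(2 (ll_null - ll_full) / n)) / (1 - exp(2 ll_null / n))`:
#' the Cox-Snell R2 rescaled to a \[0, 1\] maximum.
#'
#' @param ll_null,ll_full Log-likelihoods of the null and full models
#'   (`ll_full >= ll_null`).
#' @param n Number of observations.
#' @return The pseudo-R2 fraction.
#' @export
r2_nagelkerke <- function(ll_null, ll_full, n) {
  if (n <= 0) stop_gwasdiff("n must be positive", "gwasdiff_error_domain")
  if (ll_full < ll_null - 1e-8) {
    stop_gwasdiff("ll_full must be at least ll_null", "gwasdiff_error_domain")
  }
  (1 - exp(2 * (ll_null - ll_full) / n)) / (1 - exp(2 * ll_null / n))
}

#' Convert observed-scale variance explained to the liability scale
#'
#' The standard transform for variance explained by a score in an
#' ascertained case-control sample under the liability-threshold model.
#' With population prevalence `K`, sample case fraction `P`, threshold
#' `t = qnorm(1 - K)` and `z = dnorm(t)`:
#' `C = K(1-K)/z^2 * K(1-K)/(P(1-P))`, `m = z/K`,
#' `theta = m (P-K)/(1-K) * (m (P-K)/(1-K) - t)`, and
#' `r2_liab = r2_obs * C / (1 + r2_obs * theta * C)`.
#'
#' @param r2_obs Observed-scale variance explained, in \[0, 1).
#' @param K Population prevalence of the phenotype, in (0, 1).
#' @param P Sample case fraction, in (0, 1).
#' @return Liability-scale variance explained.
#' @export
r2_liability <- function(r2_obs, K, P) {
  check_prob(K, "K")
  check_prob(P, "P")
  if (any(r2_obs < 0) || any(r2_obs >= 1)) {
    stop_gwasdiff("r2_obs must be in [0, 1)", "gwasdiff_error_domain")
  }
  t <- qnorm(1 - K)
  zd <- dnorm(t)
  C <- K * (1 - K) / zd^2 * K * (1 - K) / (P * (1 - P))
  m <- zd / K
  theta <- m * (P - K) / (1 - K) * (m * (P - K) / (1 - K) - t)
  r2_obs * C / (1 + r2_obs * theta * C)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR-adjusted P values, `q_(i) = min_{j >= i} min(1, p_(j) m / j)`,
#' mapped back to the input order. Delegates to
#' `stats::p.adjust(method = "BH")`, which implements exactly this formula.
#'
#' @param p P values in (0, 1\].
#' @return Vector of q values, same length and order as `p`.
#' @export
fdr_bh <- function(p) {
  if (length(p) == 0) return(numeric(0))
  check_prob(p, "p", open_left = TRUE, open_right = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Fixed-effect (inverse-variance) meta-analysis
#'
#' Pools estimates with weights `w_i = 1 / se_i^2`:
#' `beta = sum(w b) / sum(w)`, `se = 1 / sqrt(sum(w))`, two-sided normal P.
#'
#' @param betas Effect estimates.
#' @param ses Their standard errors (positive, same length).
#' @return A one-row tibble: `beta`, `se`, `p`, `n_studies`.
#' @export
meta_fixed <- function(betas, ses) {
  if (length(betas) != length(ses)) {
    stop_gwasdiff("betas and ses must have equal length",
                  "gwasdiff_error_schema")
  }
  if (length(betas) < 1) {
    stop_gwasdiff("need at least one study", "gwasdiff_error_domain")
  }
  if (any(!is.finite(ses) | ses <= 0)) {
    stop_gwasdiff("standard errors must be positive", "gwasdiff_error_domain")
  }
  if (length(betas) == 1) {
    beta <- betas
    se <- ses
  } else {
    w <- 1 / ses^2
    beta <- sum(w * betas) / sum(w)
    se <- 1 / sqrt(sum(w))
  }
  tibble::tibble(
    beta = beta, se = se,
    p = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
    n_studies = length(betas)
  )
}

#' Covariate-adjusted polygenic-score profile by group
#'
#' Residualizes the score on the covariates by least squares, standardizes
#' the residuals over the whole sample, and reports the per-group mean with
#' a 95% normal CI (`mean +/- 1.96 sd / sqrt(n)`), the construction behind
#' group-wise polygenic profile plots.
#'
#' @param prs Output of [prs_score()] or a numeric score vector.
#' @param covariates Optional covariate matrix (may be `NULL`).
#' @param group_labels Factor-like group membership, at least two groups,
#'   each with at least two members.
#' @return A tibble with one row per group: `group`, `n`, `mean`,
#'   `ci_lower`, `ci_upper`.
#' @export
group_profile <- function(prs, covariates = NULL, group_labels) {
  score <- if (is.data.frame(prs)) prs$z else as.numeric(prs)
  g <- as.character(group_labels)
  if (length(unique(g)) < 2) {
    stop_gwasdiff("need at least two groups", "gwasdiff_error_domain")
  }
  if (any(table(g) < 2)) {
    stop_gwasdiff("every group needs at least two members",
                  "gwasdiff_error_domain")
  }
  resid <- if (is.null(covariates)) {
    score - mean(score)
  } else {
    X <- cbind(1, as.matrix(covariates))
    keep <- qr(X)$pivot[seq_len(qr(X)$rank)]  # drop constant/collinear cols
    lm.fit(X[, keep, drop = FALSE], score)$residuals
  }
  std <- resid / sd(resid)
  std <- std - mean(std)
  tibble::tibble(group = g, score = std) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$score),
      ci_lower = mean - 1.96 * sd(.data$score) / sqrt(n),
      ci_upper = mean + 1.96 * sd(.data$score) / sqrt(n),
      .groups = "drop"
    )
}

#' Clumping + thresholding scan over P-value cutoffs
#'
#' Clumps the training summary statistics once, then for each threshold
#' scores the target cohort on the surviving variants with `p <= threshold`,
#' fits the covariate-adjusted logistic association, and reports effect
#' sizes and variance explained on the observed and liability scales.
#' FDR q values are computed across the scan (one training/testing pairing
#' = one multiple-testing family). Thresholds at which no variant survives
#' are skipped with a message.
#'
#' @param sumstats Training summary statistics.
#' @param cohort Target [genotype_cohort()] whose `samples$label` (or
#'   `phenotype`) defines the outcome.
#' @param reference LD reference for clumping (see [clump_snvs()]).
#' @param phenotype Binary outcome vector; defaults to
#'   `samples$label == case_label`.
#' @param case_label Label treated as the case class when `phenotype` is
#'   derived from the cohort (default `"case_TRS"`).
#' @param covariates Covariate matrix for the association model.
#' @param thresholds P-value grid (default `5e-8, 1e-5, 1e-3, 0.01, 0.05,
#'   0.1, 0.5, 1`).
#' @param r2_threshold,window_kb Clumping parameters.
#' @param K Population prevalence used for the liability-scale conversion
#'   (for a within-case treatment-resistance contrast, the population is
#'   the case population, so `K` is the TRS fraction among cases).
#' @return A tibble with one row per evaluated threshold: `threshold`,
#'   `n_snvs_used`, `beta`, `se`, `or`, `or_lower`, `or_upper`, `p`, `q`,
#'   `r2_nagelkerke`, `r2_liability`, `auc`.
#' @export
threshold_scan <- function(sumstats, cohort, reference,
                           phenotype = NULL, case_label = "case_TRS",
                           covariates = NULL,
                           thresholds = c(5e-8, 1e-5, 1e-3, 0.01, 0.05,
                                          0.1, 0.5, 1),
                           r2_threshold = 0.1, window_kb = 250, K = 0.25) {
  if (is.null(phenotype)) {
    phenotype <- as.integer(cohort$samples$label == case_label)
  }
  clumped <- clump_snvs(sumstats, reference, r2_threshold = r2_threshold,
                        window_kb = window_kb)
  rows <- purrr::map(sort(thresholds), function(thr) {
    n_used <- sum(clumped$p <= thr)
    if (n_used == 0) {
      inform(sprintf("threshold %g: no variant qualifies; skipped", thr))
      return(NULL)
    }
    score <- prs_score(cohort, clumped, threshold = thr)
    fit <- associate_prs(score, phenotype, covariates)
    tibble::tibble(
      threshold = thr, n_snvs_used = n_used,
      beta = fit$beta, se = fit$se,
      or = fit$or, or_lower = fit$or_lower, or_upper = fit$or_upper,
      p = fit$p,
      r2_nagelkerke = fit$r2_nagelkerke,
      r2_liability = r2_liability(fit$r2_nagelkerke, K,
                                  mean(phenotype)),
      auc = fit$auc
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out <- dplyr::mutate(out, q = fdr_bh(.data$p), .after = "p")
  }
  out
}
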