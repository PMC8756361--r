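#' Difference-of-log-odds-ratio (interaction) test
#'
#' Compares the effect of a variant between two case-control studies by
#' differencing the log odds ratios, the Altman-Bland test for the equality
#' of two estimated effects. It is analogous to a fixed-effect moderator test
#' in meta-analysis: with independent samples,
#' `d = beta1 - beta2`, `SE(d) = sqrt(se1^2 + se2^2)`, `z = d / SE(d)` is
#' standard normal under the null of equal effects, and the two-sided P value
#' is `2 * (1 - Phi(|z|))`.
#'
#' `se1` and `se2` are standard errors of the *log* odds ratios — the scale
#' on which the difference is a regression-coefficient contrast and `z` is
#' standard normal. A positive `z` means a stronger association in study 1.
#' P values are floored at the smallest positive double rather than reported
#' as zero.
#'
#' @param beta1,beta2 Log odds ratios (vectors recycle as usual).
#' @param se1,se2 Standard errors of the log odds ratios; must be positive.
#' @return A tibble with columns `d`, `se_d`, `z`, `p`.
#' @export
#' @examples
#' interaction_test(log(1.5), 0.1, 0, 0.1)
interaction_test <- function(beta1, se1, beta2, se2) {
  if (any(!is.finite(se1) | se1 <= 0) || any(!is.finite(se2) | se2 <= 0)) {
    stop_gwasdiff("standard errors must be finite and positive",
                  "gwasdiff_error_domain")
  }
  d <- beta1 - beta2
  se_d <- sqrt(se1^2 + se2^2)
  z <- d / se_d
  p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
  tibble::tibble(d = d, se_d = se_d, z = z, p = p)
}

#' Run the case-case interaction GWAS over a harmonized table
#'
#' Applies [interaction_test()] to every retained row of a harmonized pair of
#' studies. Study 1 is the first study given to [harmonize_sumstats()]; in
#' the treatment-resistance design that is the TRS-vs-controls GWAS, so
#' positive `z` scores reflect stronger associations in TRS.
#'
#' @param harmonized Output of [harmonize_sumstats()]; excluded rows are
#'   dropped.
#' @return A tibble sorted by `(chrom, pos)` with one row per retained
#'   variant: identifiers, alleles, per-study `eaf`, and `d`, `se_d`, `z`,
#'   `p`. Emits a warning if every row was excluded.
#' @export
run_interaction_gwas <- function(harmonized) {
  kept <- dplyr::filter(harmonized, !.data$excluded)
  if (nrow(kept) == 0) {
    warn("all harmonized rows are excluded; interaction result is empty")
    return(tibble::tibble(
      snv_id = character(), chrom = character(), pos = integer(),
      effect_allele = character(), other_allele = character(),
      eaf1 = numeric(), eaf2 = numeric(),
      d = numeric(), se_d = numeric(), z = numeric(), p = numeric()
    ))
  }
  stat <- interaction_test(kept$beta1, kept$se1, kept$beta2, kept$se2)
  dplyr::bind_cols(
    dplyr::select(kept, "snv_id", "chrom", "pos", "effect_allele",
                  "other_allele", "eaf1", "eaf2"),
    stat
  ) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Convert interaction results to the canonical summary-statistics layout
#'
#' Re-expresses the difference statistic as a summary-statistics table
#' (`beta := d`, `se := se_d`) so it can feed the LD score regression and
#' polygenic-score stages through the same interfaces as any GWAS.
#'
#' @param interaction Output of [run_interaction_gwas()].
#' @param n_cases,n_controls Sample sizes to record (the two case groups of
#'   the contrast, used downstream as the effective study size).
#' @return A tibble in the layout of [read_sumstats()], with `eaf` taken from
#'   study 1.
#' @export
interaction_as_sumstats <- function(interaction, n_cases, n_controls) {
  tibble::tibble(
    snv_id = interaction$snv_id,
    chrom = interaction$chrom,
    pos = interaction$pos,
    effect_allele = interaction$effect_allele,
    other_allele = interaction$other_allele,
    eaf = interaction$eaf1,
    beta = interaction$d,
    se = interaction$se_d,
    p = interaction$p,
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls)
  )
}
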