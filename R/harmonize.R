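#' Align two summary-statistic studies to a common effect-allele frame
#'
#' Intersects two validated studies on `snv_id` and aligns study 2 to study
#' 1's effect allele using the standard swap/flip lattice:
#'
#' * `identity` — alleles already match;
#' * `swap` — study 2 reports the other allele as effect allele: its beta is
#'   negated and `eaf` becomes `1 - eaf`;
#' * `flip` — study 2 is on the opposite strand: both alleles are
#'   complemented, effect sizes unchanged;
#' * `swap_flip` — both at once.
#'
#' Three exclusion rules are applied, in order of precedence:
#' `allele_mismatch` (the allele pairs cannot be reconciled by any action),
#' `palindromic_ambiguous` (A/T or C/G variants whose minor-allele frequency
#' lies in \[0.4, 0.5\] in *both* studies, where strand cannot be resolved
#' from frequency), and `maf_diff` (post-alignment effect-allele frequency
#' difference above `maf_diff_threshold`, mirroring pre-imputation quality
#' control; the conventional cutoff is 20%).
#'
#' Excluded rows are retained in the output with `excluded = TRUE` so that
#' exclusion tallies can be reported; downstream analyses drop them.
#'
#' @param study1,study2 Validated summary-statistics tibbles
#'   (see [read_sumstats()]).
#' @param maf_diff_threshold Maximum tolerated `|eaf1 - eaf2|` after
#'   alignment (default 0.20).
#' @return A tibble with one row per shared variant: study-1 coordinates and
#'   alleles, per-study `eaf`/`beta`/`se`/`p`/sample sizes (suffixes `1`,
#'   `2`), the alignment `action`, `maf_diff`, `excluded` and
#'   `exclusion_reason`. Exclusion tallies are attached as the
#'   `"exclusion_counts"` attribute and reported via a message.
#' @export
harmonize_sumstats <- function(study1, study2, maf_diff_threshold = 0.20) {
  study1 <- validate_sumstats(study1)
  study2 <- validate_sumstats(study2)
  shared <- intersect(study1$snv_id, study2$snv_id)
  if (length(shared) == 0) {
    stop_gwasdiff("no variants shared between the two studies",
                  "gwasdiff_error_empty")
  }
  s1 <- study1[match(shared, study1$snv_id), ]
  s2 <- study2[match(shared, study2$snv_id), ]

  a1 <- s1$effect_allele; a2 <- s1$other_allele
  b1 <- s2$effect_allele; b2 <- s2$other_allele
  cb1 <- complement_base(b1); cb2 <- complement_base(b2)

  action <- rep(NA_character_, length(shared))
  action[b1 == a1 & b2 == a2] <- "identity"
  action[is.na(action) & b1 == a2 & b2 == a1] <- "swap"
  action[is.na(action) & cb1 == a1 & cb2 == a2] <- "flip"
  action[is.na(action) & cb1 == a2 & cb2 == a1] <- "swap_flip"

  aligned <- align_record(s2$beta, s2$eaf, b1, b2, action)

  palindromic <- a1 == complement_base(a2)
  maf1 <- pmin(s1$eaf, 1 - s1$eaf)
  maf2_src <- pmin(s2$eaf, 1 - s2$eaf)  # maf is alignment-invariant
  ambiguous <- palindromic & !is.na(action) &
    maf1 >= 0.4 & maf1 <= 0.5 & maf2_src >= 0.4 & maf2_src <= 0.5

  maf_diff <- abs(s1$eaf - aligned$eaf)

  reason <- rep("none", length(shared))
  reason[maf_diff > maf_diff_threshold] <- "maf_diff"
  reason[ambiguous] <- "palindromic_ambiguous"
  reason[is.na(action)] <- "allele_mismatch"
  maf_diff[is.na(action)] <- NA_real_

  out <- tibble::tibble(
    snv_id = shared,
    chrom = s1$chrom, pos = s1$pos,
    effect_allele = a1, other_allele = a2,
    eaf1 = s1$eaf, beta1 = s1$beta, se1 = s1$se, p1 = s1$p,
    n_cases1 = s1$n_cases, n_controls1 = s1$n_controls,
    eaf2 = aligned$eaf, beta2 = aligned$beta, se2 = s2$se, p2 = s2$p,
    n_cases2 = s2$n_cases, n_controls2 = s2$n_controls,
    action = action, maf_diff = maf_diff,
    excluded = reason != "none", exclusion_reason = reason
  )
  counts <- table(factor(
    reason[reason != "none"],
    levels = c("allele_mismatch", "palindromic_ambiguous", "maf_diff")
  ))
  attr(out, "exclusion_counts") <- counts
  inform(sprintf(
    "harmonized %d shared variants: %d retained, %d excluded (%s)",
    nrow(out), sum(!out$excluded), sum(out$excluded),
    paste(sprintf("%s: %d", names(counts), as.integer(counts)), collapse = ", ")
  ))
  out
}

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

# Apply (or re-apply) an alignment action to a (beta, eaf, alleles) record.
# The transform is an involution: applying the same action twice restores the
# source record.
align_record <- function(beta, eaf, effect_allele, other_allele, action) {
  swap <- !is.na(action) & action %in% c("swap", "swap_flip")
  flip <- !is.na(action) & action %in% c("flip", "swap_flip")
  out_beta <- ifelse(swap, -beta, beta)
  out_eaf <- ifelse(swap, 1 - eaf, eaf)
  ea <- ifelse(flip, complement_base(effect_allele), effect_allele)
  oa <- ifelse(flip, complement_base(other_allele), other_allele)
  tmp <- ea
  ea <- ifelse(swap, oa, ea)
  oa <- ifelse(swap, tmp, oa)
  list(beta = out_beta, eaf = out_eaf, effect_allele = ea, other_allele = oa)
}

#' Write a harmonization exclusion report
#'
#' @param harmonized Output of [harmonize_sumstats()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_harmonization_report <- function(harmonized, path) {
  excl <- dplyr::filter(harmonized, .data$excluded)
  readr::write_tsv(
    dplyr::select(excl, "snv_id", "chrom", "pos", "exclusion_reason",
                  "maf_diff"),
    path, progress = FALSE
  )
  invisible(path)
}
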