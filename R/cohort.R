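#' Construct a genotyped cohort
#'
#' Container for an individuals-by-variants dosage matrix with per-sample
#' phenotype labels and covariates and per-variant metadata. Dosages count
#' copies of the effect allele (0/1/2; `NA` allowed and mean-imputed where a
#' method needs complete data).
#'
#' @param dosages Integer/numeric matrix, individuals in rows, variants in
#'   columns.
#' @param samples Tibble with one row per individual; must contain `id` and
#'   `label` (e.g. `control`, `case_nonTRS`, `case_TRS`); any further columns
#'   (sex, covariates, simulation bookkeeping) are carried along.
#' @param snvs Tibble with one row per variant: `snv_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele` (and optionally `maf`, block structure).
#' @return An object of class `genotype_cohort`.
#' @export
genotype_cohort <- function(dosages, samples, snvs) {
  if (nrow(dosages) != nrow(samples)) {
    stop_gwasdiff("dosage rows must match sample rows", "gwasdiff_error_schema")
  }
  if (ncol(dosages) != nrow(snvs)) {
    stop_gwasdiff("dosage columns must match variant rows",
                  "gwasdiff_error_schema")
  }
  if (!all(c("id", "label") %in% names(samples))) {
    stop_gwasdiff("`samples` needs columns id and label",
                  "gwasdiff_error_schema")
  }
  if (!all(c("snv_id", "chrom", "pos", "effect_allele", "other_allele") %in%
           names(snvs))) {
    stop_gwasdiff("`snvs` needs snv_id, chrom, pos and allele columns",
                  "gwasdiff_error_schema")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop_gwasdiff("dosages must lie in [0, 2]", "gwasdiff_error_domain")
  }
  colnames(dosages) <- snvs$snv_id
  structure(
    list(dosages = dosages, samples = tibble::as_tibble(samples),
         snvs = tibble::as_tibble(snvs)),
    class = "genotype_cohort"
  )
}

#' @export
print.genotype_cohort <- function(x, ...) {
  tab <- table(x$samples$label)
  cat(sprintf("<genotype_cohort> %d individuals x %d variants (%s)\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' Subset a cohort by sample predicate
#'
#' @param cohort A [genotype_cohort()].
#' @param which Logical or integer index into the samples.
#' @return A new `genotype_cohort` restricted to the selected individuals.
#' @export
cohort_subset <- function(cohort, which) {
  genotype_cohort(cohort$dosages[which, , drop = FALSE],
                  cohort$samples[which, , drop = FALSE],
                  cohort$snvs)
}

#' Principal components of the dosage matrix
#'
#' Top-`k` principal components of the centred dosage matrix, computed from
#' the eigendecomposition of the individual-by-individual Gram matrix (cheap
#' when individuals are fewer than variants). Used as ancestry / batch
#' covariates in the polygenic-score association models.
#'
#' @param cohort A [genotype_cohort()].
#' @param k Number of components (default 4).
#' @return A numeric matrix, individuals by `k`, columns named `PC1..PCk`,
#'   each column scaled to unit variance.
#' @export
cohort_pcs <- function(cohort, k = 4) {
  D <- cohort$dosages
  if (anyNA(D)) D <- impute_col_mean(D)
  Dc <- scale(D, center = TRUE, scale = FALSE)
  G <- tcrossprod(Dc) / ncol(Dc)
  eg <- eigen(G, symmetric = TRUE)
  k <- min(k, nrow(D) - 1L)
  pcs <- eg$vectors[, seq_len(k), drop = FALSE]
  pcs <- scale(pcs)
  colnames(pcs) <- paste0("PC", seq_len(k))
  pcs
}

impute_col_mean <- function(D) {
  nai <- which(is.na(D), arr.ind = TRUE)
  if (nrow(nai) > 0) {
    mu <- colMeans(D, na.rm = TRUE)
    D[nai] <- mu[nai[, 2]]
  }
  D
}
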