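# Programmatic fixtures: small summary-statistic tables and cohorts built
# in code at test time.

make_sumstats <- function(n = 20, seed = 1, chrom = "1") {
  withr::with_seed(seed, {
    pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"),
                    ncol = 2, byrow = TRUE)
    pick <- sample(nrow(pairs), n, replace = TRUE)
    tibble::tibble(
      snv_id = sprintf("rs%d", seq_len(n)),
      chrom = chrom,
      pos = as.integer(seq_len(n) * 1000L),
      effect_allele = pairs[pick, 1],
      other_allele = pairs[pick, 2],
      eaf = round(runif(n, 0.05, 0.95), 3),
      beta = round(rnorm(n, 0, 0.1), 4),
      se = round(runif(n, 0.02, 0.2), 4),
      p = round(runif(n, 0.001, 1), 4),
      n_cases = 500L,
      n_controls = 500L
    )
  })
}

write_sumstats_text <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

sumstats_header <- function(effect = "OR") {
  paste(c("SNP", "CHR", "BP", "A1", "A2", "EAF", effect, "SE", "P",
          "N_CAS", "N_CON"), collapse = "\t")
}

sumstats_row <- function(...) paste(c(...), collapse = "\t")

# A tiny deterministic cohort with known dosages.
make_test_cohort <- function(dosages, labels, chrom = "1",
                             pos = NULL, alleles = NULL) {
  m <- ncol(dosages)
  snvs <- tibble::tibble(
    snv_id = sprintf("rs%d", seq_len(m)),
    chrom = chrom,
    pos = pos %||% as.integer(seq_len(m) * 1000L),
    effect_allele = if (is.null(alleles)) rep("A", m) else alleles[, 1],
    other_allele = if (is.null(alleles)) rep("G", m) else alleles[, 2]
  )
  samples <- tibble::tibble(
    id = sprintf("s%d", seq_len(nrow(dosages))),
    label = labels
  )
  genotype_cohort(dosages, samples, snvs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-variant study for harmonization edge cases.
base_study <- function(eaf = 0.30, beta = 0.10, ea = "A", oa = "G") {
  tibble::tibble(
    snv_id = "rs1", chrom = "1", pos = 1000L,
    effect_allele = ea, other_allele = oa,
    eaf = eaf, beta = beta, se = 0.05, p = 0.5,
    n_cases = 100L, n_controls = 100L
  )
}
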