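#' Simulation configuration
#'
#' Parameters of the two-layer liability-threshold generator. A shared
#' polygenic component with liability-scale variance `h2_shared` determines
#' schizophrenia case status at population prevalence `K_scz`; among cases,
#' an independent TRS-specific polygenic component with variance
#' `h2_specific` determines treatment resistance at a threshold chosen so
#' that the expected TRS fraction among cases equals `trs_fraction`
#' (epidemiologically 20-30% of cases; default 0.25). The two discovery
#' control sets are disjoint, matching a two-source design where each case
#' series is compared with its own healthy controls.
#'
#' Genotypes come in LD blocks: block sizes are drawn uniformly from
#' `1 .. (2 * block_size - 1)` (mean `block_size`) so that LD scores vary
#' across variants — heterogeneous LD is what identifies the LD score
#' regression. Within a block all variants share one allele frequency
#' (drawn from `maf_range`) and an exchangeable haplotype correlation
#' calibrated so pairwise dosage r^2 equals `within_block_r2`.
#'
#' @param m_snvs Number of variants.
#' @param block_size Mean LD block size in variants (1 = no LD).
#' @param within_block_r2 Target pairwise dosage r^2 within a block.
#' @param maf_range Range the per-block minor-allele frequency is drawn
#'   from.
#' @param h2_shared Liability-scale variance of the shared (schizophrenia)
#'   polygenic component.
#' @param h2_specific Liability-scale variance of the TRS-specific
#'   component among cases.
#' @param K_scz Population prevalence of the case phenotype.
#' @param trs_fraction Expected fraction of cases that are treatment
#'   resistant.
#' @param n_trs_cases,n_nontrs_cases Discovery case-group sizes.
#' @param n_controls_1,n_controls_2 Sizes of the two disjoint control sets.
#' @param n_validation Held-out validation cases (TRS and non-TRS mixed at
#'   `trs_fraction`); 0 disables the validation cohort.
#' @param n_reference Reference-sample size used for LD scores and
#'   clumping.
#' @param seed Integer seed driving every random draw (`NULL` = use the
#'   current RNG state).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(m_snvs = 5000, block_size = 5, within_block_r2 = 0.3,
                       maf_range = c(0.05, 0.5), h2_shared = 0.24,
                       h2_specific = 0.1, K_scz = 0.01, trs_fraction = 0.25,
                       n_trs_cases = 2000, n_nontrs_cases = 2000,
                       n_controls_1 = 2000, n_controls_2 = 2000,
                       n_validation = 600, n_reference = 400, seed = NULL) {
  cfg <- list(
    m_snvs = as.integer(m_snvs), block_size = as.integer(block_size),
    within_block_r2 = within_block_r2, maf_range = maf_range,
    h2_shared = h2_shared, h2_specific = h2_specific,
    K_scz = K_scz, trs_fraction = trs_fraction,
    n_trs_cases = as.integer(n_trs_cases),
    n_nontrs_cases = as.integer(n_nontrs_cases),
    n_controls_1 = as.integer(n_controls_1),
    n_controls_2 = as.integer(n_controls_2),
    n_validation = as.integer(n_validation),
    n_reference = as.integer(n_reference),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  stopifnot(
    cfg$m_snvs > 0, cfg$block_size >= 1,
    cfg$within_block_r2 >= 0, cfg$within_block_r2 < 1,
    length(cfg$maf_range) == 2, cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
    cfg$h2_shared >= 0, cfg$h2_specific >= 0,
    cfg$h2_shared < 1, cfg$h2_specific < 1,
    cfg$n_trs_cases > 0, cfg$n_nontrs_cases > 0,
    cfg$n_controls_1 > 0, cfg$n_controls_2 > 0, cfg$n_validation >= 0,
    cfg$n_reference >= 2
  )
  check_prob(cfg$K_scz, "K_scz")
  check_prob(cfg$trs_fraction, "trs_fraction")
  class(cfg) <- "sim_config"
  cfg
}

# Draw the variant frame: blocks, frequencies, alleles, coordinates.
# Blocks are laid out contiguously across 22 chromosomes, 10 kb between
# adjacent variants and an extra 40 kb between blocks.
make_snv_frame <- function(cfg) {
  m <- cfg$m_snvs
  sizes <- integer(0)
  while (sum(sizes) < m) {
    lo <- 1L
    hi <- max(1L, 2L * cfg$block_size - 1L)
    sizes <- c(sizes, sample(seq(lo, hi), 64, replace = TRUE))
  }
  sizes <- sizes[cumsum(sizes) - sizes < m]
  sizes[length(sizes)] <- m - sum(sizes[-length(sizes)])
  nb <- length(sizes)
  block <- rep(seq_len(nb), sizes)

  n_chrom <- min(22L, nb)
  block_chrom <- sort(rep_len(seq_len(n_chrom), nb))
  chrom <- as.character(block_chrom[block])

  maf_b <- runif(nb, cfg$maf_range[1], cfg$maf_range[2])
  maf <- maf_b[block]
  s <- ifelse(sizes[block] > 1, cfg$within_block_r2^(1 / 4), 0)

  pos <- integer(m)
  for (ch in unique(block_chrom)) {
    idx <- which(chrom == as.character(ch))
    step <- rep(10000L, length(idx))
    newb <- c(FALSE, diff(block[idx]) != 0)
    step[newb] <- 50000L
    pos[idx] <- cumsum(step)
  }

  pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T",
                    "A", "T", "C", "G"), ncol = 2, byrow = TRUE)
  pick <- sample(nrow(pairs), m, replace = TRUE)
  swap <- runif(m) < 0.5
  ea <- ifelse(swap, pairs[pick, 2], pairs[pick, 1])
  oa <- ifelse(swap, pairs[pick, 1], pairs[pick, 2])

  tibble::tibble(
    snv_id = sprintf("snv_%06d", seq_len(m)),
    chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa,
    maf = maf, block = block, s = s
  )
}

#' Simulate an LD reference panel
#'
#' Draws the variant frame (blocks, frequencies, alleles, coordinates),
#' simulates a reference sample of `n_reference` individuals from the
#' block-exchangeable haplotype model, and computes empirical LD scores
#' from it with [compute_ld_scores()].
#'
#' @param config A [sim_config()].
#' @return A list of class `ref_panel`: `snvs` (variant frame), `genotypes`
#'   (reference dosages, individuals x variants), `panel` (an
#'   [ld_panel()]), and `config`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  snvs <- make_snv_frame(config)
  zero <- numeric(config$m_snvs)
  chunk <- sim_dosage_chunk(config$n_reference, snvs$maf, snvs$block,
                            snvs$s, zero, zero)
  genotypes <- t(chunk$dosages)
  colnames(genotypes) <- snvs$snv_id
  panel <- compute_ld_scores(genotypes, snvs$block, snv_id = snvs$snv_id,
                             M = config$m_snvs)
  structure(
    list(snvs = snvs, genotypes = genotypes, panel = panel, config = config),
    class = "ref_panel"
  )
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf(
    "<ref_panel> %d variants in %d blocks, %d reference individuals, mean l = %.2f\n",
    nrow(x$snvs), max(x$snvs$block), nrow(x$genotypes), mean(x$panel$l)
  ))
  invisible(x)
}

# Per-SNV dosage-scale effects for a polygenic component of liability-scale
# variance h2: standardized effects alpha_j ~ N(0, h2/m) rescaled by the
# dosage SD (so E[var of the genetic score] = h2 regardless of frequencies).
draw_effects <- function(h2, maf) {
  m <- length(maf)
  # always consume the same RNG draws so configurations differing only in a
  # variance component share genotypes and noise (counterfactual pairing)
  rnorm(m, 0, sqrt(max(h2, 0) / m)) / sqrt(2 * maf * (1 - maf))
}

#' Simulate a liability-threshold cohort
#'
#' Samples individuals by rejection from the two-layer liability model and
#' fills the group quotas of `config`: the two discovery case groups, the
#' two disjoint control sets, and a held-out validation set of cases. For
#' each individual the schizophrenia liability is
#' `L1 = sum_j b_shared_j (g_j - 2 p_j) + e1`, with case status
#' `L1 > qnorm(1 - K_scz)`; among cases the resistance liability
#' `L2 = sum_j b_specific_j (g_j - 2 p_j) + e2` sets TRS status at
#' `qnorm(1 - trs_fraction)`. Effect vectors are drawn once per cohort and
#' stored with it (attributes `b_shared`, `b_specific`) so liabilities can
#' be recomputed exactly; per-individual genetic components and liabilities
#' are kept in the sample sheet. Sex is simulated as a pure noise
#' covariate.
#'
#' @param config A [sim_config()].
#' @param reference A [simulate_reference()] result (supplies the variant
#'   frame; its seed has already been consumed, so the cohort draws from
#'   `seed + 1` when a seed is set).
#' @return A [genotype_cohort()]. `samples$set` assigns each individual to
#'   `discovery_trs`, `discovery_nontrs`, `controls_1`, `controls_2` or
#'   `validation`; `samples$label` is the phenotype class. Attributes:
#'   `b_shared`, `b_specific`, `n_sampled` (pool size drawn),
#'   `case_threshold`, `trs_threshold`.
#' @export
simulate_cohort <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"), inherits(reference, "ref_panel"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  snvs <- reference$snvs
  m <- nrow(snvs)
  b1 <- draw_effects(config$h2_shared, snvs$maf)
  b2 <- draw_effects(config$h2_specific, snvs$maf)
  center1 <- sum(b1 * 2 * snvs$maf)
  center2 <- sum(b2 * 2 * snvs$maf)
  sd_e1 <- sqrt(1 - config$h2_shared)
  sd_e2 <- sqrt(1 - config$h2_specific)
  t1 <- qnorm(1 - config$K_scz)
  t2 <- qnorm(1 - config$trs_fraction)

  n_val_trs <- round(config$n_validation * config$trs_fraction)
  n_val_non <- config$n_validation - n_val_trs
  quota <- c(
    trs = config$n_trs_cases + n_val_trs,
    nontrs = config$n_nontrs_cases + n_val_non,
    control = config$n_controls_1 + config$n_controls_2
  )
  # Expected draws needed, with head-room; guards runaway rejection at tiny K.
  exp_need <- max(
    quota[["trs"]] / (config$K_scz * config$trs_fraction),
    quota[["nontrs"]] / (config$K_scz * (1 - config$trs_fraction)),
    quota[["control"]] / (1 - config$K_scz)
  )
  max_draw <- as.integer(min(ceiling(6 * exp_need) + 1000, 2^31 - 1))

  res <- sim_cohort_quota(
    snvs$maf, snvs$block, snvs$s, b1, b2, center1, center2,
    t1, sd_e1, t2, sd_e2,
    quota[["trs"]], quota[["nontrs"]], quota[["control"]], max_draw
  )
  if (res$kept < sum(quota)) {
    cls_tab <- table(factor(res$class[seq_len(res$kept)], levels = 1:3))
    stop_gwasdiff(
      sprintf(
        "rejection sampling cap reached (%d individuals drawn; got TRS %d/%d, non-TRS %d/%d, controls %d/%d). Is K_scz (%.3g) feasible for these quotas?",
        res$drawn, cls_tab[[1]], quota[["trs"]], cls_tab[[2]],
        quota[["nontrs"]], cls_tab[[3]], quota[["control"]], config$K_scz
      ),
      "gwasdiff_error_rejection_cap"
    )
  }
  n_sampled <- res$drawn
  samples <- tibble::tibble(
    class = c("trs", "nontrs", "control")[res$class],
    g_shared = res$g_shared, g_specific = res$g_specific,
    liab_scz = res$liab1, liab_trs = res$liab2
  )
  D <- t(res$dosages)

  # Deterministic assignment to analysis sets: within each class, discovery
  # first, then validation / second control set. Individuals are iid, so the
  # split is exchangeable.
  samples$set <- NA_character_
  assign_set <- function(class, sizes, names) {
    idx <- which(samples$class == class)
    off <- 0L
    for (i in seq_along(sizes)) {
      samples$set[idx[off + seq_len(sizes[i])]] <<- names[i]
      off <- off + sizes[i]
    }
  }
  assign_set("trs", c(config$n_trs_cases, n_val_trs),
             c("discovery_trs", "validation"))
  assign_set("nontrs", c(config$n_nontrs_cases, n_val_non),
             c("discovery_nontrs", "validation"))
  assign_set("control", c(config$n_controls_1, config$n_controls_2),
             c("controls_1", "controls_2"))

  samples <- tibble::tibble(
    id = sprintf("ind_%06d", seq_len(nrow(samples))),
    label = unname(c(trs = "case_TRS", nontrs = "case_nonTRS",
                     control = "control")[samples$class]),
    set = samples$set,
    sex = rbinom(nrow(samples), 1, 0.5),
    g_shared = samples$g_shared, g_specific = samples$g_specific,
    liab_scz = samples$liab_scz, liab_trs = samples$liab_trs
  )
  out <- genotype_cohort(D, samples, snvs[, c("snv_id", "chrom", "pos",
                                              "effect_allele", "other_allele",
                                              "maf", "block")])
  attr(out, "b_shared") <- b1
  attr(out, "b_specific") <- b2
  attr(out, "centers") <- c(center1, center2)
  attr(out, "n_sampled") <- n_sampled
  attr(out, "n_cases_seen") <- res$case_seen
  attr(out, "n_trs_seen") <- res$trs_seen
  attr(out, "case_threshold") <- t1
  attr(out, "trs_threshold") <- t2
  out
}

#' Simulate the full paired-GWAS design
#'
#' One call producing everything the case-case analysis consumes: the LD
#' reference panel, the TRS-vs-controls and non-TRS-vs-controls discovery
#' GWASs run on disjoint control sets with [run_gwas()], and the held-out
#' validation cohort of labelled cases. All three outputs share one variant
#' frame.
#'
#' @param config A [sim_config()].
#' @return A list: `sumstats_trs`, `sumstats_nontrs` (canonical
#'   summary-statistics tibbles), `validation` (a [genotype_cohort()] of
#'   cases, or `NULL` when `n_validation = 0`), `reference` (the
#'   [simulate_reference()] result, with `$panel`), `cohort` (the full
#'   simulated cohort) and `config`.
#' @export
make_paired_gwas <- function(config) {
  reference <- simulate_reference(config)
  cohort <- simulate_cohort(config, reference)
  gwas1 <- run_gwas(
    cohort_subset(cohort, cohort$samples$set %in% c("discovery_trs",
                                                    "controls_1")),
    case_label = "case_TRS", control_label = "control"
  )
  gwas2 <- run_gwas(
    cohort_subset(cohort, cohort$samples$set %in% c("discovery_nontrs",
                                                    "controls_2")),
    case_label = "case_nonTRS", control_label = "control"
  )
  validation <- if (config$n_validation > 0) {
    cohort_subset(cohort, cohort$samples$set == "validation")
  }
  list(sumstats_trs = gwas1, sumstats_nontrs = gwas2,
       validation = validation, reference = reference, cohort = cohort,
       config = config)
}

#' Draw summary-statistic z scores directly from the LDSC model
#'
#' Fast generator for testing the LD score regression without genotypes:
#' independent `z_j ~ Normal(0, sqrt(1 + N h2 l_j / M))`, the marginal
#' distribution implied by the polygenic model.
#'
#' @param h2 Heritability in \[0, 1).
#' @param N Sample size.
#' @param panel An [ld_panel()].
#' @param seed Optional seed.
#' @return A numeric z vector aligned to the panel.
#' @export
simulate_sumstats_direct <- function(h2, N, panel, seed = NULL) {
  if (!is.finite(h2) || h2 < 0 || h2 >= 1) {
    stop_gwasdiff("h2 must be in [0, 1)", "gwasdiff_error_domain")
  }
  if (!is.null(seed)) set.seed(seed)
  rnorm(nrow(panel), 0, sqrt(1 + N * h2 * panel$l / panel_M(panel)))
}
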