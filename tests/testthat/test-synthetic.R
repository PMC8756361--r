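small_config <- function(...) {
  args <- list(...)
  defaults <- list(
    m_snvs = 300, block_size = 3, within_block_r2 = 0.3,
    h2_shared = 0.3, h2_specific = 0.1, K_scz = 0.05, trs_fraction = 0.25,
    n_trs_cases = 60, n_nontrs_cases = 60, n_controls_1 = 60,
    n_controls_2 = 60, n_validation = 40, n_reference = 150, seed = 1
  )
  do.call(sim_config, utils::modifyList(defaults, args))
}

test_that("reference panels are deterministic with unit scores when LD-free", {
  cfg <- small_config(block_size = 1, seed = 5)
  ref <- simulate_reference(cfg)
  expect_equal(ref$panel$l, rep(1, sum(ref$panel$snv_id %in% ref$snvs$snv_id)))
  ref2 <- simulate_reference(cfg)
  expect_identical(ref$genotypes, ref2$genotypes)
  expect_identical(ref$snvs, ref2$snvs)
})

test_that("within-block dosage correlation is calibrated to its target", {
  cfg <- small_config(m_snvs = 400, block_size = 6, within_block_r2 = 0.3,
                      n_reference = 3000, seed = 6)
  ref <- simulate_reference(cfg)
  r2s <- c()
  for (b in split(seq_len(nrow(ref$snvs)), ref$snvs$block)) {
    if (length(b) >= 2) {
      r2 <- cor(ref$genotypes[, b])^2
      r2s <- c(r2s, r2[upper.tri(r2)])
    }
  }
  expect_lt(abs(mean(r2s) - 0.3), 0.04)
  # no-LD target: cross-variant r^2 stays at noise level
  cfg0 <- small_config(m_snvs = 100, block_size = 4, within_block_r2 = 0,
                       n_reference = 2000, seed = 7)
  ref0 <- simulate_reference(cfg0)
  r2 <- cor(ref0$genotypes)^2
  expect_lt(mean(r2[upper.tri(r2)]), 0.005)
})

test_that("stored effect vectors reproduce the genetic liabilities exactly", {
  cfg <- small_config(seed = 8)
  ref <- simulate_reference(cfg)
  cohort <- simulate_cohort(cfg, ref)
  b1 <- attr(cohort, "b_shared")
  b2 <- attr(cohort, "b_specific")
  centers <- attr(cohort, "centers")
  g1 <- drop(cohort$dosages %*% b1) - centers[1]
  g2 <- drop(cohort$dosages %*% b2) - centers[2]
  expect_equal(g1, cohort$samples$g_shared, tolerance = 1e-9)
  expect_equal(g2, cohort$samples$g_specific, tolerance = 1e-9)
  # labels are exactly the liability-threshold rule
  t1 <- attr(cohort, "case_threshold")
  t2 <- attr(cohort, "trs_threshold")
  is_case <- cohort$samples$liab_scz > t1
  expect_identical(unname(is_case), cohort$samples$label != "control")
  expect_identical(
    unname(is_case & cohort$samples$liab_trs > t2),
    cohort$samples$label == "case_TRS"
  )
})

test_that("cohorts are reproducible and meet their group quotas", {
  cfg <- small_config(seed = 9)
  ref <- simulate_reference(cfg)
  c1 <- simulate_cohort(cfg, ref)
  c2 <- simulate_cohort(cfg, ref)
  expect_identical(c1$dosages, c2$dosages)
  expect_identical(c1$samples, c2$samples)
  tab <- table(c1$samples$set, c1$samples$label)
  expect_identical(unname(tab["discovery_trs", "case_TRS"]), 60L)
  expect_identical(unname(tab["controls_1", "control"]), 60L)
  expect_identical(sum(c1$samples$set == "validation"), 40L)
  # validation is cases-only, mixed at the configured resistance fraction
  val <- c1$samples[c1$samples$set == "validation", ]
  expect_false(any(val$label == "control"))
  expect_identical(sum(val$label == "case_TRS"), 10L)
})

test_that("realized prevalence and resistance fraction match the model", {
  # Fixed-size population draws (no stopping rule), liabilities recomputed
  # in R from the stored model pieces.
  draw_pop <- function(cfg, seed, n) {
    ref <- simulate_reference(cfg)
    withr::with_seed(seed, {
      b1 <- gwasdiff:::draw_effects(cfg$h2_shared, ref$snvs$maf)
      b2 <- gwasdiff:::draw_effects(cfg$h2_specific, ref$snvs$maf)
      chunk <- gwasdiff:::sim_dosage_chunk(n, ref$snvs$maf, ref$snvs$block,
                                           ref$snvs$s, b1, b2)
      list(
        liab1 = chunk$g_shared - sum(b1 * 2 * ref$snvs$maf) +
          rnorm(n, 0, sqrt(1 - cfg$h2_shared)),
        liab2 = chunk$g_specific - sum(b2 * 2 * ref$snvs$maf) +
          rnorm(n, 0, sqrt(1 - cfg$h2_specific))
      )
    })
  }
  # With no genetic variance the liability is exactly standard normal, so
  # the realized prevalence is a clean binomial draw around K.
  cfg0 <- small_config(m_snvs = 120, h2_shared = 0, h2_specific = 0,
                       seed = 10)
  n <- 40000
  pop <- draw_pop(cfg0, 101, n)
  is_case <- pop$liab1 > qnorm(1 - cfg0$K_scz)
  prev <- mean(is_case)
  ci <- qnorm(0.995) * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(prev - cfg0$K_scz), ci)
  trs_frac <- mean(pop$liab2[is_case] > qnorm(1 - cfg0$trs_fraction))
  ci_trs <- qnorm(0.995) * sqrt(0.25 * 0.75 / sum(is_case))
  expect_lt(abs(trs_frac - cfg0$trs_fraction), ci_trs)
  # With a drawn polygenic architecture the realized genetic variance
  # fluctuates around h2 (O(sqrt(2/m)) relative), so the prevalence is
  # checked against a coarser bound that includes that term.
  cfgh <- small_config(m_snvs = 500, seed = 11)
  poph <- draw_pop(cfgh, 102, n)
  prev_h <- mean(poph$liab1 > qnorm(1 - cfgh$K_scz))
  expect_lt(abs(prev_h - cfgh$K_scz), 0.012)
})

test_that("an unfillable quota hits the rejection cap with a clear error", {
  cfg <- small_config(seed = 11)
  ref <- simulate_reference(cfg)
  testthat::local_mocked_bindings(
    sim_cohort_quota = function(...) {
      list(dosages = matrix(0L, cfg$m_snvs, 0), class = integer(0),
           g_shared = numeric(0), g_specific = numeric(0),
           liab1 = numeric(0), liab2 = numeric(0), kept = 0L,
           drawn = 1000L, case_seen = 0L, trs_seen = 0L)
    },
    .package = "gwasdiff"
  )
  expect_error(simulate_cohort(cfg, ref),
               class = "gwasdiff_error_rejection_cap")
})

test_that("the paired design shares one variant frame with disjoint controls", {
  cfg <- small_config(seed = 12)
  sim <- suppressMessages(make_paired_gwas(cfg))
  expect_identical(sim$sumstats_trs$snv_id, sim$sumstats_nontrs$snv_id)
  expect_true(all(sim$sumstats_trs$snv_id %in% sim$reference$snvs$snv_id))
  expect_identical(sim$validation$snvs$snv_id, sim$reference$snvs$snv_id)
  ids1 <- sim$cohort$samples$id[sim$cohort$samples$set == "controls_1"]
  ids2 <- sim$cohort$samples$id[sim$cohort$samples$set == "controls_2"]
  expect_identical(length(intersect(ids1, ids2)), 0L)
  expect_identical(length(ids1), 60L)
  expect_identical(length(ids2), 60L)
})

test_that("direct z simulation matches the polygenic marginal moments", {
  panel <- ld_panel(tibble::tibble(snv_id = sprintf("s%d", 1:4000),
                                   l = seq(1, 10, length.out = 4000)),
                    M = 4000)
  z0 <- simulate_sumstats_direct(0, 1e4, panel, seed = 31)
  expect_lt(abs(var(z0) - 1), 0.05)
  h2 <- 0.4; N <- 1e4
  z <- simulate_sumstats_direct(h2, N, panel, seed = 32)
  expected <- 1 + N * h2 * mean(panel$l) / panel_M(panel)
  expect_lt(abs(mean(z^2) - expected) / expected, 0.05)
  expect_identical(z, simulate_sumstats_direct(h2, N, panel, seed = 32))
  expect_error(simulate_sumstats_direct(1, 100, panel),
               class = "gwasdiff_error_domain")
})

test_that("a genotype-free trait yields labels independent of dosages", {
  cfg <- small_config(m_snvs = 1000, block_size = 1, h2_shared = 0,
                      h2_specific = 0, n_trs_cases = 400,
                      n_nontrs_cases = 400, n_controls_1 = 400,
                      n_controls_2 = 400, n_validation = 0, seed = 13)
  sim <- suppressMessages(make_paired_gwas(cfg))
  h <- suppressMessages(harmonize_sumstats(sim$sumstats_trs,
                                           sim$sumstats_nontrs))
  res <- run_interaction_gwas(h)
  lam <- lambda_gc(z = res$z)
  expect_gt(lam, 0.9)
  expect_lt(lam, 1.1)
})

test_that("null interaction p values are uniform in the full chain", {
  # Kolmogorov-Smirnov check on three independent chains of 10^4 variants:
  # with all SNV effects shared, every chain must clear alpha = 0.01.
  for (seed in 41:43) {
    cfg <- sim_config(
      m_snvs = 10000, block_size = 1, h2_shared = 0.24, h2_specific = 0,
      K_scz = 0.05, n_trs_cases = 400, n_nontrs_cases = 400,
      n_controls_1 = 400, n_controls_2 = 400, n_validation = 0,
      n_reference = 100, seed = seed
    )
    sim <- suppressMessages(make_paired_gwas(cfg))
    h <- suppressMessages(harmonize_sumstats(sim$sumstats_trs,
                                             sim$sumstats_nontrs))
    res <- run_interaction_gwas(h)
    ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("interaction heritability rises with the specific component", {
  # Seed-paired comparison: configurations differing only in h2_specific
  # share genotypes, shared effects and noise draws, so the paired
  # difference isolates the resistance-specific polygenic signal.
  h2_hat <- function(h2_specific, seed) {
    cfg <- sim_config(
      m_snvs = 2000, block_size = 10, within_block_r2 = 0.4,
      h2_shared = 0.24, h2_specific = h2_specific, K_scz = 0.05,
      n_trs_cases = 2500, n_nontrs_cases = 2500, n_controls_1 = 2500,
      n_controls_2 = 2500, n_validation = 0, n_reference = 400, seed = seed
    )
    sim <- suppressMessages(make_paired_gwas(cfg))
    h <- suppressMessages(harmonize_sumstats(sim$sumstats_trs,
                                             sim$sumstats_nontrs))
    res <- run_interaction_gwas(h)
    panel <- sim$reference$panel
    idx <- match(panel$snv_id, res$snv_id)
    keep <- !is.na(idx)
    sub <- ld_panel(panel[keep, ], M = panel_M(panel))
    estimate_h2(res$z[idx[keep]], N = 5000, panel = sub)$h2_obs
  }
  seeds <- 941:944
  null_h2 <- vapply(seeds, function(s) h2_hat(0, s), numeric(1))
  spec_h2 <- vapply(seeds, function(s) h2_hat(0.1, s), numeric(1))
  expect_gt(mean(spec_h2), mean(null_h2))
  expect_gte(sum(spec_h2 - null_h2 > 0), 3)
  expect_lt(abs(mean(null_h2)), 0.05)
})
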