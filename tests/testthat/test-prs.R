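# Reference with controlled LD: rs1/rs2 duplicated (r^2 = 1), rest independent.
make_clump_reference <- function(pos) {
  withr::with_seed(40, {
    n <- 200
    base <- rbinom(n, 2, 0.4)
    D <- cbind(base, base, rbinom(n, 2, 0.4), rbinom(n, 2, 0.4))
  })
  make_test_cohort(D, rep("x", 200), pos = pos)
}

clump_input <- function(p, pos) {
  tibble::tibble(
    snv_id = sprintf("rs%d", seq_along(p)),
    chrom = "1", pos = as.integer(pos), p = p
  )
}

test_that("clumping keeps the best of a correlated pair inside the window", {
  pos <- c(1000L, 11000L, 50000L, 90000L)
  ref <- make_clump_reference(pos)
  ss <- clump_input(c(1e-8, 1e-4, 0.5, 0.9), pos)
  kept <- clump_snvs(ss, ref, r2_threshold = 0.1, window_kb = 250)
  expect_identical(kept$snv_id, c("rs1", "rs3", "rs4"))
})

test_that("uncorrelated or distant pairs both survive clumping", {
  pos <- c(1000L, 11000L, 50000L, 90000L)
  ref0 <- make_test_cohort(withr::with_seed(41, {
    matrix(rbinom(200 * 4, 2, 0.4), 200, 4)
  }), rep("x", 200), pos = pos)
  ss <- clump_input(c(1e-8, 1e-4, 0.5, 0.9), pos)
  kept <- clump_snvs(ss, ref0, r2_threshold = 0.1, window_kb = 250)
  expect_identical(nrow(kept), 4L)

  # duplicated pair but 300 kb apart: outside the window, both kept
  far <- c(1000L, 301000L, 500000L, 700000L)
  ref_far <- make_clump_reference(far)
  kept <- clump_snvs(clump_input(c(1e-8, 1e-4, 0.5, 0.9), far), ref_far,
                     r2_threshold = 0.1, window_kb = 250)
  expect_identical(nrow(kept), 4L)
})

test_that("variants missing from the reference warn and are dropped or kept", {
  pos <- c(1000L, 11000L, 50000L, 90000L)
  ref <- make_clump_reference(pos)
  ss <- clump_input(c(1e-8, 1e-4, 0.5, 0.9), pos)
  ss$snv_id[3] <- "rs_absent"
  expect_warning(kept <- clump_snvs(ss, ref), "missing")
  expect_false("rs_absent" %in% kept$snv_id)
  expect_warning(
    kept2 <- clump_snvs(ss, ref, keep_unmatched = TRUE),
    "missing"
  )
  expect_true("rs_absent" %in% kept2$snv_id)
})

test_that("scores are weighted allele sums with mean imputation", {
  D <- rbind(c(2, 1), c(0, 2), c(1, NA))
  cohort <- make_test_cohort(D, rep("x", 3))
  w <- tibble::tibble(
    snv_id = c("rs1", "rs2"), effect_allele = "A", other_allele = "G",
    beta = c(0.1, -0.2), p = c(0.5, 0.5)
  )
  s <- prs_score(cohort, w)
  expect_equal(s$raw[1], 2 * 0.1 + 1 * -0.2)  # = 0
  expect_equal(s$raw[2], 0 * 0.1 + 2 * -0.2)
  expect_equal(s$raw[3], 1 * 0.1 + mean(c(1, 2)) * -0.2)

  doubled <- prs_score(cohort, dplyr::mutate(w, beta = beta * 2))
  expect_equal(doubled$raw, s$raw * 2)
  expect_equal(doubled$z, s$z)  # standardization absorbs the scale
})

test_that("weights are realigned to the cohort's allele frame", {
  D <- cbind(c(2, 1, 0, 1), c(0, 1, 2, 2))
  cohort <- make_test_cohort(D, rep("x", 4),
                             alleles = cbind(c("A", "C"), c("G", "T")))
  direct <- tibble::tibble(
    snv_id = c("rs1", "rs2"), effect_allele = c("A", "C"),
    other_allele = c("G", "T"), beta = c(0.3, 0.2), p = 0.5
  )
  # rs1 allele-swapped; rs2 coded on the opposite strand with swapped alleles
  swapped <- tibble::tibble(
    snv_id = c("rs1", "rs2"), effect_allele = c("G", "A"),
    other_allele = c("A", "G"), beta = c(-0.3, 0.2), p = 0.5
  )
  s1 <- prs_score(cohort, direct)
  s2 <- prs_score(cohort, swapped)
  expect_equal(s1$raw, drop(D %*% c(0.3, 0.2)))
  expect_equal(s2$raw, drop(D %*% c(0.3, -0.2)))
  # irreconcilable weights are dropped with a message
  bad <- dplyr::mutate(direct, effect_allele = c("A", "C"),
                       other_allele = c("C", "T"))
  expect_message(s3 <- prs_score(cohort, bad), "unmatched")
  expect_equal(s3$raw, D[, 2] * 0.2)
  expect_error(
    suppressMessages(
      prs_score(cohort, dplyr::mutate(bad, snv_id = c("zz1", "zz2")))
    ),
    class = "gwasdiff_error_empty"
  )
})

test_that("no variant under the threshold raises an empty-set error", {
  D <- cbind(c(2, 1, 0), c(0, 1, 2))
  cohort <- make_test_cohort(D, rep("x", 3))
  w <- tibble::tibble(snv_id = c("rs1", "rs2"), effect_allele = "A",
                      other_allele = "G", beta = c(0.1, 0.2), p = c(0.3, 0.4))
  expect_error(prs_score(cohort, w, threshold = 0.01),
               class = "gwasdiff_error_empty")
})

test_that("the logistic association recovers closed-form anchors", {
  withr::with_seed(42, {
    n <- 2000
    prs <- rnorm(n)
    y <- rbinom(n, 1, 0.3)
    fit <- associate_prs(prs, y)
    # intercept-only anchor: fitted intercept ~ logit of the case fraction
    null_fit <- glm(y ~ 1, family = binomial())
    expect_equal(unname(coef(null_fit)[1]), qlogis(mean(y)), tolerance = 1e-8)
    expect_equal(fit$n_cases, sum(y))
    expect_equal(fit$or_lower, exp(fit$beta - 1.96 * fit$se))
    td <- tidy(fit)
    expect_identical(td$term, "prs")
    expect_equal(glance(fit)$or, fit$or)
  })
})

test_that("a null PRS is rarely called significant", {
  withr::with_seed(43, {
    hits <- 0
    for (i in 1:40) {
      prs <- rnorm(400)
      y <- rbinom(400, 1, 0.4)
      fit <- associate_prs(prs, y)
      if (abs(fit$z) > 1.96) hits <- hits + 1
    }
    expect_lte(hits, 6)  # ~5% expected; 6/40 leaves slack at binomial noise
  })
})

test_that("perfect separation raises a classed error", {
  prs <- c(rep(-2, 50), rep(2, 50)) + rnorm(100, 0, 0.01)
  y <- as.integer(prs > 0)
  expect_error(associate_prs(prs, y), class = "gwasdiff_error_separation")
  expect_error(associate_prs(rnorm(10), rep(1, 10)),
               class = "gwasdiff_error_domain")
})

test_that("rank-deficient covariates are rejected", {
  withr::with_seed(44, {
    prs <- rnorm(100)
    y <- rbinom(100, 1, 0.5)
    covar <- cbind(a = rnorm(100))
    covar2 <- cbind(covar, b = covar[, 1] * 2)
    expect_error(associate_prs(prs, y, covar2),
                 class = "gwasdiff_error_domain")
    expect_s3_class(associate_prs(prs, y, covar), "prs_fit")
  })
})

test_that("Nagelkerke R2 follows its definition and bounds", {
  expect_identical(r2_nagelkerke(-100, -100, 50), 0)
  r_small <- r2_nagelkerke(-100, -95, 50)
  r_large <- r2_nagelkerke(-100, -80, 50)
  expect_gt(r_large, r_small)        # monotone in ll_full
  expect_lt(r_large, 1)
  expect_equal(r2_nagelkerke(-100, 0, 50), 1)  # saturated model bound
  expect_error(r2_nagelkerke(-100, -101, 50),
               class = "gwasdiff_error_domain")
  expect_error(r2_nagelkerke(-10, -5, 0), class = "gwasdiff_error_domain")
})

test_that("liability-scale R2 matches the closed form at K = P", {
  expect_identical(r2_liability(0, 0.25, 0.25), 0)
  # K = P = 0.5: theta = 0 and C = pi/2
  expect_equal(r2_liability(0.1, 0.5, 0.5), 0.1 * pi / 2, tolerance = 1e-12)
  expect_equal(r2_liability(0.3, 0.5, 0.5) / 0.3, 1.570796, tolerance = 1e-6)
  # monotone in r2_obs
  grid <- seq(0, 0.9, by = 0.1)
  vals <- r2_liability(grid, 0.2, 0.4)
  expect_true(all(diff(vals) > 0))
  expect_error(r2_liability(1, 0.2, 0.4), class = "gwasdiff_error_domain")
  expect_error(r2_liability(0.1, 0, 0.4), class = "gwasdiff_error_domain")
})

test_that("BH adjustment equals the brute-force definition", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(fdr_bh(0.37), 0.37)
  expect_equal(fdr_bh(c(0.001, 0.5)), c(0.002, 0.5))
  withr::with_seed(45, {
    for (i in 1:25) {
      p <- runif(sample(1:40, 1))^sample(1:3, 1)
      p <- pmin(pmax(p, 1e-12), 1)
      expect_equal(fdr_bh(p), bh_oracle(p))
    }
  })
  # q is monotone in the order statistics of p
  withr::with_seed(46, {
    p <- runif(50)
    q <- fdr_bh(p)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q >= p))
  })
})

test_that("fixed-effect pooling follows inverse-variance weights", {
  one <- meta_fixed(0.2, 0.1)
  expect_identical(one$beta, 0.2)
  expect_identical(one$se, 0.1)
  two <- meta_fixed(c(0.2, 0.2), c(0.1, 0.1))
  expect_equal(two$beta, 0.2)
  expect_equal(two$se, 0.070710678118654752, tolerance = 1e-12)
  withr::with_seed(47, {
    for (i in 1:20) {
      k <- sample(2:6, 1)
      b <- rnorm(k); s <- runif(k, 0.05, 0.5)
      pooled <- meta_fixed(b, s)
      expect_lte(pooled$se, min(s))
      expect_equal(pooled$beta, sum(b / s^2) / sum(1 / s^2))
    }
  })
  expect_error(meta_fixed(c(0.1, 0.2), 0.1), class = "gwasdiff_error_schema")
  expect_error(meta_fixed(0.1, 0), class = "gwasdiff_error_domain")
})

test_that("group profiles are standardized, centred and covariate-stable", {
  withr::with_seed(48, {
    score <- rnorm(400)
    groups <- rep(c("g1", "g2"), each = 200)
    prof <- group_profile(score, NULL, groups)
    expect_identical(nrow(prof), 2L)
    # both groups drawn from one distribution: means inside their own CI of 0
    expect_true(all(prof$ci_lower < 0 & prof$ci_upper > 0))
    # grand standardized mean is zero by construction
    expect_equal(sum(prof$mean * prof$n) / sum(prof$n), 0, tolerance = 1e-12)
    # a constant covariate changes nothing
    prof2 <- group_profile(score, cbind(rep(1, 400)), groups)
    expect_equal(prof2$mean, prof$mean, tolerance = 1e-12)
    expect_error(group_profile(score, NULL, rep("g1", 400)),
                 class = "gwasdiff_error_domain")
    expect_error(group_profile(score, NULL, c("g2", rep("g1", 399))),
                 class = "gwasdiff_error_domain")
  })
})

test_that("the threshold scan is monotone in variant count with shared FDR", {
  withr::with_seed(50, {
    n <- 300; m <- 60
    D <- matrix(rbinom(n * m, 2, 0.4), n, m)
    risk <- scale(D[, 1:10]) %*% rep(0.4, 10)
    y <- rbinom(n, 1, stats::plogis(-0.5 + drop(risk)))
    cohort <- make_test_cohort(D, ifelse(y == 1, "case", "control"),
                               pos = as.integer(seq_len(m) * 400000L))
    train <- suppressMessages(run_gwas(cohort, "case", "control"))
  })
  scan <- suppressMessages(threshold_scan(
    train, cohort, cohort, phenotype = y,
    thresholds = c(1e-10, 0.01, 0.1, 0.5, 1), K = 0.3
  ))
  # the hopeless threshold is skipped; counts grow with the cutoff
  expect_lte(nrow(scan), 5L)
  expect_true(all(diff(scan$n_snvs_used[order(scan$threshold)]) >= 0))
  expect_true(all(scan$q >= scan$p))
  expect_true(all(scan$r2_nagelkerke >= 0 & scan$r2_nagelkerke <= 1))
  best <- max(scan$r2_nagelkerke)
  expect_true(all(scan$r2_nagelkerke <= best))
  # rerunning the scan reproduces it exactly
  scan2 <- suppressMessages(threshold_scan(
    train, cohort, cohort, phenotype = y,
    thresholds = c(1e-10, 0.01, 0.1, 0.5, 1), K = 0.3
  ))
  expect_identical(scan, scan2)
})

test_that("a real covariate shift is removed by residualization", {
  withr::with_seed(49, {
    covar <- rnorm(500)
    groups <- rep(c("a", "b"), 250)
    score <- 2 * covar + rnorm(500, 0, 0.2)  # group-independent confounding
    prof <- group_profile(score, cbind(covar), groups)
    expect_true(all(abs(prof$mean) < 0.2))
  })
})
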