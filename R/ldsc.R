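#' Construct an LD score panel
#'
#' An LD score panel holds, for each scored variant, the sum of squared
#' correlations with the variants of its LD neighbourhood (including itself,
#' so `l >= 1`), together with `M`, the total number of panel variants the
#' polygenic model is spread over.
#'
#' @param scores A tibble with columns `snv_id` and `l`.
#' @param M Total panel variant count (`M >= nrow(scores)`).
#' @return The panel: a tibble of class `ld_panel` with attribute `M`.
#' @export
ld_panel <- function(scores, M) {
  if (!all(c("snv_id", "l") %in% names(scores))) {
    stop_gwasdiff("`scores` needs columns snv_id and l", "gwasdiff_error_schema")
  }
  if (any(!is.finite(scores$l)) || any(scores$l < 1)) {
    stop_gwasdiff("LD scores must be finite and >= 1 (self r^2 included)",
                  "gwasdiff_error_domain")
  }
  if (M < nrow(scores)) {
    stop_gwasdiff("M must be at least the number of scored variants",
                  "gwasdiff_error_domain")
  }
  out <- tibble::as_tibble(scores[, c("snv_id", "l")])
  attr(out, "M") <- as.integer(M)
  class(out) <- c("ld_panel", class(out))
  out
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("<ld_panel> %d scored variants, M = %d, mean l = %.3f\n",
              nrow(x), panel_M(x), mean(x$l)))
  NextMethod()
}

#' Total variant count of an LD score panel
#' @param panel An [ld_panel()].
#' @return Integer `M`.
#' @export
panel_M <- function(panel) {
  M <- attr(panel, "M")
  if (is.null(M)) {
    stop_gwasdiff("panel has no M attribute; construct it with ld_panel()",
                  "gwasdiff_error_schema")
  }
  M
}

#' Compute LD scores from reference dosages
#'
#' For each variant `j`, `l_j` is the sum over the variants `k` of its LD
#' block of the squared Pearson correlation of dosages, including `k = j`.
#' Variants with zero dosage variance carry no LD information and are
#' dropped with a message.
#'
#' @param dosages Numeric matrix, individuals by variants (at least two
#'   individuals).
#' @param blocks Integer vector assigning each variant to an LD block.
#' @param snv_id Optional variant identifiers (defaults to column names or
#'   `snv_*`).
#' @param M Panel size recorded in the result (defaults to the number of
#'   variants supplied, before dropping).
#' @return An [ld_panel()].
#' @export
compute_ld_scores <- function(dosages, blocks, snv_id = NULL, M = ncol(dosages)) {
  if (nrow(dosages) < 2) {
    stop_gwasdiff("need at least two individuals to correlate dosages",
                  "gwasdiff_error_domain")
  }
  m <- ncol(dosages)
  if (length(blocks) != m) {
    stop_gwasdiff("`blocks` must have one entry per variant",
                  "gwasdiff_error_schema")
  }
  if (is.null(snv_id)) {
    snv_id <- colnames(dosages) %||% sprintf("snv_%06d", seq_len(m))
  }
  v <- apply(dosages, 2, var)
  keep <- v > 0
  if (!any(keep)) {
    stop_gwasdiff("all variants have constant dosages", "gwasdiff_error_domain")
  }
  if (any(!keep)) {
    inform(sprintf("dropping %d zero-variance variant(s) from LD scoring",
                   sum(!keep)))
  }
  idx <- which(keep)
  l <- rep(NA_real_, m)
  for (b in split(idx, blocks[idx])) {
    if (length(b) == 1) {
      l[b] <- 1
    } else {
      r2 <- cor(dosages[, b, drop = FALSE])^2
      l[b] <- rowSums(r2)
    }
  }
  ld_panel(tibble::tibble(snv_id = snv_id[keep], l = l[keep]), M = M)
}

#' Write / read an LD score panel TSV
#'
#' The file is a two-column TSV (`SNP`, `L2`) preceded by a `# M=<count>`
#' metadata line.
#'
#' @param panel An [ld_panel()].
#' @param path File path.
#' @return `path` (write) or the panel (read).
#' @export
write_ld_panel <- function(panel, path) {
  writeLines(sprintf("# M=%d", panel_M(panel)), path)
  readr::write_tsv(
    tibble::tibble(SNP = panel$snv_id, L2 = panel$l),
    path, append = TRUE, col_names = TRUE, progress = FALSE
  )
  invisible(path)
}

#' @rdname write_ld_panel
#' @export
read_ld_panel <- function(path) {
  first <- readLines(path, n = 1L)
  M <- as.integer(sub("^# *M=", "", first))
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  ld_panel(tibble::tibble(snv_id = as.character(tbl$SNP), l = tbl$L2), M = M)
}

# Weighted two-parameter regression machinery --------------------------------

ldsc_blocks <- function(n_snvs, n_blocks) {
  n_blocks <- min(n_blocks, floor(n_snvs / 10))
  if (n_blocks < 2) {
    stop_gwasdiff("too few variants for a block jackknife (need >= 20)",
                  "gwasdiff_error_domain")
  }
  sort(rep_len(seq_len(n_blocks), n_snvs))
}

# Weighted least squares of y on (1, x) with a delete-a-block jackknife.
# Returns full-fit coefficients and the B delete-block coefficient pairs.
wls_jackknife <- function(y, x, w, blocks) {
  X <- cbind(intercept = 1, slope = x)
  wX <- X * w
  xtx_b <- rowsum(cbind(wX[, 1] * X[, 1], wX[, 1] * X[, 2], wX[, 2] * X[, 2]),
                  blocks)
  xty_b <- rowsum(wX * y, blocks)
  solve2 <- function(sxx) {
    # sxx = c(s11, s12, s22, t1, t2)
    det <- sxx[1] * sxx[3] - sxx[2]^2
    if (!is.finite(det) || abs(det) < 1e-12 * max(sxx[1] * sxx[3], 1)) {
      stop_gwasdiff(
        "degenerate regression design (constant LD scores?); slope and intercept are not identifiable",
        "gwasdiff_error_degenerate"
      )
    }
    unname(c((sxx[3] * sxx[4] - sxx[2] * sxx[5]) / det,
             (sxx[1] * sxx[5] - sxx[2] * sxx[4]) / det))
  }
  tot <- c(colSums(xtx_b), colSums(xty_b))
  full <- solve2(tot)
  B <- nrow(xtx_b)
  del <- matrix(NA_real_, B, 2)
  for (b in seq_len(B)) {
    del[b, ] <- solve2(tot - c(xtx_b[b, ], xty_b[b, ]))
  }
  list(coef = full, delete = del, n_blocks = B)
}

jackknife_se <- function(theta_b) {
  B <- sum(is.finite(theta_b))
  tb <- theta_b[is.finite(theta_b)]
  sqrt((B - 1) / B * sum((tb - mean(tb))^2))
}

ldsc_weights <- function(y, x, l) {
  ols <- lm.fit(cbind(1, x), y)$coefficients
  mu <- pmax(ols[1] + pmin(pmax(ols[2], 0), 1) * x, 0.1)
  list(mu = mu, w = 1 / (pmax(l, 1) * mu^2))
}

#' Estimate SNV-based heritability by LD score regression
#'
#' Regresses per-variant association chi-squares on scaled LD scores. Under a
#' polygenic model, `E[chi2_j] = intercept + N * h2 * l_j / M`: the slope of
#' the regression is the observed-scale SNV heritability and the free
#' intercept absorbs confounding inflation (it is 1 in its absence).
#'
#' The regression is weighted by `1 / (l_j * mu_j^2)`, where `mu_j` is the
#' fitted mean chi-square from a preliminary unweighted pass — the `1/l`
#' factor down-weights variants counted repeatedly through LD, and `1/mu^2`
#' is inverse-variance weighting for chi-square heteroskedasticity. The
#' weights are updated once (single step), not iterated. Standard errors
#' come from a delete-a-block jackknife over contiguous blocks of variants
#' (`n_blocks`, automatically reduced to `floor(n_snvs / 10)` when variants
#' are few).
#'
#' @param z Z scores, aligned to (same length and order as) `panel`.
#' @param N GWAS sample size (total individuals).
#' @param panel An [ld_panel()].
#' @param n_blocks Jackknife block count (default 200).
#' @return An object of class `ldsc_fit` with elements `intercept`,
#'   `h2_obs`, `se_intercept`, `se_h2`, `n_blocks`, `n_snvs`, `N`, `M`.
#' @export
estimate_h2 <- function(z, N, panel, n_blocks = 200) {
  if (length(z) != nrow(panel)) {
    stop_gwasdiff("`z` must be aligned to the panel (same length and order)",
                  "gwasdiff_error_schema")
  }
  if (!is.finite(N) || N <= 1) {
    stop_gwasdiff("`N` must exceed 1", "gwasdiff_error_domain")
  }
  M <- panel_M(panel)
  y <- z^2
  x <- N * panel$l / M
  blocks <- ldsc_blocks(length(z), n_blocks)
  wt <- ldsc_weights(y, x, panel$l)
  fit <- wls_jackknife(y, x, wt$w, blocks)
  structure(
    list(
      mode = "h2",
      intercept = fit$coef[1], h2_obs = fit$coef[2],
      se_intercept = jackknife_se(fit$delete[, 1]),
      se_h2 = jackknife_se(fit$delete[, 2]),
      n_blocks = fit$n_blocks, n_snvs = length(z), N = N, M = M,
      delete_values = fit$delete, block_id = blocks, mu = wt$mu
    ),
    class = "ldsc_fit"
  )
}

#' Estimate cross-trait genetic correlation by LD score regression
#'
#' Regresses the per-variant product `z1 * z2` on `sqrt(N1 * N2) * l / M`
#' with a free intercept; the slope estimates the genetic covariance, and
#' the genetic correlation is `rg = cov / sqrt(h2_1 * h2_2)` with the
#' per-trait heritabilities estimated by [estimate_h2()] on the same panel.
#' The jackknife recomputes the full ratio in every delete-block replicate,
#' so `se_rg` propagates the uncertainty of all three regressions.
#'
#' No sample-overlap intercept constraint is applied: the intended design is
#' two studies with disjoint samples, where the cross-trait intercept is
#' zero in expectation but is still estimated freely.
#'
#' If either per-trait heritability estimate is non-positive the correlation
#' is undefined; the fit is returned with `rg = NA` and `rg_defined = FALSE`.
#'
#' @param z1,z2 Z score vectors aligned to `panel`.
#' @param N1,N2 The two sample sizes.
#' @param panel An [ld_panel()].
#' @param n_blocks Jackknife block count.
#' @return An `ldsc_fit` in pair mode: adds `rg`, `se_rg`, `rg_defined`,
#'   `gencov`, `intercept_xy` and the per-trait fits `fit1`, `fit2`.
#' @export
estimate_rg <- function(z1, N1, z2, N2, panel, n_blocks = 200) {
  fit1 <- estimate_h2(z1, N1, panel, n_blocks)
  fit2 <- estimate_h2(z2, N2, panel, n_blocks)
  M <- panel_M(panel)
  y12 <- z1 * z2
  x12 <- sqrt(N1 * N2) * panel$l / M
  blocks <- fit1$block_id
  ols12 <- lm.fit(cbind(1, x12), y12)$coefficients
  mu12 <- ols12[1] + ols12[2] * x12
  w12 <- 1 / (pmax(panel$l, 1) * (fit1$mu * fit2$mu + mu12^2))
  cross <- wls_jackknife(y12, x12, w12, blocks)

  rg_from <- function(cov, h1, h2) {
    if (!is.finite(cov) || !is.finite(h1) || !is.finite(h2) ||
        h1 <= 0 || h2 <= 0) {
      return(NA_real_)
    }
    cov / sqrt(h1 * h2)
  }
  rg <- rg_from(cross$coef[2], fit1$h2_obs, fit2$h2_obs)
  rg_del <- vapply(seq_len(cross$n_blocks), function(b) {
    rg_from(cross$delete[b, 2], fit1$delete_values[b, 2],
            fit2$delete_values[b, 2])
  }, numeric(1))
  defined <- is.finite(rg)
  if (!defined) {
    warn("non-positive heritability estimate; genetic correlation undefined")
  }
  structure(
    list(
      mode = "rg",
      rg = rg,
      se_rg = if (defined) jackknife_se(rg_del) else NA_real_,
      rg_defined = defined,
      gencov = cross$coef[2], intercept_xy = cross$coef[1],
      se_gencov = jackknife_se(cross$delete[, 2]),
      fit1 = fit1, fit2 = fit2,
      n_blocks = cross$n_blocks, n_snvs = length(z1), M = M
    ),
    class = "ldsc_fit"
  )
}

#' @export
print.ldsc_fit <- function(x, ...) {
  if (x$mode == "h2") {
    cat(sprintf(
      "<ldsc_fit> h2_obs = %.4f (SE %.4f), intercept = %.4f (SE %.4f), %d variants, %d jackknife blocks\n",
      x$h2_obs, x$se_h2, x$intercept, x$se_intercept, x$n_snvs, x$n_blocks
    ))
  } else {
    cat(sprintf(
      "<ldsc_fit> rg = %.4f (SE %.4f), gencov = %.4f, h2_1 = %.4f, h2_2 = %.4f\n",
      x$rg, x$se_rg, x$gencov, x$fit1$h2_obs, x$fit2$h2_obs
    ))
  }
  invisible(x)
}

#' Convert observed-scale heritability to the liability scale
#'
#' The standard transform for a binary trait under the liability-threshold
#' model: `h2_liab = h2_obs * K^2 (1-K)^2 / (z^2 P (1-P))`, where `K` is the
#' population prevalence, `P` the sample case fraction, and `z` the standard
#' normal density at the liability threshold `qnorm(1 - K)`.
#'
#' @param h2_obs Observed-scale heritability.
#' @param K Population prevalence, in (0, 1).
#' @param P Sample case fraction, in (0, 1).
#' @return Liability-scale heritability.
#' @export
h2_observed_to_liability <- function(h2_obs, K, P) {
  check_prob(K, "K")
  check_prob(P, "P")
  zd <- dnorm(qnorm(1 - K))
  h2_obs * K^2 * (1 - K)^2 / (zd^2 * P * (1 - P))
}
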