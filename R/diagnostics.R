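#' Genomic inflation factor
#'
#' The genomic control lambda: the median association chi-square divided by
#' the median of the chi-square distribution with one degree of freedom
#' (0.4549364). Values near 1 indicate a well-calibrated test statistic;
#' values above 1 indicate inflation, whether from confounding or from true
#' polygenic signal.
#'
#' @param p Two-sided P values in (0, 1\]; converted to chi-square via the
#'   upper-tail quantile transform. Supply exactly one of `p` or `z`.
#' @param z Z scores; squared to chi-square.
#' @return The scalar inflation factor.
#' @export
lambda_gc <- function(p = NULL, z = NULL) {
  if (is.null(p) == is.null(z)) {
    stop_gwasdiff("supply exactly one of `p` or `z`", "gwasdiff_error_domain")
  }
  if (!is.null(z)) {
    if (length(z) == 0 || any(!is.finite(z))) {
      stop_gwasdiff("`z` must be non-empty and finite", "gwasdiff_error_domain")
    }
    chi2 <- z^2
  } else {
    if (length(p) == 0) {
      stop_gwasdiff("`p` must be non-empty", "gwasdiff_error_domain")
    }
    check_prob(p, "p", open_left = TRUE, open_right = FALSE)
    chi2 <- qchisq(p, df = 1, lower.tail = FALSE)
  }
  median(chi2) / qchisq(0.5, df = 1)
}

#' Rescale lambda to a 1000-case / 1000-control study
#'
#' Genomic inflation grows with sample size even for a fixed confounding
#' level, so lambdas from different studies are compared after rescaling to a
#' nominal 1000/1000 design:
#' `lambda_1000 = 1 + (lambda - 1) * (1/n1 + 1/n2) / (2/1000)`.
#' For the case-case difference statistic, `n1` and `n2` are the two case
#' group sizes.
#'
#' @param lambda Inflation factor from [lambda_gc()].
#' @param n1,n2 Sizes of the two compared groups.
#' @return The rescaled inflation factor.
#' @export
lambda_1000 <- function(lambda, n1, n2) {
  if (any(!is.finite(c(n1, n2))) || n1 <= 0 || n2 <= 0) {
    stop_gwasdiff("group sizes must be positive", "gwasdiff_error_domain")
  }
  if (!is.finite(lambda) || lambda < 0) {
    stop_gwasdiff("`lambda` must be non-negative", "gwasdiff_error_domain")
  }
  1 + (lambda - 1) * (1 / n1 + 1 / n2) / (1 / 1000 + 1 / 1000)
}

#' Observed-versus-expected quantile table for P values
#'
#' Pairs the sorted observed `-log10(P)` with the expected quantiles
#' `-log10((rank - 0.5) / n)` of the uniform distribution, the standard Q-Q
#' construction for GWAS calibration plots.
#'
#' @param p P values in (0, 1\].
#' @return A tibble with columns `expected` and `observed` (both `-log10`
#'   scale), sorted so observed `-log10(P)` is ascending.
#' @export
qq_table <- function(p) {
  if (length(p) == 0) {
    stop_gwasdiff("`p` must be non-empty", "gwasdiff_error_domain")
  }
  check_prob(p, "p", open_left = TRUE, open_right = FALSE)
  n <- length(p)
  obs <- sort(p, decreasing = TRUE)
  tibble::tibble(
    expected = -log10((n:1 - 0.5) / n),
    observed = -log10(obs)
  )
}

#' Inflation report for an association scan
#'
#' @param p P values of the scan (or give `z`).
#' @param z Alternative to `p`: z scores.
#' @param n1,n2 Group sizes used for the lambda-1000 rescaling.
#' @return A one-row tibble: `lambda_gc`, `lambda_1000`, `n_snvs`,
#'   `median_chi2`.
#' @export
inflation_report <- function(p = NULL, z = NULL, n1, n2) {
  lam <- lambda_gc(p = p, z = z)
  tibble::tibble(
    lambda_gc = lam,
    lambda_1000 = lambda_1000(lam, n1, n2),
    n_snvs = length(p %||% z),
    median_chi2 = lam * qchisq(0.5, df = 1)
  )
}
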