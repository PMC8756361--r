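#' Tidy an LD score regression fit
#'
#' @param x An `ldsc_fit` from [estimate_h2()] or [estimate_rg()].
#' @param ... Unused.
#' @return A tibble with one row per estimated quantity: `term`,
#'   `estimate`, `std.error`.
#' @export
tidy.ldsc_fit <- function(x, ...) {
  if (x$mode == "h2") {
    tibble::tibble(
      term = c("intercept", "h2_obs"),
      estimate = c(x$intercept, x$h2_obs),
      std.error = c(x$se_intercept, x$se_h2)
    )
  } else {
    tibble::tibble(
      term = c("rg", "gencov", "intercept_xy", "h2_obs_1", "h2_obs_2"),
      estimate = c(x$rg, x$gencov, x$intercept_xy,
                   x$fit1$h2_obs, x$fit2$h2_obs),
      std.error = c(x$se_rg, x$se_gencov, NA_real_,
                    x$fit1$se_h2, x$fit2$se_h2)
    )
  }
}

#' @rdname tidy.ldsc_fit
#' @export
glance.ldsc_fit <- function(x, ...) {
  if (x$mode == "h2") {
    tibble::tibble(
      h2_obs = x$h2_obs, se_h2 = x$se_h2,
      intercept = x$intercept, se_intercept = x$se_intercept,
      n_snvs = x$n_snvs, n_blocks = x$n_blocks, N = x$N, M = x$M
    )
  } else {
    tibble::tibble(
      rg = x$rg, se_rg = x$se_rg, rg_defined = x$rg_defined,
      gencov = x$gencov, h2_obs_1 = x$fit1$h2_obs, h2_obs_2 = x$fit2$h2_obs,
      n_snvs = x$n_snvs, n_blocks = x$n_blocks
    )
  }
}

#' Tidy a polygenic-score association fit
#'
#' @param x A `prs_fit` from [associate_prs()].
#' @param ... Unused.
#' @return One-row tibble of the PRS term (`tidy`) or of the fit summary
#'   (`glance`).
#' @export
tidy.prs_fit <- function(x, ...) {
  tibble::tibble(
    term = "prs", estimate = x$beta, std.error = x$se,
    statistic = x$z, p.value = x$p
  )
}

#' @rdname tidy.prs_fit
#' @export
glance.prs_fit <- function(x, ...) {
  tibble::tibble(
    or = x$or, or_lower = x$or_lower, or_upper = x$or_upper,
    p = x$p, r2_nagelkerke = x$r2_nagelkerke, auc = x$auc,
    n = x$n, n_cases = x$n_cases
  )
}
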