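#' Run the full case-case analysis end to end
#'
#' Orchestrates every stage on a simulated design: paired discovery GWASs
#' (disjoint controls) — harmonization — interaction GWAS — inflation
#' diagnostics — LD score regression (heritability of the interaction
#' statistics, genetic correlation of the two discovery GWASs) — clumping +
#' thresholding polygenic scores validated on the held-out case cohort,
#' with FDR correction within the scan and group polygenic profiles.
#'
#' When `out_dir` is given every stage writes its table as a TSV preceded
#' by a provenance header (package version, seed, configuration hash), and
#' a `summary.tsv` aggregates the headline metrics; re-running with the
#' same configuration and seed reproduces the outputs byte for byte.
#'
#' @param config A [sim_config()]; its `seed` drives all randomness.
#' @param out_dir Optional output directory (created if needed).
#' @param thresholds P-value grid for the polygenic-score scan.
#' @param ldsc_n_blocks Jackknife block count for the LDSC fits.
#' @param K_grid Prevalence values over which the liability-scale
#'   conversions are reported (the TRS share of cases is uncertain —
#'   roughly 20-30% — so results that depend on it are shown over a grid).
#' @param n_pcs Number of dosage principal components used as covariates
#'   in the validation association.
#' @return A list: `sim` (the [make_paired_gwas()] result), `harmonized`,
#'   `interaction`, `inflation`, `h2_interaction` (`ldsc_fit`),
#'   `rg_discovery` (`ldsc_fit`), `prs_scan`, `prs_scan_nontrs`,
#'   `profile`, `liability_grid`, and the one-row-per-metric `summary`
#'   tibble.
#' @export
run_pipeline <- function(config = sim_config(seed = 1), out_dir = NULL,
                         thresholds = c(5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1,
                                        0.5, 1),
                         ldsc_n_blocks = 200,
                         K_grid = c(0.20, 0.25, 0.30), n_pcs = 4) {
  t0 <- Sys.time()
  inform("stage simulate: paired discovery GWASs + validation cohort")
  sim <- make_paired_gwas(config)

  inform("stage harmonize")
  harmonized <- harmonize_sumstats(sim$sumstats_trs, sim$sumstats_nontrs)

  inform("stage interact")
  interaction <- run_interaction_gwas(harmonized)
  if (nrow(interaction) == 0) {
    stop_gwasdiff("interaction table is empty after harmonization",
                  "gwasdiff_error_empty")
  }
  inflation <- inflation_report(p = interaction$p,
                                n1 = config$n_trs_cases,
                                n2 = config$n_nontrs_cases)

  inform("stage ldsc")
  panel <- sim$reference$panel
  int_aligned <- interaction[match(panel$snv_id, interaction$snv_id), ]
  keep <- !is.na(int_aligned$snv_id)
  sub_panel <- ld_panel(panel[keep, ], M = panel_M(panel))
  n_int <- config$n_trs_cases + config$n_nontrs_cases
  h2_int <- estimate_h2(int_aligned$z[keep], N = n_int, panel = sub_panel,
                        n_blocks = ldsc_n_blocks)

  z1 <- align_z(sim$sumstats_trs, panel)
  z2 <- align_z(sim$sumstats_nontrs, panel)
  ok <- !is.na(z1) & !is.na(z2)
  rg_panel <- ld_panel(panel[ok, ], M = panel_M(panel))
  rg <- estimate_rg(z1[ok], config$n_trs_cases + config$n_controls_1,
                    z2[ok], config$n_nontrs_cases + config$n_controls_2,
                    rg_panel, n_blocks = ldsc_n_blocks)

  prs_scan <- prs_scan_nontrs <- profile <- liability_grid <- NULL
  if (!is.null(sim$validation)) {
    inform("stage prs")
    val <- sim$validation
    covar <- cbind(sex = val$samples$sex, cohort_pcs(val, k = n_pcs))
    int_ss <- interaction_as_sumstats(interaction, config$n_trs_cases,
                                      config$n_nontrs_cases)
    prs_scan <- threshold_scan(
      int_ss, val, sim$reference, covariates = covar,
      thresholds = thresholds, K = config$trs_fraction
    )
    prs_scan_nontrs <- threshold_scan(
      sim$sumstats_nontrs, val, sim$reference, covariates = covar,
      thresholds = thresholds, K = config$trs_fraction
    )
    best <- prs_scan[which.max(prs_scan$r2_nagelkerke), ]
    score <- prs_score(val, clump_snvs(int_ss, sim$reference),
                       threshold = best$threshold)
    profile <- group_profile(score, covar, val$samples$label)
    liability_grid <- tidyr::crossing(K = K_grid) |>
      dplyr::mutate(r2_liability = r2_liability(
        best$r2_nagelkerke, .data$K,
        mean(val$samples$label == "case_TRS")
      ))
  }

  summary <- pipeline_summary(config, harmonized, interaction, inflation,
                              h2_int, rg, prs_scan)
  result <- list(
    sim = sim, harmonized = harmonized, interaction = interaction,
    inflation = inflation, h2_interaction = h2_int, rg_discovery = rg,
    prs_scan = prs_scan, prs_scan_nontrs = prs_scan_nontrs,
    profile = profile, liability_grid = liability_grid, summary = summary
  )
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, config, out_dir)
  }
  inform(sprintf("pipeline finished in %.1f s",
                 as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  result
}

align_z <- function(sumstats, panel) {
  i <- match(panel$snv_id, sumstats$snv_id)
  (sumstats$beta / sumstats$se)[i]
}

pipeline_summary <- function(config, harmonized, interaction, inflation,
                             h2_int, rg, prs_scan) {
  rows <- list(
    c("n_snvs_simulated", config$m_snvs),
    c("n_snvs_harmonized", nrow(harmonized)),
    c("n_snvs_excluded", sum(harmonized$excluded)),
    c("n_snvs_interaction", nrow(interaction)),
    c("lambda_gc", inflation$lambda_gc),
    c("lambda_1000", inflation$lambda_1000),
    c("ldsc_intercept_interaction", h2_int$intercept),
    c("h2_obs_interaction", h2_int$h2_obs),
    c("h2_obs_interaction_se", h2_int$se_h2),
    c("rg_discovery", rg$rg),
    c("rg_discovery_se", rg$se_rg)
  )
  if (!is.null(prs_scan) && nrow(prs_scan) > 0) {
    best <- prs_scan[which.max(prs_scan$r2_nagelkerke), ]
    rows <- c(rows, list(
      c("prs_best_threshold", best$threshold),
      c("prs_n_snvs_used", best$n_snvs_used),
      c("prs_or_per_sd", best$or),
      c("prs_or_lower", best$or_lower),
      c("prs_or_upper", best$or_upper),
      c("prs_p", best$p),
      c("prs_q_fdr", best$q),
      c("prs_r2_nagelkerke", best$r2_nagelkerke),
      c("prs_r2_liability", best$r2_liability)
    ))
  }
  tibble::tibble(
    metric = vapply(rows, `[`, "", 1),
    value = as.numeric(vapply(rows, `[`, "", 2))
  )
}

config_hash <- function(config) {
  rlang::hash(config[order(names(unclass(config)))])
}

write_tsv_provenance <- function(tbl, path, config) {
  header <- sprintf(
    "# gwasdiff %s | seed=%s | config=%s",
    as.character(utils::packageVersion("gwasdiff")),
    if (is.null(config$seed)) "NA" else config$seed,
    config_hash(config)
  )
  writeLines(header, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

write_pipeline_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tbl, name) {
    if (!is.null(tbl)) {
      write_tsv_provenance(tbl, file.path(out_dir, name), config)
    }
  }
  w(result$sim$sumstats_trs, "sumstats_trs.tsv")
  w(result$sim$sumstats_nontrs, "sumstats_nontrs.tsv")
  w(result$harmonized, "harmonized.tsv")
  w(result$interaction, "interaction.tsv")
  w(result$inflation, "inflation.tsv")
  w(tidy(result$h2_interaction), "ldsc_h2_interaction.tsv")
  w(tidy(result$rg_discovery), "ldsc_rg_discovery.tsv")
  w(result$prs_scan, "prs_scan_interaction.tsv")
  w(result$prs_scan_nontrs, "prs_scan_nontrs.tsv")
  w(result$profile, "prs_group_profile.tsv")
  w(result$liability_grid, "prs_liability_grid.tsv")
  w(result$summary, "summary.tsv")
  invisible(out_dir)
}
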