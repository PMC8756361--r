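#' Read a GWAS summary-statistics file
#'
#' Reads a tab- or whitespace-delimited association table with a header row
#' into the package's canonical tibble layout and validates every record.
#' Files may report effects as odds ratios (`OR` column) or directly on the
#' log-odds scale (`BETA` column); odds ratios are converted with
#' `beta = log(OR)`.
#'
#' The canonical column names are `SNP`, `CHR`, `BP`, `A1` (effect allele),
#' `A2` (other allele), `EAF`, `OR` or `BETA`, `SE`, `P`, `N_CAS`, `N_CON`.
#' Files using other headers are accommodated through `dialect`, a named
#' character vector mapping canonical names to the names found in the file,
#' e.g. `c(SNP = "rsid", BP = "position")`.
#'
#' @param path Path to the summary-statistics file.
#' @param dialect Optional named character vector remapping canonical column
#'   names to the file's column names.
#' @return A tibble with columns `snv_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `p`, `n_cases`, `n_controls`, in
#'   file row order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tCHR\tBP\tA1\tA2\tEAF\tOR\tSE\tP\tN_CAS\tN_CON",
#'              "rs1\t1\t1000\tA\tG\t0.3\t1.0\t0.05\t1.0\t100\t100"), f)
#' read_sumstats(f)
read_sumstats <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    stop_gwasdiff(sprintf("file not found: %s", path), "gwasdiff_error_io")
  }
  first <- readLines(path, n = 1L)
  # read as character (an allele "T" must not be guessed as logical) and
  # convert explicitly below
  raw <- if (grepl("\t", first)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = "c"))
  } else {
    readr::read_table(path, show_col_types = FALSE, progress = FALSE,
                      col_types = readr::cols(.default = "c"))
  }
  names(raw) <- apply_dialect(names(raw), dialect)

  has_or <- "OR" %in% names(raw)
  has_beta <- "BETA" %in% names(raw)
  mandatory <- c("SNP", "CHR", "BP", "A1", "A2", "EAF", "SE", "P",
                 "N_CAS", "N_CON")
  missing <- setdiff(mandatory, names(raw))
  if (!has_or && !has_beta) missing <- c(missing, "OR/BETA")
  if (length(missing) > 0) {
    stop_gwasdiff(
      sprintf("missing mandatory column(s): %s", paste(missing, collapse = ", ")),
      "gwasdiff_error_schema"
    )
  }

  tbl <- tibble::tibble(
    snv_id = as.character(raw$SNP),
    chrom = as.character(raw$CHR),
    pos = as.integer(raw$BP),
    effect_allele = toupper(as.character(raw$A1)),
    other_allele = toupper(as.character(raw$A2)),
    eaf = as.numeric(raw$EAF),
    se = as.numeric(raw$SE),
    p = as.numeric(raw$P),
    n_cases = as.integer(raw$N_CAS),
    n_controls = as.integer(raw$N_CON)
  )
  if (has_or && !has_beta) {
    or <- as.numeric(raw$OR)
    bad <- which(!is.finite(or) | or <= 0)
    if (length(bad) > 0) {
      stop_gwasdiff(row_diag("OR must be finite and > 0", bad),
                    "gwasdiff_error_validation")
    }
    tbl$beta <- log(or)
  } else {
    tbl$beta <- as.numeric(raw$BETA)
  }
  tbl <- tbl[, sumstats_cols()]
  validate_sumstats(tbl)
}

sumstats_cols <- function() {
  c("snv_id", "chrom", "pos", "effect_allele", "other_allele",
    "eaf", "beta", "se", "p", "n_cases", "n_controls")
}

apply_dialect <- function(nms, dialect) {
  if (is.null(dialect)) return(nms)
  if (is.null(names(dialect)) || any(names(dialect) == "")) {
    stop_gwasdiff("`dialect` must be a fully named character vector",
                  "gwasdiff_error_schema")
  }
  for (canonical in names(dialect)) {
    nms[nms == dialect[[canonical]]] <- canonical
  }
  nms
}

row_diag <- function(msg, rows) {
  shown <- head(rows, 5L)
  sprintf("%s (row%s %s%s)", msg, if (length(rows) > 1) "s" else "",
          paste(shown, collapse = ", "),
          if (length(rows) > length(shown)) ", ..." else "")
}

#' Validate a summary-statistics tibble
#'
#' Checks the record-level invariants of the canonical layout: single-base
#' distinct alleles, `eaf` in \[0, 1\], `se > 0`, `p` in (0, 1\], positive
#' sample counts, and unique variant identifiers. Called by [read_sumstats()]
#' and [write_sumstats()]; exported so externally assembled tables can be
#' checked too.
#'
#' @param tbl A tibble in the layout of [read_sumstats()].
#' @return `tbl`, invisibly unchanged, if valid; otherwise an error carrying
#'   row-level diagnostics.
#' @export
validate_sumstats <- function(tbl) {
  need <- setdiff(sumstats_cols(), names(tbl))
  if (length(need) > 0) {
    stop_gwasdiff(sprintf("missing column(s): %s", paste(need, collapse = ", ")),
                  "gwasdiff_error_schema")
  }
  fail <- function(cond, what) {
    bad <- which(cond)
    if (length(bad) > 0) {
      stop_gwasdiff(row_diag(what, bad), "gwasdiff_error_validation")
    }
  }
  bases <- c("A", "C", "G", "T")
  fail(!tbl$effect_allele %in% bases, "effect allele must be one of A/C/G/T")
  fail(!tbl$other_allele %in% bases, "other allele must be one of A/C/G/T")
  fail(tbl$effect_allele == tbl$other_allele, "alleles must differ")
  fail(!is.finite(tbl$eaf) | tbl$eaf < 0 | tbl$eaf > 1, "EAF must be in [0, 1]")
  fail(!is.finite(tbl$beta), "beta must be finite")
  fail(!is.finite(tbl$se) | tbl$se <= 0, "SE must be > 0")
  fail(!is.finite(tbl$p) | tbl$p <= 0 | tbl$p > 1, "P must be in (0, 1]")
  fail(is.na(tbl$n_cases) | tbl$n_cases <= 0, "N_CAS must be a positive integer")
  fail(is.na(tbl$n_controls) | tbl$n_controls <= 0,
       "N_CON must be a positive integer")
  fail(is.na(tbl$pos) | tbl$pos < 1, "BP must be a positive 1-based position")
  dup <- duplicated(tbl$snv_id)
  if (any(dup)) {
    stop_gwasdiff(
      row_diag(sprintf("duplicated snv_id (e.g. %s)", tbl$snv_id[which(dup)[1]]),
               which(dup)),
      "gwasdiff_error_validation"
    )
  }
  tbl
}

#' Write summary statistics to a canonical TSV
#'
#' Serializes a validated table to the canonical tab-delimited layout with a
#' `BETA` column (log odds ratios). Negative zero is normalized to `0` so the
#' file is byte-stable, and `read_sumstats()` on the output reproduces the
#' input exactly.
#'
#' @param tbl A validated summary-statistics tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(tbl, path) {
  tbl <- validate_sumstats(tbl)
  out <- tibble::tibble(
    SNP = tbl$snv_id, CHR = tbl$chrom, BP = tbl$pos,
    A1 = tbl$effect_allele, A2 = tbl$other_allele, EAF = tbl$eaf,
    BETA = tbl$beta + 0,  # -0.0 -> 0.0
    SE = tbl$se, P = tbl$p, N_CAS = tbl$n_cases, N_CON = tbl$n_controls
  )
  tryCatch(
    readr::write_tsv(out, path, progress = FALSE),
    error = function(e) {
      stop_gwasdiff(sprintf("cannot write to %s: %s", path, conditionMessage(e)),
                    "gwasdiff_error_io")
    }
  )
  invisible(path)
}
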