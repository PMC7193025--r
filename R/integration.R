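# Cross-evidence integration: chemicals significant on the GWAS/TWAS side
# (in one or more tissues) AND in the expression screen, per disease; then the
# cross-disease common set. Counts follow union-with-overlap accounting: the
# per-tissue counts sum to the union size minus the multi-tissue overlap.

#' Intersect GWAS-side and expression-side significant chemicals
#'
#' A chemical is *common* when its empirical p-value is below `alpha` in the
#' expression stream AND in at least one GWAS-side tissue stream. The
#' per-tissue breakdown is retained: for each tissue, the count of common
#' chemicals significant in that tissue, plus the count significant in more
#' than one tissue, so that `sum(tissue counts) - multi_tissue = |union|`.
#' Chemicals absent (untested) in a stream are never declared common.
#'
#' @param gwas_side `gsea_result` rows for one or more GWAS-side tissue
#'   streams (distinguished by their `stream` column).
#' @param expr_side `gsea_result` rows for the expression stream.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with one row per common chemical (`chemical` plus one
#'   logical column per tissue stream), sorted by chemical; the accounting
#'   table is attached as attribute `"breakdown"` (tibble `region`, `n`).
#' @export
intersect_streams <- function(gwas_side, expr_side, alpha = 0.05) {
  if (nrow(gwas_side) == 0 || nrow(expr_side) == 0) {
    out <- tibble::tibble(chemical = character())
    attr(out, "breakdown") <- tibble::tibble(region = character(), n = integer())
    return(out)
  }
  expr_sig <- trimws(expr_side$chemical[expr_side$p_empirical < alpha])
  tissues <- unique(gwas_side$stream)
  sig_by_tissue <- lapply(tissues, function(ts) {
    trimws(gwas_side$chemical[gwas_side$stream == ts &
                                gwas_side$p_empirical < alpha])
  })
  names(sig_by_tissue) <- tissues
  common <- sort(intersect(expr_sig, unique(unlist(sig_by_tissue))))
  flags <- lapply(sig_by_tissue, function(s) common %in% s)
  out <- tibble::as_tibble(c(list(chemical = common), flags))
  n_per_tissue <- vapply(flags, sum, integer(1))
  n_multi <- if (length(flags) > 0) {
    sum(Reduce(`+`, flags) > 1)
  } else 0L
  attr(out, "breakdown") <- tibble::tibble(
    region = c(tissues, "multi_tissue", "union"),
    n = as.integer(c(n_per_tissue, n_multi, length(common)))
  )
  out
}

#' Chemicals common to two diseases
#'
#' Exact intersection by chemical name (after whitespace trimming), sorted.
#'
#' @param colon_common,rectal_common Character vectors of chemical names (or
#'   tibbles with a `chemical` column, e.g. from [intersect_streams()]).
#' @return Sorted character vector of shared chemical names.
#' @export
common_chemicals <- function(colon_common, rectal_common) {
  pull_chem <- function(x) {
    if (is.data.frame(x)) x <- x$chemical
    trimws(as.character(x))
  }
  sort(intersect(pull_chem(colon_common), pull_chem(rectal_common)))
}

#' Build the cross-stream integration report
#'
#' Takes all enrichment results over every (disease, stream) combination and
#' assembles: one row per chemical appearing in any stream with per-stream
#' p-values and significance flags (`NA` where the chemical was absent from a
#' stream — absence is never treated as non-significance); the per-disease
#' common sets (expression AND >= 1 GWAS-side tissue); the cross-disease
#' common set; and a region-count table.
#'
#' @param results Tibble of enrichment rows with columns `disease`, `stream`,
#'   `chemical`, `p_empirical` (e.g. the bound `gsea` element of a
#'   [run_pipeline()] result). Streams named `"expression"` form the
#'   expression side; all others are GWAS-side tissue streams.
#' @param alpha Significance level (default 0.05).
#' @return An `integration_report`: list with `chemicals` (wide per-chemical
#'   tibble), `counts` (tibble `disease`, `region`, `n`), `common` (named list
#'   of per-disease common chemical vectors), `pan_common` (character vector)
#'   and `alpha`.
#' @export
build_report <- function(results, alpha = 0.05) {
  need <- c("disease", "stream", "chemical", "p_empirical")
  miss <- setdiff(need, names(results))
  if (length(miss) > 0) {
    chem_abort(sprintf("results must contain column(s): %s",
                       paste(miss, collapse = ", ")), "schema")
  }
  if (nrow(results) == 0) chem_abort("at least one stream is required", "domain")
  results <- dplyr::mutate(tibble::as_tibble(results),
                           chemical = trimws(.data$chemical))

  diseases <- unique(results$disease)
  common <- lapply(diseases, function(d) {
    rows <- results[results$disease == d, ]
    ix <- intersect_streams(rows[rows$stream != "expression", ],
                            rows[rows$stream == "expression", ],
                            alpha = alpha)
    ix
  })
  names(common) <- diseases
  pan_common <- Reduce(common_chemicals, common)
  if (is.data.frame(pan_common)) pan_common <- sort(trimws(pan_common$chemical))

  counts <- dplyr::bind_rows(lapply(diseases, function(d) {
    br <- attr(common[[d]], "breakdown")
    dplyr::mutate(br, disease = d, .before = 1)
  }))
  counts <- dplyr::bind_rows(
    counts,
    tibble::tibble(disease = "all", region = "pan_common",
                   n = length(pan_common))
  )

  wide_p <- tidyr::pivot_wider(
    dplyr::transmute(results, key = paste0("p_", .data$disease, ".", .data$stream),
                     chemical = .data$chemical, p = .data$p_empirical),
    names_from = "key", values_from = "p"
  )
  wide_sig <- tidyr::pivot_wider(
    dplyr::transmute(results, key = paste0("sig_", .data$disease, ".", .data$stream),
                     chemical = .data$chemical, sig = .data$p_empirical < alpha),
    names_from = "key", values_from = "sig"
  )
  chem_tbl <- dplyr::full_join(wide_p, wide_sig, by = "chemical")
  for (d in diseases) {
    chem_tbl[[paste0("common_", d)]] <- chem_tbl$chemical %in% common[[d]]$chemical
  }
  chem_tbl$pan_common <- chem_tbl$chemical %in% pan_common
  # analogue of the published top tables: order by GWAS-side p, then expression p
  p_cols <- grep("^p_", names(chem_tbl), value = TRUE)
  gwas_p <- setdiff(p_cols, grep("expression$", p_cols, value = TRUE))
  chem_tbl <- dplyr::arrange(
    chem_tbl,
    dplyr::across(dplyr::all_of(c(gwas_p, setdiff(p_cols, gwas_p)))),
    .data$chemical
  )

  structure(
    list(chemicals = chem_tbl, counts = counts, common = common,
         pan_common = pan_common, alpha = alpha),
    class = "integration_report"
  )
}

#' @export
print.integration_report <- function(x, ...) {
  cat("Chemical integration report (alpha = ", x$alpha, ")\n", sep = "")
  for (d in names(x$common)) {
    cat("  ", d, ": ", nrow(x$common[[d]]), " common chemical(s)\n", sep = "")
  }
  cat("  shared across diseases: ", length(x$pan_common), "\n", sep = "")
  if (length(x$pan_common) > 0) {
    cat("    ", paste(utils::head(x$pan_common, 10), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
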