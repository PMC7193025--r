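# broom-style accessors for the package's result objects.

#' Tidy a gsea_result
#'
#' @param x A `gsea_result` from [run_gsea()].
#' @param ... Unused.
#' @return A plain tibble of the per-chemical enrichment rows.
#' @export
tidy.gsea_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "gsea_result")
  attr(out, "skipped") <- NULL
  attr(out, "config") <- NULL
  out
}

#' @rdname tidy.gsea_result
#' @export
glance.gsea_result <- function(x, ...) {
  cfg <- attr(x, "config")
  skipped <- attr(x, "skipped")
  tibble::tibble(
    stream = if (nrow(x) > 0) x$stream[1] else NA_character_,
    n_sets = nrow(x),
    n_significant = sum(x$significant),
    min_p = if (nrow(x) > 0) min(x$p_empirical) else NA_real_,
    n_skipped = if (is.null(skipped)) 0L else as.integer(sum(skipped)),
    n_permutations = if (is.null(cfg)) NA_integer_ else cfg$n_permutations,
    alpha = if (is.null(cfg)) NA_real_ else cfg$alpha
  )
}

#' Tidy an integration_report
#'
#' @param x An `integration_report` from [build_report()].
#' @param ... Unused.
#' @return The wide per-chemical tibble (`tidy`) or the one-row summary of
#'   region counts (`glance`).
#' @export
tidy.integration_report <- function(x, ...) x$chemicals

#' @rdname tidy.integration_report
#' @export
glance.integration_report <- function(x, ...) {
  per_disease <- vapply(x$common, nrow, integer(1))
  out <- tibble::as_tibble(as.list(stats::setNames(
    per_disease, paste0("n_common_", names(per_disease))
  )))
  out$n_pan_common <- length(x$pan_common)
  out$alpha <- x$alpha
  out
}

#' Tidy a chem_screen pipeline result
#'
#' @param x A `chem_screen` from [run_pipeline()].
#' @param ... Unused.
#' @return All enrichment rows across diseases and streams (`tidy`), or a
#'   one-row pipeline summary (`glance`).
#' @export
tidy.chem_screen <- function(x, ...) tibble::as_tibble(x$gsea)

#' @rdname tidy.chem_screen
#' @export
glance.chem_screen <- function(x, ...) {
  g <- glance.integration_report(x$report)
  g$n_genes <- x$config$n_genes
  g$n_chemicals <- x$config$n_chemicals
  g$n_causal_chemicals <- length(x$truth$causal_chemicals)
  g
}
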