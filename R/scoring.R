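# Gene scoring: ranked gene lists (one per evidence stream) feeding the
# enrichment core. Scores are magnitudes (|z|, |t|); ranking is descending
# with ties broken by gene_id.

new_gene_scores <- function(gene_id, score, stream) {
  tb <- tibble::tibble(gene_id = gene_id, score = score)
  tb <- dplyr::arrange(tb, dplyr::desc(score), gene_id)
  tb$rank <- seq_len(nrow(tb))
  structure(tb, stream = stream, class = c("gene_scores", class(tb)))
}

#' Construct a ranked gene score table
#'
#' Builds the ranked-list container used by the enrichment core: scores are
#' non-negative magnitudes, sorted descending with ties broken by `gene_id`
#' ascending, and ranks assigned 1..N.
#'
#' @param gene_id Character vector of unique gene ids.
#' @param score Non-negative numeric scores, same length.
#' @param stream Label describing the evidence stream.
#' @return A `gene_scores` tibble with columns `gene_id`, `score`, `rank`.
#' @export
gene_scores <- function(gene_id, score, stream = "scores") {
  if (length(gene_id) != length(score)) {
    chem_abort("`gene_id` and `score` must have equal length", "validation")
  }
  if (anyDuplicated(gene_id)) {
    chem_abort("`gene_id` must be unique", "validation")
  }
  if (any(!is.finite(score)) || any(score < 0)) {
    chem_abort("`score` must be finite and non-negative", "validation")
  }
  new_gene_scores(as.character(gene_id), as.numeric(score), stream)
}

#' Stream label of a gene score table
#' @param scores A `gene_scores` tibble.
#' @return The stream label, or `"scores"` when unset.
#' @export
score_stream <- function(scores) attr(scores, "stream") %||% "scores"

#' Best-SNP gene scores from GWAS summary statistics
#'
#' Assigns to each gene the most significant GWAS statistic among SNPs falling
#' within `window_bp` of the gene body on the same chromosome:
#' `r = max |z|` over SNPs with `pos` in `[start - window_bp, end + window_bp]`
#' (equivalently the smallest p). Genes with no in-window SNP are excluded
#' from the table (and counted in a message), so the ranked universe is
#' stream-specific.
#'
#' @param gwas GWAS summary tibble.
#' @param genes Gene records tibble: `gene_id`, `chrom`, `start`, `end`.
#' @param window_bp Flanking window in base pairs (default 50 kb).
#' @return A `gene_scores` tibble (`gene_id`, `score`, `rank`), stream
#'   `"gwas_best_snp"`.
#' @export
score_genes_best_snp <- function(gwas, genes, window_bp = 50000) {
  if (!is_scalar_number(window_bp) || window_bp < 0) {
    chem_abort("`window_bp` must be >= 0", "domain")
  }
  if (nrow(genes) == 0) {
    return(new_gene_scores(character(), double(), "gwas_best_snp"))
  }
  hits <- dplyr::inner_join(
    gwas[, c("chrom", "pos", "z")], genes,
    by = "chrom", relationship = "many-to-many"
  )
  hits <- dplyr::filter(hits, .data$pos >= .data$start - window_bp,
                        .data$pos <= .data$end + window_bp)
  scored <- dplyr::summarise(dplyr::group_by(hits, .data$gene_id),
                             score = max(abs(.data$z)), .groups = "drop")
  n_excluded <- nrow(genes) - nrow(scored)
  if (n_excluded > 0) {
    rlang::inform(sprintf(
      "score_genes_best_snp: %d gene(s) with no SNP within %d bp excluded",
      n_excluded, as.integer(window_bp)
    ))
  }
  new_gene_scores(scored$gene_id, scored$score, "gwas_best_snp")
}

#' Gene scores from TWAS results
#'
#' `r = |z_twas|` per gene, for a single tissue's results.
#'
#' @param twas Tibble from [run_twas()] restricted to one tissue.
#' @return A `gene_scores` tibble, stream `"twas:<tissue>"`.
#' @export
score_genes_from_twas <- function(twas) {
  tissues <- unique(twas$tissue)
  if (length(tissues) > 1) {
    chem_abort(sprintf("score_genes_from_twas expects one tissue, found: %s",
                       paste(tissues, collapse = ", ")), "validation")
  }
  stream <- if (length(tissues) == 1) paste0("twas:", tissues) else "twas"
  new_gene_scores(twas$gene_id, abs(twas$z_twas), stream)
}

#' Gene scores from a two-group expression comparison
#'
#' Welch two-sample t statistic per gene between case and control samples;
#' `r = |t|`. Genes with zero variance in both groups receive `r = 0` with a
#' warning (never an error).
#'
#' @param expr Expression tibble: `gene_id` plus one numeric column per sample.
#' @param groups Tibble `sample_id`, `group` (`case`/`control`), each group
#'   with at least two samples.
#' @return A `gene_scores` tibble, stream `"expression"`.
#' @export
score_genes_expression <- function(expr, groups) {
  validate_sample_groups(groups)
  missing_samples <- setdiff(groups$sample_id, names(expr))
  if (length(missing_samples) > 0) {
    chem_abort(sprintf("expression matrix lacks sample column(s): %s",
                       paste(utils::head(missing_samples, 5), collapse = ", ")),
               "validation")
  }
  X <- as.matrix(expr[, groups$sample_id])
  case <- groups$group == "case"
  t_stat <- welch_t(X[, case, drop = FALSE], X[, !case, drop = FALSE])
  flat <- !is.finite(t_stat)
  if (any(flat)) {
    rlang::warn(sprintf(
      "score_genes_expression: %d gene(s) with zero variance in both groups scored 0",
      sum(flat)
    ))
    t_stat[flat] <- 0
  }
  new_gene_scores(expr$gene_id, abs(t_stat), "expression")
}

# Row-wise Welch t between two sample matrices (genes x samples).
welch_t <- function(X1, X2) {
  n1 <- ncol(X1)
  n2 <- ncol(X2)
  m1 <- rowMeans(X1)
  m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  t_stat <- (m1 - m2) / se
  # zero variance in both groups with equal means -> 0/0; leave NaN for caller
  t_stat[se == 0 & m1 == m2] <- NaN
  t_stat
}
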