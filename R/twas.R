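# Summary-based TWAS: gene-level association statistics from GWAS z-scores,
# expression weights and an LD reference.

#' Summary TWAS association statistic
#'
#' Computes `z = w'Z / sqrt(w'Lw)` for one gene: `Z` the GWAS z-scores at the
#' model SNPs, `w` the expression weights, `L` the SNP LD matrix, all aligned
#' on the same SNP order. If the LD block is not numerically positive definite
#' (smallest eigenvalue below `1e-8`), it is ridged as
#' `L <- (1 - ridge) L + ridge I` before the quadratic form; well-conditioned
#' blocks are used exactly, so closed-form cases are reproduced to machine
#' precision.
#'
#' @param w Numeric weight vector.
#' @param ld Square LD matrix aligned to `w`.
#' @param z Numeric GWAS z-score vector aligned to `w`.
#' @param ridge Ridge mass used for non-positive-definite blocks.
#' @param tol Degeneracy tolerance on `w'Lw`.
#' @return The scalar TWAS z-statistic.
#' @export
twas_z <- function(w, ld, z, ridge = 0.01, tol = 1e-12) {
  stopifnot(is.numeric(w), is.numeric(z))
  if (length(w) != length(z) || length(w) != nrow(ld) || nrow(ld) != ncol(ld)) {
    chem_abort("w, z and ld must share one SNP dimension", "validation")
  }
  ev_min <- min(eigen(ld, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-8) {
    ld <- (1 - ridge) * ld + ridge * diag(nrow(ld))
  }
  qf <- drop(crossprod(w, ld %*% w))
  if (!is.finite(qf) || qf <= tol) {
    chem_abort("degenerate expression model: w'Lw is not positive", "degenerate")
  }
  drop(crossprod(w, z)) / sqrt(qf)
}

#' Two-sided normal p-value for a TWAS statistic
#'
#' @param z_twas Numeric vector of TWAS z-statistics (finite).
#' @return Two-sided standard-normal p-values clipped to `[1e-300, 1]`.
#' @export
twas_pvalue <- function(z_twas) {
  if (any(!is.finite(z_twas))) {
    chem_abort("`z_twas` must be finite", "domain")
  }
  pmin(pmax(2 * stats::pnorm(-abs(z_twas)), 1e-300), 1)
}

#' Run summary TWAS across genes
#'
#' One statistic per (gene, tissue) model whose SNPs can be matched to the
#' GWAS summary. Model SNPs absent from the GWAS are dropped jointly from
#' `w`, `L` and `Z`; a gene is skipped entirely when no SNP remains or when
#' its quadratic form degenerates. Skip counts are reported via a message.
#'
#' @param gwas GWAS summary tibble (see [read_gwas_summary()]).
#' @param models Long weights tibble: `gene_id`, `tissue`, `snp_id`, `weight`.
#' @param ld Either a single LD matrix shared by all genes (SNP order =
#'   model row order per gene) or a named list of per-gene matrices.
#' @return Tibble `gene_id`, `tissue`, `z_twas`, `p`, one row per computed
#'   gene; empty (with a warning) if no gene is computable.
#' @export
run_twas <- function(gwas, models, ld) {
  gid <- models$gene_id
  tis <- models$tissue
  snp <- models$snp_id
  wt <- models$weight
  pos_in_gwas <- match(snp, gwas$snp_id)
  zv <- gwas$z[pos_in_gwas]
  present <- !is.na(pos_in_gwas)
  key <- paste(gid, tis, sep = "\r")
  idx <- split(seq_along(gid), factor(key, levels = unique(key)))

  shared_ld <- is.matrix(ld)
  if (shared_ld) {
    # ridge decision made once for the shared block; any principal submatrix
    # of a positive-definite matrix is positive definite
    ev_min <- min(eigen(ld, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < 1e-8) ld <- 0.99 * ld + 0.01 * diag(nrow(ld))
  }

  n_missing_snp <- 0L
  n_skipped_empty <- 0L
  n_skipped_degenerate <- 0L
  gene_out <- character(length(idx))
  tissue_out <- character(length(idx))
  z_out <- rep(NA_real_, length(idx))

  for (i in seq_along(idx)) {
    ii <- idx[[i]]
    keep <- present[ii]
    if (!all(keep)) {
      n_missing_snp <- n_missing_snp + sum(!keep)
      if (!any(keep)) {
        n_skipped_empty <- n_skipped_empty + 1L
        next
      }
      ii <- ii[keep]
    }
    w <- wt[ii]
    if (shared_ld) {
      if (nrow(ld) != length(keep)) {
        chem_abort(sprintf("LD block for gene %s does not match its model",
                           gid[ii[1]]), "validation")
      }
      L <- if (all(keep)) ld else ld[keep, keep, drop = FALSE]
      qf <- sum(w * (L %*% w))
    } else {
      L <- ld[[gid[ii[1]]]]
      if (is.null(L) || nrow(L) != length(keep)) {
        chem_abort(sprintf("LD block for gene %s does not match its model",
                           gid[ii[1]]), "validation")
      }
      if (!all(keep)) L <- L[keep, keep, drop = FALSE]
      ev <- min(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
      if (ev < 1e-8) L <- 0.99 * L + 0.01 * diag(nrow(L))
      qf <- sum(w * (L %*% w))
    }
    if (!is.finite(qf) || qf <= 1e-12) {
      n_skipped_degenerate <- n_skipped_degenerate + 1L
      next
    }
    gene_out[i] <- gid[ii[1]]
    tissue_out[i] <- tis[ii[1]]
    z_out[i] <- sum(w * zv[ii]) / sqrt(qf)
  }

  ok <- !is.na(z_out)
  out <- tibble::tibble(gene_id = gene_out[ok], tissue = tissue_out[ok],
                        z_twas = z_out[ok])
  if (n_skipped_empty + n_skipped_degenerate > 0L || n_missing_snp > 0L) {
    rlang::inform(sprintf(
      "run_twas: %d SNP(s) absent from GWAS; skipped %d gene(s) with no usable SNP and %d degenerate model(s)",
      n_missing_snp, n_skipped_empty, n_skipped_degenerate
    ))
  }
  if (nrow(out) == 0) {
    rlang::warn("run_twas: no gene was computable")
    return(tibble::tibble(gene_id = character(), tissue = character(),
                          z_twas = double(), p = double()))
  }
  out$p <- twas_pvalue(out$z_twas)
  out
}
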