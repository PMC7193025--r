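# Readers and writers for every on-disk format the pipeline touches.
# All tables are UTF-8, tab-separated, with a mandatory header; "." is missing.
# Genomic coordinates are 1-based inclusive.

#' Read GWAS summary statistics
#'
#' Reads a tab-separated GWAS summary file with columns `snp_id`, `chrom`,
#' `pos` and at least one of `z` (association z-score) or `p` (two-sided
#' p-value). Optional columns: `effect_allele`, `other_allele`, `direction`
#' (`+`/`-`, used to reconstruct a signed z when only p-values are given).
#' Missing values are encoded as `"."`.
#'
#' If `z` is absent, it is reconstructed as the signed two-sided normal
#' quantile `sign * qnorm(p/2, lower.tail = FALSE)`; if `p` is absent it is
#' filled in as `2 * pnorm(-|z|)`. When both are present they must agree
#' under the two-sided normal test to within `1e-6`.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `z`, `p`, one row per SNP.
#' @export
read_gwas_summary <- function(path) {
  raw <- readr::read_tsv(
    path,
    na = ".",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("snp_id", "chrom", "pos")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    chem_abort(
      sprintf("GWAS summary file is missing required column(s): %s",
              paste(miss, collapse = ", ")),
      "schema"
    )
  }
  if (!any(c("z", "p") %in% names(raw))) {
    chem_abort("GWAS summary file must contain a 'z' or 'p' column", "schema")
  }
  get_chr <- function(col) if (col %in% names(raw)) raw[[col]] else NA_character_
  out <- tibble::tibble(
    snp_id        = raw$snp_id,
    chrom         = raw$chrom,
    pos           = as.integer(raw$pos),
    effect_allele = get_chr("effect_allele"),
    other_allele  = get_chr("other_allele"),
    z             = if ("z" %in% names(raw)) as.numeric(raw$z) else NA_real_,
    p             = if ("p" %in% names(raw)) as.numeric(raw$p) else NA_real_
  )
  if (all(is.na(out$z))) {
    if (!"direction" %in% names(raw)) {
      chem_abort(
        "GWAS summary file has no 'z' column; reconstructing z from 'p' requires a 'direction' (+/-) column",
        "schema"
      )
    }
    sgn <- ifelse(trimws(raw$direction) == "-", -1, 1)
    out$z <- sgn * stats::qnorm(out$p / 2, lower.tail = FALSE)
  }
  fill <- is.na(out$p) & !is.na(out$z)
  out$p[fill] <- 2 * stats::pnorm(-abs(out$z[fill]))
  validate_gwas_summary(out)
  out
}

validate_gwas_summary <- function(gwas) {
  if (any(is.na(gwas$snp_id) | !nzchar(gwas$snp_id))) {
    chem_abort("snp_id must be non-empty for every row", "validation")
  }
  dup <- gwas$snp_id[duplicated(gwas$snp_id)]
  if (length(dup) > 0) {
    chem_abort(
      sprintf("duplicate snp_id in GWAS summary: %s",
              paste(utils::head(unique(dup), 5), collapse = ", ")),
      "validation"
    )
  }
  if (any(is.na(gwas$pos)) || any(gwas$pos < 1L)) {
    chem_abort("pos must be an integer >= 1 for every row", "validation")
  }
  bad_p <- !is.na(gwas$p) & (gwas$p <= 0 | gwas$p > 1)
  if (any(bad_p)) chem_abort("p must lie in (0, 1]", "validation")
  both <- !is.na(gwas$z) & !is.na(gwas$p)
  if (any(both)) {
    delta <- abs(gwas$p[both] - 2 * stats::pnorm(-abs(gwas$z[both])))
    if (any(delta > 1e-6)) {
      chem_abort(
        sprintf("z and p disagree under the two-sided normal test for snp_id %s",
                gwas$snp_id[both][which.max(delta)]),
        "validation"
      )
    }
  }
  invisible(gwas)
}

#' Write GWAS summary statistics
#'
#' @param gwas Tibble as returned by [read_gwas_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas_summary <- function(gwas, path) {
  readr::write_tsv(gwas, path, na = ".", progress = FALSE)
  invisible(path)
}

#' Read chemical gene sets in GMT format
#'
#' Each line is `name TAB source_id TAB member TAB member ...`. Duplicate
#' members within a line are collapsed (first occurrence kept); set order is
#' preserved. Chemical names are trimmed of surrounding whitespace and treated
#' as opaque keys thereafter.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `chemical`, `source_id`, and a list-column
#'   `members` of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(
      chemical = character(), source_id = character(), members = list()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    chem_abort(
      sprintf("GMT line %d has %d field(s); expected name, source id and at least one member",
              which(nf < 3)[1], nf[which(nf < 3)[1]]),
      "parse"
    )
  }
  tibble::tibble(
    chemical  = trimws(vapply(fields, `[[`, character(1), 1L)),
    source_id = vapply(fields, `[[`, character(1), 2L),
    members   = lapply(fields, function(f) {
      m <- f[-(1:2)]
      unique(m[nzchar(m)])
    })
  )
}

#' Write chemical gene sets in GMT format
#'
#' @param sets Tibble with columns `chemical`, `source_id`, `members`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$chemical[i], sets$source_id[i], sets$members[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read per-tissue expression weights
#'
#' Long-format TSV with columns `gene_id`, `snp_id`, `weight`; one row per
#' (gene, SNP). SNP order within a gene is meaningful and must match the
#' ordering of that gene's LD matrix.
#'
#' @param path Path to a weights TSV.
#' @param tissue Tissue label attached to every row.
#' @return A tibble with columns `gene_id`, `tissue`, `snp_id`, `weight`.
#' @export
read_weights <- function(path, tissue = "tissue") {
  raw <- readr::read_tsv(
    path, na = ".",
    col_types = readr::cols(
      gene_id = readr::col_character(),
      snp_id = readr::col_character(),
      weight = readr::col_double()
    ),
    progress = FALSE
  )
  miss <- setdiff(c("gene_id", "snp_id", "weight"), names(raw))
  if (length(miss) > 0) {
    chem_abort(
      sprintf("weights file is missing required column(s): %s",
              paste(miss, collapse = ", ")),
      "schema"
    )
  }
  dup <- duplicated(raw[, c("gene_id", "snp_id")])
  if (any(dup)) chem_abort("duplicate (gene_id, snp_id) pair in weights file", "validation")
  tibble::tibble(
    gene_id = raw$gene_id, tissue = tissue,
    snp_id = raw$snp_id, weight = raw$weight
  )
}

#' @rdname read_weights
#' @param models Tibble with columns `gene_id`, `snp_id`, `weight`.
#' @export
write_weights <- function(models, path) {
  readr::write_tsv(models[, c("gene_id", "snp_id", "weight")], path,
                   na = ".", progress = FALSE)
  invisible(path)
}

#' Read / write a square LD matrix
#'
#' TSV with a header row of SNP ids and one numeric row per SNP, in the same
#' order as the corresponding gene's weights. The matrix must be square and
#' symmetric with a unit diagonal (to `1e-8`).
#'
#' @param path Path to an LD matrix TSV.
#' @return A numeric matrix with SNP ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()),
                         progress = FALSE)
  L <- as.matrix(raw)
  rownames(L) <- colnames(L)
  validate_ld_block(L)
  L
}

#' @rdname read_ld_matrix
#' @param L Square numeric matrix with SNP-id dimnames.
#' @export
write_ld_matrix <- function(L, path) {
  df <- tibble::as_tibble(L, .name_repair = "minimal")
  names(df) <- colnames(L)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

validate_ld_block <- function(L, tol = 1e-8) {
  if (!is.matrix(L) || nrow(L) != ncol(L)) {
    chem_abort("LD block must be a square matrix", "validation")
  }
  if (max(abs(L - t(L))) > tol) chem_abort("LD block must be symmetric", "validation")
  if (max(abs(diag(L) - 1)) > tol) {
    chem_abort("LD block must have a unit diagonal", "validation")
  }
  invisible(L)
}

#' Read / write an expression matrix and its sample groups
#'
#' The expression table is genes x samples: a `gene_id` column followed by one
#' numeric column per sample (log-scale intensities). Sample groups live in a
#' separate two-column file `sample_id`, `group` with groups `case`/`control`;
#' each group needs at least two samples.
#'
#' @param path Path to the expression TSV.
#' @return `read_expression()`: a tibble, `gene_id` plus sample columns.
#' @export
read_expression <- function(path) {
  raw <- readr::read_tsv(path, na = ".",
                         col_types = readr::cols(
                           gene_id = readr::col_character(),
                           .default = readr::col_double()
                         ),
                         progress = FALSE)
  if (!"gene_id" %in% names(raw)) {
    chem_abort("expression file is missing required column: gene_id", "schema")
  }
  if (ncol(raw) < 2) chem_abort("expression file has no sample columns", "schema")
  if (anyDuplicated(raw$gene_id)) {
    chem_abort("duplicate gene_id in expression file", "validation")
  }
  raw
}

#' @rdname read_expression
#' @param expr Tibble with `gene_id` plus one numeric column per sample.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path, na = ".", progress = FALSE)
  invisible(path)
}

#' @rdname read_expression
#' @export
read_sample_groups <- function(path) {
  raw <- readr::read_tsv(path,
                         col_types = readr::cols(
                           sample_id = readr::col_character(),
                           group = readr::col_character()
                         ),
                         progress = FALSE)
  miss <- setdiff(c("sample_id", "group"), names(raw))
  if (length(miss) > 0) {
    chem_abort(sprintf("sample group file is missing required column(s): %s",
                       paste(miss, collapse = ", ")), "schema")
  }
  validate_sample_groups(raw)
  raw
}

#' @rdname read_expression
#' @param groups Tibble with columns `sample_id`, `group`.
#' @export
write_sample_groups <- function(groups, path) {
  readr::write_tsv(groups, path, progress = FALSE)
  invisible(path)
}

validate_sample_groups <- function(groups) {
  bad <- setdiff(unique(groups$group), c("case", "control"))
  if (length(bad) > 0) {
    chem_abort(sprintf("sample groups must be 'case' or 'control'; found: %s",
                       paste(bad, collapse = ", ")), "validation")
  }
  n <- table(factor(groups$group, levels = c("case", "control")))
  if (any(n < 2)) chem_abort("each group needs at least 2 samples", "validation")
  invisible(groups)
}

#' Read / write an enrichment results table
#'
#' Tab-separated with columns `chemical`, `stream`, `n_overlap`, `es`, `nes`,
#' `p_empirical` and, when present, `q_bh` and `significant`. Numeric values
#' round-trip to at least six significant digits.
#'
#' @param results Tibble of enrichment results (see [run_gsea()]).
#' @param path Output path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_results_table <- function(results, path) {
  core <- c("chemical", "stream", "n_overlap", "es", "nes", "p_empirical")
  miss <- setdiff(core, names(results))
  if (length(miss) > 0) {
    chem_abort(sprintf("results table is missing column(s): %s",
                       paste(miss, collapse = ", ")), "schema")
  }
  keep <- intersect(c(core, "q_bh", "significant"), names(results))
  readr::write_tsv(tibble::as_tibble(results)[, keep], path, na = ".",
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, na = ".",
                  col_types = readr::cols(
                    chemical = readr::col_character(),
                    stream = readr::col_character(),
                    n_overlap = readr::col_integer(),
                    .default = readr::col_guess()
                  ),
                  progress = FALSE)
}
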