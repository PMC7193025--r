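# Synthetic-data generators. Every pipeline input (GWAS z-scores with block
# LD, per-gene expression weights, overlapping chemical gene sets with a
# planted causal subset, a two-group expression matrix) can be produced with
# known ground truth, so every downstream stage is testable without external
# downloads. All generators are pure functions of (config, seed).

#' Simulation configuration
#'
#' Study conditions for the synthetic generators. Defaults emulate the scale
#' of the motivating design at desk size: 2,000 genes with 10 SNPs each under
#' AR(1) LD (rho = 0.5), 500 chemical gene sets of 10-200 genes of which 5 are
#' causal, a TWAS effect of lambda = 4 standard deviations for causal genes,
#' an expression mean shift of delta = 1 for causal genes, and 77 case vs 117
#' control expression samples (the tumor/mucosa sample sizes of the motivating
#' expression dataset).
#'
#' @param n_genes Number of genes in the universe.
#' @param n_snps_per_gene SNPs per gene model.
#' @param ld_rho AR(1) LD correlation in `[0, 1)`.
#' @param n_chemicals Number of chemical gene sets.
#' @param set_size_range Integer `c(min, max)` of set sizes (uniform).
#' @param n_causal_chemicals The first `n_causal_chemicals` sets are causal.
#' @param causal_fraction Fraction of each causal set's members that carry
#'   effects, in `(0, 1]`.
#' @param twas_effect Planted TWAS mean (lambda >= 0) for causal genes.
#' @param expr_effect Expression mean shift (delta >= 0) in case samples of
#'   causal genes.
#' @param n_case,n_control Expression sample sizes (each >= 2).
#' @param seed Global seed; component generators use fixed-offset child seeds.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_snps_per_gene = 10, ld_rho = 0.5,
                       n_chemicals = 500, set_size_range = c(10, 200),
                       n_causal_chemicals = 5, causal_fraction = 0.5,
                       twas_effect = 4, expr_effect = 1,
                       n_case = 77, n_control = 117, seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_snps_per_gene = check_count(n_snps_per_gene, "n_snps_per_gene"),
    ld_rho = ld_rho,
    n_chemicals = check_count(n_chemicals, "n_chemicals", min = 0L),
    set_size_range = as.integer(set_size_range),
    n_causal_chemicals = check_count(n_causal_chemicals, "n_causal_chemicals", min = 0L),
    causal_fraction = causal_fraction,
    twas_effect = twas_effect,
    expr_effect = expr_effect,
    n_case = check_count(n_case, "n_case", min = 2L),
    n_control = check_count(n_control, "n_control", min = 2L),
    seed = as.integer(seed)
  )
  if (!is_scalar_number(ld_rho) || ld_rho < 0 || ld_rho >= 1) {
    chem_abort("`ld_rho` must lie in [0, 1)", "domain")
  }
  if (length(cfg$set_size_range) != 2 || cfg$set_size_range[1] > cfg$set_size_range[2] ||
      cfg$set_size_range[1] < 1) {
    chem_abort("`set_size_range` must be c(min, max) with 1 <= min <= max", "domain")
  }
  if (cfg$set_size_range[2] > cfg$n_genes) {
    chem_abort("`set_size_range` max cannot exceed `n_genes`", "domain")
  }
  if (cfg$n_causal_chemicals > cfg$n_chemicals) {
    chem_abort("`n_causal_chemicals` cannot exceed `n_chemicals`", "domain")
  }
  if (!is_scalar_number(causal_fraction) || causal_fraction <= 0 || causal_fraction > 1) {
    chem_abort("`causal_fraction` must lie in (0, 1]", "domain")
  }
  if (!is_scalar_number(twas_effect) || twas_effect < 0) {
    chem_abort("`twas_effect` must be >= 0", "domain")
  }
  if (!is_scalar_number(expr_effect) || expr_effect < 0) {
    chem_abort("`expr_effect` must be >= 0", "domain")
  }
  structure(cfg, class = "sim_config")
}

#' AR(1) linkage-disequilibrium block
#'
#' Closed-form `m x m` correlation matrix with entries `rho^|i-j|`: symmetric,
#' unit diagonal, positive definite for `rho` in `[0, 1)`.
#'
#' @param m Number of SNPs (>= 1).
#' @param rho AR(1) correlation in `[0, 1)`.
#' @return An `m x m` numeric matrix.
#' @export
simulate_ld_block <- function(m, rho) {
  m <- check_count(m, "m")
  if (!is_scalar_number(rho) || rho < 0 || rho >= 1) {
    chem_abort("`rho` must lie in [0, 1)", "domain")
  }
  idx <- seq_len(m)
  rho^abs(outer(idx, idx, "-"))
}

#' Gene and SNP annotation for the synthetic genome
#'
#' Deterministic layout: genes are assigned round-robin to chromosomes
#' `chr1..chr22`, spaced 150 kb apart with a 20 kb body; each gene carries
#' `n_snps_per_gene` SNPs evenly spaced across its body, named
#' `<gene_id>_s<k>`.
#'
#' @param config A [sim_config()].
#' @return A list with tibbles `genes` (`gene_id`, `chrom`, `start`, `end`)
#'   and `snps` (`snp_id`, `gene_id`, `chrom`, `pos`).
#' @export
simulate_gene_annotation <- function(config) {
  g <- config$n_genes
  m <- config$n_snps_per_gene
  gene_id <- sprintf("g%05d", seq_len(g))
  chrom_i <- ((seq_len(g) - 1L) %% 22L) + 1L
  within <- ((seq_len(g) - 1L) %/% 22L)
  start <- 50000L + within * 150000L
  end <- start + 19999L
  genes <- tibble::tibble(
    gene_id = gene_id, chrom = paste0("chr", chrom_i),
    start = start, end = end
  )
  offs <- as.integer(round(seq(0, 19999, length.out = m)))
  snps <- tibble::tibble(
    snp_id = paste0(rep(gene_id, each = m), "_s",
                    sprintf("%02d", rep(seq_len(m), times = g))),
    gene_id = rep(gene_id, each = m),
    chrom = rep(genes$chrom, each = m),
    pos = rep(start, each = m) + rep(offs, times = g)
  )
  list(genes = genes, snps = snps)
}

#' Simulate per-gene expression weights
#'
#' Draws independent standard-normal weights per SNP and rescales each gene's
#' vector so that `w'Lw = 1` under the supplied LD block (so the TWAS
#' denominator is exactly one by construction). Deterministic given the seed.
#'
#' @param genes Tibble of gene records (needs `gene_id`).
#' @param n_snps SNPs per gene.
#' @param ld `n_snps x n_snps` LD block shared across genes
#'   (see [simulate_ld_block()]).
#' @param tissue Tissue label attached to the models.
#' @param seed RNG seed.
#' @return Long tibble: `gene_id`, `tissue`, `snp_id`, `weight`, with SNP
#'   order matching the LD block rows.
#' @export
simulate_weights <- function(genes, n_snps, ld, tissue = "tissue", seed = 1L) {
  n_snps <- check_count(n_snps, "n_snps")
  if (nrow(genes) == 0) {
    return(tibble::tibble(gene_id = character(), tissue = character(),
                          snp_id = character(), weight = double()))
  }
  stopifnot(nrow(ld) == n_snps, ncol(ld) == n_snps)
  g <- nrow(genes)
  W <- with_rng(seed, matrix(stats::rnorm(n_snps * g), nrow = n_snps))
  qf <- colSums(W * (ld %*% W))
  W <- sweep(W, 2, sqrt(qf), "/")
  tibble::tibble(
    gene_id = rep(genes$gene_id, each = n_snps),
    tissue = tissue,
    snp_id = paste0(rep(genes$gene_id, each = n_snps), "_s",
                    sprintf("%02d", rep(seq_len(n_snps), times = g))),
    weight = as.vector(W)
  )
}

#' Simulate GWAS summary z-scores
#'
#' Per gene, the SNP z-vector is drawn as `Z = lambda * L w / sqrt(w'Lw) + e`
#' with `e ~ MVN(0, L)` for causal genes and `Z = e` otherwise. Under the
#' summary TWAS statistic this gives `E[z_twas] = lambda` for causal genes and
#' `z_twas ~ N(0, 1)` for null genes.
#'
#' @param models Long weights tibble (`gene_id`, `snp_id`, `weight`) as from
#'   [simulate_weights()].
#' @param ld Shared LD block matching each gene's SNP order.
#' @param snps SNP annotation tibble (`snp_id`, `chrom`, `pos`) as from
#'   [simulate_gene_annotation()]; provides coordinates for the output.
#' @param truth Ground truth list with element `causal_genes`.
#' @param lambda Planted TWAS mean, >= 0.
#' @param seed RNG seed.
#' @return GWAS summary tibble (`snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `z`, `p`).
#' @export
simulate_gwas_z <- function(models, ld, snps, truth, lambda, seed = 1L) {
  if (!is_scalar_number(lambda) || lambda < 0) {
    chem_abort("`lambda` must be >= 0", "domain")
  }
  gene_ids <- unique(models$gene_id)
  m <- nrow(ld)
  if (nrow(models) != length(gene_ids) * m) {
    chem_abort("model and LD dimensions do not match", "validation")
  }
  g <- length(gene_ids)
  # models are in gene-major, SNP-ordered long form; reshape to m x g
  W <- matrix(models$weight, nrow = m)
  R <- chol(ld)
  E <- with_rng(seed, matrix(stats::rnorm(m * g), nrow = m))
  Z <- crossprod(R, E)                      # columns ~ MVN(0, L)
  if (lambda > 0 && length(truth$causal_genes) > 0) {
    causal <- gene_ids %in% truth$causal_genes
    if (any(causal)) {
      Wc <- W[, causal, drop = FALSE]
      qf <- colSums(Wc * (ld %*% Wc))
      Mu <- sweep(ld %*% Wc, 2, sqrt(qf), "/") * lambda
      Z[, causal] <- Z[, causal, drop = FALSE] + Mu
    }
  }
  z <- as.vector(Z)
  out <- tibble::tibble(
    snp_id = models$snp_id,
    z = z,
    p = pmax(2 * stats::pnorm(-abs(z)), 1e-300)
  )
  ann <- snps[match(out$snp_id, snps$snp_id), ]
  tibble::tibble(
    snp_id = out$snp_id,
    chrom = ann$chrom,
    pos = ann$pos,
    effect_allele = "A",
    other_allele = "G",
    z = out$z,
    p = out$p
  )
}

#' Simulate overlapping chemical gene sets with a planted causal subset
#'
#' Set sizes are uniform over `set_size_range`; members are sampled without
#' replacement per set from the gene universe (overlap across sets allowed).
#' The first `n_causal_chemicals` sets are causal; per causal set, a
#' `causal_fraction` share of its members (rounded up) is marked causal.
#'
#' @param config A [sim_config()].
#' @param gene_ids Character vector, the gene universe.
#' @return List with `sets` (tibble `chemical`, `source_id`, `members`) and
#'   `truth` (list `causal_chemicals`, `causal_genes`).
#' @export
simulate_gene_sets <- function(config, gene_ids) {
  n <- config$n_chemicals
  rng <- config$set_size_range
  if (rng[2] > length(gene_ids)) {
    chem_abort("set size range exceeds the gene universe", "domain")
  }
  if (n == 0) {
    return(list(
      sets = tibble::tibble(chemical = character(), source_id = character(),
                            members = list()),
      truth = list(causal_chemicals = character(), causal_genes = character())
    ))
  }
  out <- with_rng(child_seed(config$seed, 307L), {
    sizes <- rng[1] + sample.int(rng[2] - rng[1] + 1L, n, replace = TRUE) - 1L
    members <- lapply(sizes, function(s) sample(gene_ids, s))
    causal_genes <- character(0)
    k <- config$n_causal_chemicals
    if (k > 0) {
      causal_genes <- unique(unlist(lapply(members[seq_len(k)], function(m) {
        sample(m, ceiling(config$causal_fraction * length(m)))
      })))
    }
    list(members = members, causal_genes = causal_genes)
  })
  chems <- sprintf("chem_%04d", seq_len(n))
  list(
    sets = tibble::tibble(
      chemical = chems,
      source_id = sprintf("SYN:%04d", seq_len(n)),
      members = out$members
    ),
    truth = list(
      causal_chemicals = chems[seq_len(config$n_causal_chemicals)],
      causal_genes = out$causal_genes
    )
  )
}

#' Simulate a two-group expression matrix
#'
#' Values are N(0, 1) per gene and sample; case-group samples of causal genes
#' are shifted by `+ expr_effect`. Case samples come first.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth list with `causal_genes`.
#' @param gene_ids Gene universe (defaults to the annotation's layout).
#' @return List with `expression` (tibble: `gene_id` + one column per sample)
#'   and `groups` (tibble: `sample_id`, `group`).
#' @export
simulate_expression <- function(config, truth, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  g <- length(gene_ids)
  n1 <- config$n_case
  n2 <- config$n_control
  X <- with_rng(child_seed(config$seed, 401L),
                matrix(stats::rnorm(g * (n1 + n2)), nrow = g))
  causal <- gene_ids %in% truth$causal_genes
  if (any(causal) && config$expr_effect > 0) {
    X[causal, seq_len(n1)] <- X[causal, seq_len(n1)] + config$expr_effect
  }
  sample_id <- c(sprintf("case_%03d", seq_len(n1)),
                 sprintf("ctrl_%03d", seq_len(n2)))
  colnames(X) <- sample_id
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                           tibble::as_tibble(X))
  groups <- tibble::tibble(
    sample_id = sample_id,
    group = rep(c("case", "control"), c(n1, n2))
  )
  list(expression = expr, groups = groups)
}

#' Simulate a complete single-disease study
#'
#' Bundles annotation, LD, expression weights, GWAS summary, chemical gene
#' sets with ground truth, and a two-group expression matrix for one disease
#' and one tissue. All randomness fans out from `config$seed` through fixed
#' offsets, so components are independently reproducible.
#'
#' @param config A [sim_config()].
#' @param tissue Tissue label for the weight models.
#' @return A `chem_sim` list: `config`, `genes`, `snps`, `ld`, `models`,
#'   `gwas`, `sets`, `truth`, `expression`, `groups`.
#' @export
simulate_study <- function(config = sim_config(), tissue = "colon") {
  ann <- simulate_gene_annotation(config)
  ld <- simulate_ld_block(config$n_snps_per_gene, config$ld_rho)
  sg <- simulate_gene_sets(config, ann$genes$gene_id)
  models <- simulate_weights(ann$genes, config$n_snps_per_gene, ld,
                             tissue = tissue,
                             seed = child_seed(config$seed, 101L))
  gwas <- simulate_gwas_z(models, ld, ann$snps, sg$truth,
                          lambda = config$twas_effect,
                          seed = child_seed(config$seed, 211L))
  ex <- simulate_expression(config, sg$truth, ann$genes$gene_id)
  structure(
    list(config = config, genes = ann$genes, snps = ann$snps, ld = ld,
         models = models, gwas = gwas, sets = sg$sets, truth = sg$truth,
         expression = ex$expression, groups = ex$groups),
    class = "chem_sim"
  )
}

#' Write a simulated study to disk
#'
#' Emits the pipeline's on-disk dialect: `gwas_<tissue>.tsv`,
#' `weights_<tissue>.tsv`, `ld_block.tsv` (the AR(1) block shared by all
#' genes), `chemsets.gmt`, `expression.tsv`, `groups.tsv`, `truth.json`.
#'
#' @param study A `chem_sim` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tissue <- study$models$tissue[1] %||% "tissue"
  write_gwas_summary(study$gwas, file.path(dir, paste0("gwas_", tissue, ".tsv")))
  write_weights(study$models, file.path(dir, paste0("weights_", tissue, ".tsv")))
  L <- study$ld
  colnames(L) <- paste0("s", sprintf("%02d", seq_len(ncol(L))))
  write_ld_matrix(L, file.path(dir, "ld_block.tsv"))
  write_gmt(study$sets, file.path(dir, "chemsets.gmt"))
  write_expression(study$expression, file.path(dir, "expression.tsv"))
  write_sample_groups(study$groups, file.path(dir, "groups.tsv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}
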