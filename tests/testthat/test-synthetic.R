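# Synthetic generators: LD structure, weight normalization, planted effects,
# determinism.

test_that("AR(1) LD block has the closed form rho^|i-j|", {
  expect_equal(simulate_ld_block(1, 0.9), matrix(1, 1, 1))
  expect_equal(simulate_ld_block(2, 0), diag(2))
  L <- simulate_ld_block(3, 0.5)
  expect_equal(L, matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3))
  expect_true(min(eigen(simulate_ld_block(10, 0.95),
                        only.values = TRUE)$values) > 0)
  expect_error(simulate_ld_block(3, 1), class = "chemgsea_domain")
  expect_error(simulate_ld_block(3, -0.1), class = "chemgsea_domain")
})

test_that("simulated weights satisfy w'Lw = 1 and are seed-deterministic", {
  genes <- tibble::tibble(gene_id = sprintf("g%05d", 1:50))
  L <- simulate_ld_block(6, 0.5)
  m1 <- simulate_weights(genes, 6, L, seed = 42)
  m2 <- simulate_weights(genes, 6, L, seed = 42)
  expect_identical(m1, m2)
  qf <- vapply(split(m1$weight, m1$gene_id), function(w) {
    drop(crossprod(w, L %*% w))
  }, numeric(1))
  expect_equal(unname(qf), rep(1, 50), tolerance = 1e-9)

  # single-SNP models: normalization forces w = +/- 1
  w1 <- simulate_weights(genes, 1, matrix(1, 1, 1), seed = 1)
  expect_true(all(abs(abs(w1$weight) - 1) < 1e-12))

  empty <- simulate_weights(genes[0, ], 3, simulate_ld_block(3, 0.2))
  expect_equal(nrow(empty), 0L)
})

test_that("simulated GWAS z-scores are deterministic and carry positions", {
  cfg <- sim_config(n_genes = 40, n_snps_per_gene = 4, n_chemicals = 5,
                    set_size_range = c(3, 8), n_causal_chemicals = 1,
                    seed = 9)
  ann <- simulate_gene_annotation(cfg)
  L <- simulate_ld_block(4, 0.5)
  models <- simulate_weights(ann$genes, 4, L, seed = 2)
  truth <- list(causal_genes = character())
  g1 <- simulate_gwas_z(models, L, ann$snps, truth, lambda = 0, seed = 5)
  g2 <- simulate_gwas_z(models, L, ann$snps, truth, lambda = 0, seed = 5)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 160L)
  expect_true(all(g1$pos >= 1))
  expect_true(all(g1$snp_id %in% ann$snps$snp_id))
  expect_error(simulate_gwas_z(models, L, ann$snps, truth, lambda = -1),
               class = "chemgsea_domain")
  expect_error(
    simulate_gwas_z(models[-1, ], L, ann$snps, truth, lambda = 0, seed = 5),
    class = "chemgsea_validation"
  )
})

test_that("gene-set generator respects sizes, causal marking and boundaries", {
  gene_ids <- sprintf("g%05d", 1:100)
  cfg <- sim_config(n_genes = 100, n_chemicals = 30, set_size_range = c(10, 10),
                    n_causal_chemicals = 3, causal_fraction = 1, seed = 4)
  sg <- simulate_gene_sets(cfg, gene_ids)
  expect_equal(lengths(sg$sets$members), rep(10L, 30))
  expect_equal(sg$truth$causal_chemicals, sg$sets$chemical[1:3])
  # causal_fraction = 1: causal genes are exactly the union of causal sets
  expect_setequal(sg$truth$causal_genes, unique(unlist(sg$sets$members[1:3])))
  expect_true(all(!vapply(sg$sets$members, anyDuplicated, integer(1)) > 0))

  none <- simulate_gene_sets(sim_config(n_genes = 100, n_chemicals = 0,
                                        n_causal_chemicals = 0,
                                        set_size_range = c(5, 10)), gene_ids)
  expect_equal(nrow(none$sets), 0L)
  expect_length(none$truth$causal_chemicals, 0L)

  expect_error(
    simulate_gene_sets(sim_config(n_genes = 100, set_size_range = c(10, 500)),
                       gene_ids),
    class = "chemgsea_domain"
  )
})

test_that("expression generator plants mean shifts only in causal case samples", {
  cfg <- sim_config(n_genes = 2000, n_chemicals = 2, set_size_range = c(5, 10),
                    n_causal_chemicals = 0, expr_effect = 0,
                    n_case = 10, n_control = 10, seed = 21)
  ex <- simulate_expression(cfg, list(causal_genes = character()))
  expect_identical(
    ex$expression,
    simulate_expression(cfg, list(causal_genes = character()))$expression
  )
  # null two-group t statistics center at zero
  sc <- suppressWarnings(score_genes_expression(ex$expression, ex$groups))
  X <- as.matrix(ex$expression[, -1])
  tsgn <- rowMeans(X[, 1:10]) - rowMeans(X[, 11:20])
  expect_lt(abs(mean(sign(tsgn) * sc$score[match(ex$expression$gene_id,
                                                 sc$gene_id)])), 0.1)

  # delta = 3 at n = 20 + 20: ncp ~ 9.5, Welch t above 2 essentially always
  cfg2 <- sim_config(n_genes = 300, n_chemicals = 2, set_size_range = c(5, 10),
                     n_causal_chemicals = 1, causal_fraction = 1,
                     expr_effect = 3, n_case = 20, n_control = 20, seed = 8)
  truth2 <- list(causal_genes = sprintf("g%05d", 1:150))
  ex2 <- simulate_expression(cfg2, truth2)
  sc2 <- score_genes_expression(ex2$expression, ex2$groups)
  causal_t <- sc2$score[sc2$gene_id %in% truth2$causal_genes]
  expect_gte(mean(causal_t > 2), 0.99)

  expect_error(sim_config(n_case = 1), class = "chemgsea_domain")
})

test_that("a whole simulated study is reproducible and writable", {
  cfg <- sim_config(n_genes = 60, n_snps_per_gene = 3, n_chemicals = 10,
                    set_size_range = c(5, 15), n_causal_chemicals = 2,
                    seed = 77)
  s1 <- simulate_study(cfg, tissue = "colon")
  s2 <- simulate_study(cfg, tissue = "colon")
  expect_identical(s1$gwas, s2$gwas)
  expect_identical(s1$sets, s2$sets)
  expect_identical(s1$expression, s2$expression)

  dir <- withr::local_tempdir()
  write_simulation(s1, dir)
  expect_setequal(
    list.files(dir),
    c("gwas_colon.tsv", "weights_colon.tsv", "ld_block.tsv", "chemsets.gmt",
      "expression.tsv", "groups.tsv", "truth.json")
  )
  back <- read_gwas_summary(file.path(dir, "gwas_colon.tsv"))
  expect_equal(back$z, s1$gwas$z, tolerance = 1e-6)
  expect_equal(read_gmt(file.path(dir, "chemsets.gmt"))$members,
               s1$sets$members)
})
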