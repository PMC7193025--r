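# Enrichment core: running-sum statistic, permutation null, NES, empirical p.

test_that("worked enrichment-score examples reproduce by hand", {
  sc <- toy_scores()
  # set {rank1, rank3}: running sum 0.625, 0.29167, 0.66667, 0.33333, 0
  es <- enrichment_score(sc, c("g1", "g3"))
  expect_equal(es$es, 2 / 3, tolerance = 1e-12)
  expect_equal(es$hit_curve,
               c(5 / 8, 5 / 8 - 1 / 3, 1 - 1 / 3, 1 - 2 / 3, 0),
               tolerance = 1e-12)
  # bottom-concentrated set: the maximum is the final 0
  expect_equal(enrichment_score(sc, c("g4", "g5"))$es, 0, tolerance = 1e-12)
  # a single top-ranked member attains the upper bound 1
  expect_equal(enrichment_score(sc, "g1")$es, 1, tolerance = 1e-12)
})

test_that("degenerate sets raise classed errors", {
  sc <- toy_scores()
  expect_error(enrichment_score(sc, c("x", "y")),
               class = "chemgsea_empty_overlap")
  expect_error(enrichment_score(sc, paste0("g", 1:5)),
               class = "chemgsea_degenerate")
  zero <- gene_scores(paste0("g", 1:4), c(1, 1, 0, 0))
  expect_error(enrichment_score(zero, c("g3", "g4")),
               class = "chemgsea_degenerate")
})

test_that("single-pass ES equals the brute-force double loop", {
  set.seed(101)
  worst <- 0
  for (i in 1:250) {
    N <- sample(5:50, 1)
    sc <- rand_scores(N)
    members <- sample(sc$gene_id, sample(1:(N - 1), 1))
    p <- sample(c(0, 0.5, 1, 2), 1)
    a <- enrichment_score(sc, members, weight_exponent = p)$es
    b <- brute_force_es(sc, members, p = p)
    worst <- max(worst, abs(a - b))
    # and the position-based fast path used by the permutation engine
    pos <- sort(which(sc$gene_id %in% members))
    cpos <- chemgsea:::es_from_positions(pos, abs(sc$score)^p, N)
    worst <- max(worst, abs(a - cpos))
  }
  expect_lt(worst, 1e-12)
})

test_that("two-sided variant equals its brute-force oracle and sees bottom sets", {
  set.seed(55)
  worst <- 0
  for (i in 1:100) {
    N <- sample(6:40, 1)
    sc <- rand_scores(N)
    members <- sample(sc$gene_id, sample(1:(N - 1), 1))
    a <- enrichment_score(sc, members, two_sided = TRUE)$es
    b <- brute_force_es(sc, members, two_sided = TRUE)
    worst <- max(worst, abs(a - b))
    pos <- sort(which(sc$gene_id %in% members))
    worst <- max(worst, abs(a - chemgsea:::es_from_positions(
      pos, abs(sc$score), N, two_sided = TRUE)))
  }
  expect_lt(worst, 1e-12)
  # a bottom-concentrated set scores negative under the two-sided variant
  sc <- toy_scores()
  expect_lt(enrichment_score(sc, c("g4", "g5"), two_sided = TRUE)$es, 0)
})

test_that("ES lies in [0, 1] on randomized fixtures", {
  set.seed(77)
  for (i in 1:400) {
    N <- sample(3:60, 1)
    sc <- rand_scores(N)
    members <- sample(sc$gene_id, sample(1:(N - 1), 1))
    es <- enrichment_score(sc, members)$es
    expect_gte(es, 0)
    expect_lte(es, 1 + 1e-12)
  }
})

test_that("promoting a member never decreases the unweighted (p = 0) ES", {
  set.seed(13)
  for (i in 1:200) {
    N <- sample(6:40, 1)
    sc <- rand_scores(N)
    members <- sample(sc$gene_id, sample(2:(N - 2), 1))
    hit <- sc$gene_id %in% members
    worst_hit <- max(which(hit))
    better <- which(!hit & seq_len(N) < worst_hit)
    if (length(better) == 0) next
    promoted <- c(setdiff(members, sc$gene_id[worst_hit]),
                  sc$gene_id[sample(better, 1)])
    expect_gte(enrichment_score(sc, promoted, weight_exponent = 0)$es,
               enrichment_score(sc, members, weight_exponent = 0)$es - 1e-12)
  }
})

test_that("permutation null is deterministic; constant scores reduce to the unweighted statistic", {
  # with constant scores the weighted hit increments become uniform 1/N_H, so
  # the p = 1 statistic coincides with the unweighted p = 0 one for every set,
  # and ES depends on the members only through their positions
  sc <- gene_scores(sprintf("g%03d", 1:40), rep(2, 40))
  for (m in list(c(3, 17, 30), 1:5, 36:40)) {
    members <- sc$gene_id[m]
    expect_equal(enrichment_score(sc, members)$es,
                 enrichment_score(sc, members, weight_exponent = 0)$es,
                 tolerance = 1e-12)
  }
  # and the null distribution is then a pure function of (size, seed): a
  # different constant gives the identical null vector
  sc_other <- gene_scores(sprintf("g%03d", 1:40), rep(9, 40))
  expect_equal(permutation_null(sc, 3, n_perm = 50, seed = 5),
               permutation_null(sc_other, 3, n_perm = 50, seed = 5),
               tolerance = 1e-12)

  sc2 <- rand_scores(60)
  expect_identical(permutation_null(sc2, 10, n_perm = 25, seed = 9),
                   permutation_null(sc2, 10, n_perm = 25, seed = 9))
  expect_length(permutation_null(sc2, 10, n_perm = 1, seed = 2), 1L)
  expect_error(permutation_null(sc2, 10, n_perm = 0, seed = 1),
               class = "chemgsea_domain")
  expect_error(permutation_null(sc2, 60, n_perm = 5, seed = 1),
               class = "chemgsea_domain")
})

test_that("normalize_and_test follows the NES formula and add-one estimator", {
  # printed-formula arithmetic: (0.6 - 0.2) / 0.1 = 4
  null1 <- c(0.1, 0.2, 0.3)  # mean 0.2, sd 0.1
  nt <- normalize_and_test(0.6, null1)
  expect_equal(nt$nes, 4, tolerance = 1e-12)

  nt2 <- normalize_and_test(0.35, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(nt2$p_empirical, 0.4)

  # observed equal to every null: p = 1, nes = 0 (degenerate sd)
  nt3 <- normalize_and_test(0.2, rep(0.2, 10))
  expect_equal(nt3$p_empirical, 1)
  expect_equal(nt3$nes, 0)

  expect_error(normalize_and_test(0.5, numeric(0)), class = "chemgsea_domain")
})

test_that("run_gsea filters by size, shares nulls per size, and orders results", {
  set.seed(2024)
  sc <- rand_scores(80)
  sets <- tibble::tibble(
    chemical = c("tiny", "bigA", "bigB", "ghost"),
    source_id = paste0("SYN:", 1:4),
    members = list(
      sc$gene_id[c(1, 2)],                      # below min_set_size
      sc$gene_id[seq(1, 40, by = 2)],           # size 20
      sc$gene_id[seq(2, 41, by = 2)],           # size 20 (shares the null)
      c("nope1", "nope2")                       # no overlap
    )
  )
  cfg <- gsea_config(n_permutations = 200, min_set_size = 5, seed = 42)
  expect_message(res <- run_gsea(sc, sets, cfg), "skipped 2")
  expect_setequal(res$chemical, c("bigA", "bigB"))
  expect_equal(attr(res, "skipped")[["too_small"]], 1L)
  expect_equal(attr(res, "skipped")[["empty_overlap"]], 1L)
  expect_equal(res$q_bh, p.adjust(res$p_empirical, "BH"))
  expect_true(all(diff(res$p_empirical) >= 0))

  # shared null per size: recomputing either chemical alone gives the same
  # nes/p as the joint run (null depends only on size and seed)
  null20 <- permutation_null(sc, 20, n_perm = 200,
                             seed = chemgsea:::child_seed(42, 20))
  esA <- enrichment_score(sc, sets$members[[2]])$es
  ntA <- normalize_and_test(esA, null20)
  expect_equal(res$nes[res$chemical == "bigA"], ntA$nes, tolerance = 1e-12)
  expect_equal(res$p_empirical[res$chemical == "bigA"], ntA$p_empirical)

  # nothing survives: warning and empty result
  cfg_strict <- gsea_config(n_permutations = 10, min_set_size = 50, seed = 1)
  expect_warning(none <- suppressMessages(run_gsea(sc, sets, cfg_strict)),
                 "no gene set")
  expect_equal(nrow(none), 0L)
})

test_that("a top-loaded planted set attains the minimum attainable p", {
  set.seed(31)
  sc <- gene_scores(sprintf("g%03d", 1:200),
                    sort(abs(rnorm(200, sd = 1)) + c(rep(4, 15), rep(0, 185)),
                         decreasing = TRUE))
  sets <- tibble::tibble(
    chemical = c("planted", paste0("null", 1:20)),
    source_id = paste0("SYN:", 0:20),
    members = c(list(sc$gene_id[1:15]),
                lapply(1:20, function(i) sample(sc$gene_id, 15)))
  )
  cfg <- gsea_config(n_permutations = 400, seed = 8)
  res <- suppressMessages(run_gsea(sc, sets, cfg))
  expect_equal(res$p_empirical[res$chemical == "planted"], 1 / 401)
  expect_equal(res$chemical[1], "planted")
})

test_that("run_gsea output is byte-identical across reruns with one seed", {
  set.seed(3)
  sc <- rand_scores(100)
  sets <- tibble::tibble(
    chemical = sprintf("c%02d", 1:12),
    source_id = sprintf("SYN:%02d", 1:12),
    members = lapply(1:12, function(i) sample(sc$gene_id, 10 + i))
  )
  cfg <- gsea_config(n_permutations = 150, seed = 99)
  r1 <- suppressMessages(run_gsea(sc, sets, cfg))
  r2 <- suppressMessages(run_gsea(sc, sets, cfg))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(r1, f1)
  write_results_table(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
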