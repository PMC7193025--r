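# Shared fixtures and independent oracles.

# Brute-force enrichment score: explicit double loop over list positions,
# recomputing prefix hit and miss mass from scratch at every position.
# Independent of the package's single-pass implementation.
brute_force_es <- function(scores, members, p = 1, two_sided = FALSE) {
  ord <- order(-scores$score, scores$gene_id)
  score <- scores$score[ord]
  gene <- scores$gene_id[ord]
  hit <- gene %in% members
  N <- length(gene)
  n_h <- sum(hit)
  n_r <- sum(abs(score[hit])^p)
  dev <- numeric(N)
  for (j in seq_len(N)) {
    hit_mass <- 0
    miss_mass <- 0
    for (k in seq_len(j)) {
      if (hit[k]) hit_mass <- hit_mass + abs(score[k])^p / n_r
      else miss_mass <- miss_mass + 1 / (N - n_h)
    }
    dev[j] <- hit_mass - miss_mass
  }
  if (two_sided) {
    mx <- max(max(dev), 0)
    mn <- min(min(dev), 0)
    # same fp-tolerant tie rule as the implementation: ties go positive
    if (abs(mn) > abs(mx) + 1e-12) mn else mx
  } else {
    max(max(dev), 0)
  }
}

# Random ranked score table over n genes.
rand_scores <- function(n, stream = "scores") {
  gene_scores(sprintf("g%04d", seq_len(n)), abs(rnorm(n)), stream)
}

# Small deterministic score table: scores 5,4,3,2,1 on genes g1..g5.
toy_scores <- function() gene_scores(paste0("g", 1:5), 5:1, "toy")

# Minimal enrichment-result tibble for integration tests.
fake_results <- function(disease, stream, chems, p) {
  tibble::tibble(disease = disease, stream = stream, chemical = chems,
                 p_empirical = p)
}
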