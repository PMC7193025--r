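# Enrichment core: weighted Kolmogorov-Smirnov-like running-sum enrichment
# score per chemical gene set, permutation null shared per set size, NES
# normalization and add-one empirical p-values.
#
# For a universe of N genes ranked by score r (descending) and a set S with
# N_H members in the universe, the running sum at position j is
#   sum_{hits <= j} |r|^p / N_R  -  sum_{misses <= j} 1 / (N - N_H),
# with N_R = sum_{hits} |r|^p, and ES(S) = max_j of the running sum. The sum
# ends at 0 (hit mass 1 minus miss mass 1), so 0 <= ES <= 1 by construction
# and bottom-concentrated sets score 0: the statistic is one-sided toward the
# top of the list.

#' Enrichment configuration
#'
#' @param weight_exponent Exponent `p >= 0` applied to scores in the hit
#'   increments (default 1, the classic weighted statistic; 0 gives the
#'   unweighted Kolmogorov-Smirnov form).
#' @param n_permutations Permutations for the empirical null (default 5000).
#' @param min_set_size,max_set_size Retain sets whose overlap with the ranked
#'   universe lies in `[min_set_size, max_set_size]` (defaults 5, 500).
#' @param alpha Significance level on the empirical p-value (default 0.05).
#' @param seed Seed for the permutation null; per-size child seeds are derived
#'   from it, so nulls do not depend on set order.
#' @param two_sided Use the classic two-sided variant (maximum absolute
#'   deviation, signed). Off by default; the default statistic is one-sided
#'   toward the top of the ranking.
#' @return An `enrichment_config` list.
#' @export
gsea_config <- function(weight_exponent = 1, n_permutations = 5000,
                        min_set_size = 5, max_set_size = 500,
                        alpha = 0.05, seed = 1L, two_sided = FALSE) {
  if (!is_scalar_number(weight_exponent) || weight_exponent < 0) {
    chem_abort("`weight_exponent` must be >= 0", "domain")
  }
  n_permutations <- check_count(n_permutations, "n_permutations")
  min_set_size <- check_count(min_set_size, "min_set_size")
  max_set_size <- check_count(max_set_size, "max_set_size")
  if (min_set_size > max_set_size) {
    chem_abort("`min_set_size` must be <= `max_set_size`", "domain")
  }
  structure(
    list(weight_exponent = weight_exponent, n_permutations = n_permutations,
         min_set_size = min_set_size, max_set_size = max_set_size,
         alpha = alpha, seed = as.integer(seed), two_sided = isTRUE(two_sided)),
    class = "enrichment_config"
  )
}

#' Running-sum enrichment score for one gene set
#'
#' Single pass over the ranked list: hit positions add `|r|^p / N_R`, miss
#' positions subtract `1 / (N - N_H)`; the score is the maximum of the running
#' sum (or, with `two_sided = TRUE`, the signed maximum absolute deviation).
#'
#' @param scores A `gene_scores` tibble (or any tibble with `gene_id`,
#'   `score`); re-sorted canonically (score descending, gene_id ascending).
#' @param members Character vector of member gene ids.
#' @param weight_exponent Score exponent `p` (default 1).
#' @param two_sided Classic signed max-absolute-deviation variant.
#' @return List with `es`, `hit_curve` (the running sum, length N), and
#'   `n_overlap`.
#' @export
enrichment_score <- function(scores, members, weight_exponent = 1,
                             two_sided = FALSE) {
  scores <- dplyr::arrange(tibble::as_tibble(scores),
                           dplyr::desc(score), gene_id)
  hit <- scores$gene_id %in% members
  N <- length(hit)
  n_h <- sum(hit)
  if (n_h == 0) {
    chem_abort("gene set has no overlap with the ranked universe",
               "empty_overlap")
  }
  if (n_h == N) {
    chem_abort("gene set covers the entire ranked universe", "degenerate")
  }
  rp <- abs(scores$score)^weight_exponent
  n_r <- sum(rp[hit])
  if (n_r <= 0) {
    chem_abort("all member scores are zero (N_R = 0)", "degenerate")
  }
  incr <- ifelse(hit, rp / n_r, -1 / (N - n_h))
  run <- cumsum(incr)
  # the running sum is analytically 0 at j = N; clamp the accumulated
  # floating-point residual there so the maximum is never spuriously negative
  mx <- max(max(run), 0)
  es <- if (two_sided) {
    mn <- min(min(run), 0)
    # magnitude ties (within fp tolerance) resolve to the positive deviation
    if (abs(mn) > abs(mx) + 1e-12) mn else mx
  } else {
    mx
  }
  list(es = es, hit_curve = run, n_overlap = n_h)
}

# Fast ES for a random member-position set: the running sum only attains its
# maximum at hit positions (it decreases at misses and ends at exactly 0), so
# ES = max_i { cum-hit-mass_i - misses-before_i / (N - m) }. For the
# two-sided variant the minimum lies just before a hit (or at position N).
es_from_positions <- function(pos_sorted, rp, N, two_sided = FALSE) {
  m <- length(pos_sorted)
  w <- cumsum(rp[pos_sorted])
  nr <- w[m]
  if (nr <= 0) return(0)
  i <- seq_len(m)
  peaks <- w / nr - (pos_sorted - i) / (N - m)
  es <- max(max(peaks), 0)
  if (two_sided) {
    # running sum just before hit i: (i-1) hit masses, (pos_i - i) misses
    troughs <- c(0, w[-m]) / nr - (pos_sorted - i) / (N - m)
    es_min <- min(troughs, 0)
    if (abs(es_min) > abs(es) + 1e-12) es <- es_min
  }
  es
}

#' Permutation null for the enrichment score
#'
#' Draws `n_perm` uniformly random subsets of `set_size` genes from the ranked
#' universe and records each subset's enrichment score. Deterministic given
#' the seed. Nulls depend on the set only through its size, so they are
#' computed once per size and shared across chemicals (see [run_gsea()]).
#'
#' @inheritParams enrichment_score
#' @param set_size Number of member genes per null draw (`1 <= set_size < N`).
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed.
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
permutation_null <- function(scores, set_size, weight_exponent = 1,
                             n_perm = 5000, seed = 1L, two_sided = FALSE) {
  n_perm <- check_count(n_perm, "n_perm")
  scores <- dplyr::arrange(tibble::as_tibble(scores),
                           dplyr::desc(score), gene_id)
  N <- nrow(scores)
  set_size <- check_count(set_size, "set_size")
  if (set_size >= N) {
    chem_abort("`set_size` must be smaller than the universe", "domain")
  }
  rp <- abs(scores$score)^weight_exponent
  with_rng(seed, {
    if (two_sided) {
      vapply(seq_len(n_perm), function(i) {
        pos <- sort.int(sample.int(N, set_size))
        es_from_positions(pos, rp, N, two_sided = TRUE)
      }, numeric(1))
    } else {
      # inlined one-sided fast path: the running-sum maximum is attained at a
      # hit position, so only member positions need visiting
      out <- numeric(n_perm)
      i_seq <- seq_len(set_size)
      denom <- N - set_size
      for (b in seq_len(n_perm)) {
        pos <- sort.int(sample.int(N, set_size))
        w <- cumsum(rp[pos])
        nr <- w[set_size]
        out[b] <- if (nr > 0) max(w / nr - (pos - i_seq) / denom) else 0
      }
      out
    }
  })
}

#' Normalize an enrichment score and compute its empirical p-value
#'
#' `NES = (ES - mean(ES_null)) / SD(ES_null)` (SD with denominator n-1) and
#' the add-one empirical p-value `p = (1 + #\{ES_null >= ES\}) / (n + 1)`,
#' never exactly zero. If the null SD collapses below `1e-12` (e.g. constant
#' scores), `NES = 0` while the p-value is still computed from counts.
#'
#' @param es_obs Observed enrichment score.
#' @param es_null Numeric vector of null enrichment scores (length >= 1).
#' @return List with `nes` and `p_empirical`.
#' @export
normalize_and_test <- function(es_obs, es_null) {
  if (length(es_null) < 1) {
    chem_abort("`es_null` must contain at least one value", "domain")
  }
  s <- stats::sd(es_null)
  nes <- if (!is.finite(s) || s < 1e-12) 0 else (es_obs - mean(es_null)) / s
  p <- (1 + sum(es_null >= es_obs)) / (length(es_null) + 1)
  list(nes = nes, p_empirical = p)
}

#' Chemical gene-set enrichment over a ranked gene list
#'
#' For every chemical set whose overlap with the ranked universe survives the
#' size filters, computes the running-sum enrichment score, a permutation null
#' shared across chemicals of equal overlap size, the normalized enrichment
#' score, the add-one empirical p-value and a Benjamini-Hochberg q-value.
#' Significance follows the raw empirical p (`p < alpha`); q-values are
#' reported alongside. Results are sorted by `p_empirical`, then `nes`
#' (descending), then `chemical`.
#'
#' @param scores A `gene_scores` tibble (universe of at least 2 genes).
#' @param sets Gene-set tibble (`chemical`, `source_id`, `members`), as from
#'   [read_gmt()] or [simulate_gene_sets()].
#' @param config An [gsea_config()].
#' @param stream Stream label for the output; defaults to the label carried by
#'   `scores`.
#' @return A `gsea_result` tibble: `chemical`, `stream`, `n_overlap`, `es`,
#'   `nes`, `p_empirical`, `q_bh`, `significant`. Counts of sets skipped by
#'   reason are attached as attribute `"skipped"` and reported via a message.
#' @export
run_gsea <- function(scores, sets, config = gsea_config(), stream = NULL) {
  stream <- stream %||% score_stream(scores)
  scores <- dplyr::arrange(tibble::as_tibble(scores),
                           dplyr::desc(score), gene_id)
  N <- nrow(scores)
  if (N < 2) chem_abort("ranked universe must contain at least 2 genes", "domain")
  universe <- scores$gene_id
  rp <- abs(scores$score)^config$weight_exponent

  pos_list <- lapply(sets$members, function(m) {
    sort.int(which(universe %in% m))
  })
  n_overlap <- lengths(pos_list)
  nr_all <- vapply(pos_list, function(p) sum(rp[p]), numeric(1))
  reason <- dplyr::case_when(
    n_overlap == 0 ~ "empty_overlap",
    n_overlap == N ~ "full_universe",
    n_overlap < config$min_set_size ~ "too_small",
    n_overlap > config$max_set_size ~ "too_large",
    nr_all <= 0 ~ "zero_scores",
    TRUE ~ "kept"
  )
  skipped <- table(reason[reason != "kept"])
  if (length(skipped) > 0) {
    rlang::inform(paste0(
      "run_gsea: skipped ", sum(skipped), " set(s): ",
      paste(sprintf("%s=%d", names(skipped), as.integer(skipped)),
            collapse = ", ")
    ))
  }
  keep <- which(reason == "kept")
  if (length(keep) == 0) {
    rlang::warn("run_gsea: no gene set survives the size filters")
    out <- tibble::tibble(
      chemical = character(), stream = character(), n_overlap = integer(),
      es = double(), nes = double(), p_empirical = double(),
      q_bh = double(), significant = logical()
    )
    return(structure(out, skipped = skipped, config = config,
                     class = c("gsea_result", class(out))))
  }

  es_obs <- vapply(keep, function(i) {
    es_from_positions(pos_list[[i]], rp, N, two_sided = config$two_sided)
  }, numeric(1))

  sizes <- sort(unique(n_overlap[keep]))
  nulls <- lapply(sizes, function(s) {
    permutation_null(scores, s,
                     weight_exponent = config$weight_exponent,
                     n_perm = config$n_permutations,
                     seed = child_seed(config$seed, s),
                     two_sided = config$two_sided)
  })
  names(nulls) <- as.character(sizes)

  nt <- lapply(seq_along(keep), function(k) {
    normalize_and_test(es_obs[k], nulls[[as.character(n_overlap[keep[k]])]])
  })
  p_emp <- vapply(nt, `[[`, numeric(1), "p_empirical")

  out <- tibble::tibble(
    chemical = sets$chemical[keep],
    stream = stream,
    n_overlap = as.integer(n_overlap[keep]),
    es = es_obs,
    nes = vapply(nt, `[[`, numeric(1), "nes"),
    p_empirical = p_emp,
    q_bh = stats::p.adjust(p_emp, method = "BH"),
    significant = p_emp < config$alpha
  )
  out <- dplyr::arrange(out, p_empirical, dplyr::desc(nes), chemical)
  structure(out, skipped = skipped, config = config,
            class = c("gsea_result", class(out)))
}
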