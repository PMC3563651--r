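# Independent oracles and small fixture builders shared across tests.

clan <- c("F-box", "F-box-like", "F-box-like_2")

# Exhaustive chain oracle: DFS over ALL monotone chains (both
# orientations), sharing no code with the DP in chain_anchors().
brute_force_best_chain <- function(anchors, max_gap = 10L, gap_penalty = 1.0) {
  n <- nrow(anchors)
  best <- -Inf
  for (dir in c(1, -1)) {
    ra <- anchors$rank_a
    rb <- dir * anchors$rank_b
    sc <- anchors$score
    succ <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- logical(n)
      for (j in seq_len(n)) {
        da <- ra[j] - ra[i]
        db <- rb[j] - rb[i]
        ok[j] <- da >= 1 && db >= 1 && (da - 1) <= max_gap && (db - 1) <= max_gap
      }
      succ[[i]] <- which(ok)
    }
    extend <- function(i, score_so_far) {
      best <<- max(best, score_so_far)
      for (j in succ[[i]]) {
        pen <- gap_penalty * (ra[j] - ra[i] - 1 + rb[j] - rb[i] - 1)
        extend(j, score_so_far + sc[j] - pen)
      }
    }
    for (i in seq_len(n)) extend(i, sc[i])
  }
  best
}

random_anchor_instance <- function(n, rank_max = 15L) {
  data.frame(gene_a = sprintf("a%d", seq_len(n)),
             gene_b = sprintf("b%d", seq_len(n)),
             chrom_a = "cA", chrom_b = "cB",
             rank_a = sample.int(rank_max, n, replace = TRUE),
             rank_b = sample.int(rank_max, n, replace = TRUE),
             score = round(runif(n, 1, 20), 2),
             stringsAsFactors = FALSE)
}

# Rand index by pair counting (agreements / all pairs).
rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  same_x <- outer(x, x, "==")
  same_y <- outer(y, y, "==")
  up <- upper.tri(same_x)
  mean(same_x[up] == same_y[up])
}

# Hand-built annotation: one gene per rank, unit geometry.
toy_annotation <- function(n_per_chrom, chroms = "chr1", family = character(0)) {
  rows <- do.call(rbind, lapply(chroms, function(cc) {
    start <- seq(1L, by = 1000L, length.out = n_per_chrom)
    data.frame(gene_id = sprintf("%s_g%03d", cc, seq_len(n_per_chrom)),
               chrom = cc, start = start, end = start + 500L, strand = "+",
               stringsAsFactors = FALSE)
  }))
  rows$family <- rows$gene_id %in% family
  genome_annotation(rows)
}

# Minimal homology rows linking the given id pairs (reciprocal).
toy_homology <- function(pairs, e_value = 1e-20) {
  if (nrow(pairs) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      pct_identity = numeric(), aln_len = integer(),
                      mismatches = integer(), gap_opens = integer(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      e_value = numeric(), bit_score = numeric()))
  }
  base <- data.frame(pct_identity = 80, aln_len = 200L, mismatches = 40L,
                     gap_opens = 1L, q_start = 1L, q_end = 200L,
                     s_start = 1L, s_end = 200L, e_value = e_value,
                     bit_score = 300)
  rbind(cbind(data.frame(query_id = pairs[[1]], subject_id = pairs[[2]]), base),
        cbind(data.frame(query_id = pairs[[2]], subject_id = pairs[[1]]), base))
}

# public wrappers over internals used when tests run against the
# installed namespace
block_incidence_pub <- function(blocks) syndup:::block_incidence(blocks, "a")

shuffle_labels_with_seed <- function(annotation, n, seed) {
  withr::with_seed(seed, shuffle_labels(annotation, n))
}
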