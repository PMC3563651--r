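test_that("ancestor simulation honours counts, labels, and determinism", {
  g0 <- simulate_ancestor(1, 10, 0.0, seed = 1)
  expect_equal(nrow(g0), 10L)
  expect_equal(sum(g0$family), 0L)

  g <- simulate_ancestor(2, 100, 0.1, seed = 7)
  expect_equal(nrow(g), 200L)
  expect_equal(sum(g$family), 20L)  # floor(0.1 * 200)

  expect_identical(simulate_ancestor(3, 50, 0.5, seed = 3),
                   simulate_ancestor(3, 50, 0.5, seed = 3))

  expect_error(simulate_ancestor(1, 10, 1.5, seed = 1), "family_fraction")
  expect_error(simulate_ancestor(1, 10, NaN, seed = 1), "family_fraction")
})

test_that("genes are unique, non-overlapping and rank-ordered by start", {
  for (seed in 1:5) {
    g <- simulate_ancestor(3, 40, 0.2, seed = seed)
    expect_false(anyDuplicated(g$gene_id) > 0)
    for (cc in unique(g$chrom)) {
      cg <- g[g$chrom == cc, ]
      cg <- cg[order(cg$rank), ]
      expect_equal(cg$rank, seq_len(nrow(cg)))
      expect_true(all(diff(cg$start) > 0))
      expect_true(all(cg$start[-1] > cg$end[-nrow(cg)])) # no overlap
    }
  }
})

test_that("WGD duplicates chromosomes and loses copies at the retention rate", {
  g <- simulate_ancestor(1, 10, 0.0, seed = 2)
  full <- apply_wgd(g, 1.0, seed = 1)
  expect_equal(nrow(full$genome), 20L)
  expect_equal(nrow(full$paralog_map), 10L)
  expect_setequal(unique(full$genome$chrom), c("chr01", "chr01_d"))

  none <- apply_wgd(g, 0.0, seed = 1)
  expect_equal(nrow(none$genome), 10L)
  expect_equal(nrow(none$paralog_map), 0L)

  big <- simulate_ancestor(4, 250, 0.0, seed = 3)
  half <- apply_wgd(big, 0.5, seed = 9)
  retained <- nrow(half$paralog_map)
  # 99.9% binomial interval for Binomial(1000, 0.5), computed analytically
  bounds <- qbinom(c(0.0005, 0.9995), 1000, 0.5)
  expect_gte(retained, bounds[1])
  expect_lte(retained, bounds[2])
})

test_that("tandem duplication inserts adjacent, family-labelled copies", {
  g <- simulate_ancestor(1, 50, 0.3, seed = 4)
  noop <- apply_tandem_duplications(g, 0, seed = 1)
  expect_identical(noop$genome, g)
  expect_length(noop$arrays, 0L)

  td <- apply_tandem_duplications(g, 1, array_size_sampler = function(n) rep(3L, n),
                                  seed = 5)
  arr <- td$arrays[[1]]
  expect_length(arr, 3L)
  ranks <- td$genome$rank[match(arr, td$genome$gene_id)]
  expect_equal(sort(ranks), min(ranks) + 0:2)  # consecutive ranks
  expect_true(all(td$genome$family[match(arr, td$genome$gene_id)]))
  # coordinates remain valid after insertion
  expect_s3_class(genome_annotation(as.data.frame(td$genome)), "genome_annotation")

  expect_error(apply_tandem_duplications(g, 1000, seed = 1), "exceeds")
})

test_that("domain-hit decoys fail exactly one filter criterion", {
  g <- simulate_ancestor(2, 100, 0.2, seed = 6)
  hits <- emit_domain_hits(g, true_positive_rate = 1, decoy_rate = 1, seed = 7)
  fam <- family_members(g)
  true_hits <- hits[hits$gene_id %in% fam, ]
  decoys <- hits[!hits$gene_id %in% fam, ]
  expect_equal(sort(unique(true_hits$gene_id)), sort(fam))
  expect_equal(nrow(decoys), 160L)  # every non-family gene at decoy_rate 1

  cov <- domain_coverage(hits)
  pass_e <- hits$e_value <= 1.0
  pass_cov <- cov >= 0.5
  expect_true(all(pass_e[hits$gene_id %in% fam] & pass_cov[hits$gene_id %in% fam]))
  n_failed <- (!pass_e[hits$gene_id %in% decoys$gene_id]) +
    (!pass_cov[hits$gene_id %in% decoys$gene_id])
  expect_true(all(n_failed == 1L))
})

test_that("homology emission is deterministic, reciprocal, and filter-aware", {
  pair <- simulate_genome_pair(2, 50, 0.2, wgd_retention = 0.7,
                               n_tandem_a = 2, seed = 11)
  h1 <- emit_homology_hits(pair, spurious_rate = 0.3, seed = 3)
  h2 <- emit_homology_hits(pair, spurious_rate = 0.3, seed = 3)
  expect_identical(h1, h2)

  clean <- emit_homology_hits(pair, spurious_rate = 0, seed = 3)
  keys <- paste(clean$query_id, clean$subject_id)
  rev_keys <- paste(clean$subject_id, clean$query_id)
  expect_true(all(rev_keys %in% keys))  # reciprocal
  expect_true(all(clean$e_value < 0.01))

  # with spurious hits, anchors after the 0.01 filter still only join
  # annotated genes, and spurious e-values straddle the threshold
  spur <- h1[!paste(h1$query_id, h1$subject_id) %in% keys &
               !paste(h1$subject_id, h1$query_id) %in% keys, ]
  expect_gt(sum(spur$e_value > 0.01), 0)
  expect_gt(sum(spur$e_value <= 0.01), 0)
})

test_that("pair ground truth is internally consistent", {
  pair <- simulate_genome_pair(3, 60, 0.15, wgd_retention = 0.6,
                               n_tandem_a = 4, n_tandem_b = 3,
                               ortholog_retention_b = 0.8, seed = 21)
  ids_a <- pair$genome_a$gene_id
  ids_b <- pair$genome_b$gene_id
  expect_true(all(pair$true_orthologs$gene_a %in% ids_a))
  expect_true(all(pair$true_orthologs$gene_b %in% ids_b))
  expect_true(all(pair$true_segmental_pairs$gene_a %in% ids_a))
  expect_true(all(pair$true_segmental_pairs$gene_b %in% ids_a))
  expect_true(all(unlist(pair$true_tandem_arrays$a) %in% ids_a))
  expect_true(all(unlist(pair$true_tandem_arrays$b) %in% ids_b))
  expect_true(all(lengths(pair$true_tandem_arrays$a) >= 2L))
  expect_true(all(pair$true_family_members$a %in% ids_a))
  one_chrom <- vapply(pair$true_tandem_arrays$a, function(g) {
    length(unique(pair$genome_a$chrom[match(g, ids_a)])) == 1L
  }, logical(1))
  expect_true(all(one_chrom))
  expect_gte(length(pair$event_log), 4L)
})

test_that("expression simulation is noiseless-exact and floored at zero", {
  genes <- sprintf("g%02d", 1:9)
  tissues <- c("root", "leaf", "nodule")
  assign <- setNames(rep(c("c1", "c2", "c3"), each = 3), genes)
  pref <- c(c1 = "root", c2 = "leaf", c3 = "nodule")
  m <- simulate_expression(genes, tissues, assign, pref,
                           effect_size = 5, noise_sd = 0, baseline = 1, seed = 1)
  argmax <- colnames(m)[apply(unclass(m), 1, which.max)]
  expect_equal(argmax, unname(pref[assign]))
  expect_true(all(unclass(m) >= 0))

  expect_error(simulate_expression(genes, tissues, assign,
                                   c(c1 = "root", c2 = "leaf", c3 = "mars"),
                                   5, 1, seed = 1),
               "unknown tissue")
})
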