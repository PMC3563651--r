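# Build a 4-chromosome genome pair in which genome B retains orthologs
# only as simulated, then detect blocks once; the permutation machinery
# reuses this fixed synteny map.
synteny_fixture <- function(n_chrom = 4, n_per = 100, seed = 301) {
  pair <- simulate_genome_pair(n_chrom, n_per, family_fraction = 0,
                               wgd_retention = NA, seed = seed)
  # restrict homology to half the chromosomes so block coverage is partial
  keep_chroms <- sort(unique(pair$genome_b$chrom))[seq_len(n_chrom / 2)]
  keep_b <- pair$genome_b$gene_id[pair$genome_b$chrom %in% keep_chroms]
  hom <- emit_homology_hits(pair, spurious_rate = 0, seed = seed + 1)
  hom <- hom[hom$query_id %in% keep_b | hom$subject_id %in% keep_b, ]
  blocks <- detect_synteny_blocks(pair$genome_a, pair$genome_b, hom)
  list(annotation = pair$genome_a, blocks = blocks)
}

test_that("label shuffling is uniform, boundary-exact, and validated", {
  ann <- toy_annotation(10)
  set.seed(5)
  expect_setequal(shuffle_labels(ann, 10), ann$gene_id)
  expect_length(shuffle_labels(ann, 0), 0L)
  expect_error(shuffle_labels(ann, 11), "exceeds")

  draws <- replicate(10000, shuffle_labels(ann, 1))
  counts <- table(factor(draws, levels = ann$gene_id))
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("saturated and empty synteny maps give degenerate results", {
  # blocks covering every gene position: the null statistic is constant
  pair <- simulate_genome_pair(2, 30, family_fraction = 0, wgd_retention = NA,
                               seed = 341)
  hom <- emit_homology_hits(pair, spurious_rate = 0, seed = 342)
  blocks <- detect_synteny_blocks(pair$genome_a, pair$genome_b, hom)
  ann <- pair$genome_a
  covered <- names(block_incidence_pub(blocks))
  expect_setequal(covered, ann$gene_id)
  members <- ann$gene_id[seq(1, 60, by = 4)]
  res <- synteny_permutation_test(ann, members, blocks,
                                  side = "a", n_reps = 50, seed = 1)
  expect_equal(res$observed, length(members))
  expect_true(all(res$null_counts == res$observed))
  expect_equal(res$p_greater, 1)

  none <- synteny_permutation_test(ann, members, list(),
                                   side = "a", n_reps = 50, seed = 1)
  expect_equal(none$observed, 0L)
  expect_true(all(none$null_counts == 0))
})

test_that("permutation results are bit-identical under a fixed seed", {
  fix <- synteny_fixture(4, 50)
  members <- shuffle_labels_with_seed(fix$annotation, 30, seed = 9)
  r1 <- synteny_permutation_test(fix$annotation, members, fix$blocks,
                                 side = "a", n_reps = 200, seed = 42)
  r2 <- synteny_permutation_test(fix$annotation, members, fix$blocks,
                                 side = "a", n_reps = 200, seed = 42)
  expect_identical(r1, r2)
  # add-one estimator identity
  expect_gte(r1$p_greater + r1$p_less, 1 + 1 / (r1$n_reps + 1))
  expect_equal(r1$null_mean, mean(r1$null_counts))
})

test_that("a fully in-block family is called enriched; the null mean matches coverage", {
  fix <- synteny_fixture(4, 250, seed = 311)
  ann <- fix$annotation
  inc <- block_incidence_pub(fix$blocks)
  covered <- intersect(names(inc), ann$gene_id)
  expect_equal(length(covered), 500L)  # half the 1000 positions
  members <- covered[seq(1, length(covered), length.out = 100)]
  res <- synteny_permutation_test(ann, members, fix$blocks, side = "a",
                                  n_reps = 2000, seed = 7)
  expect_equal(res$observed, 100L)
  expect_lte(res$p_greater, 0.001)
  se <- res$null_sd / sqrt(res$n_reps)
  expect_lt(abs(res$null_mean - 0.5 * 100), 3 * se + 1e-9)
})

test_that("multiplicity counting distributes one-to-many labels over blocks", {
  ann <- toy_annotation(20, "chr1")
  blk <- function(ga) {
    structure(list(anchors = data.frame(gene_a = ga,
                                        gene_b = sprintf("x%d", seq_along(ga)),
                                        rank_a = seq_along(ga),
                                        rank_b = seq_along(ga), score = 10),
                   orientation = "same", chain_score = 1,
                   chrom_a = "chr1", chrom_b = "cx"),
              class = "synteny_block")
  }
  blocks <- list(blk(c("chr1_g001", "chr1_g002")), blk(c("chr1_g001")))
  d <- synteny_permutation_test(ann, "chr1_g001", blocks, side = "a",
                                n_reps = 10, counting = "distinct", seed = 1)
  m <- synteny_permutation_test(ann, "chr1_g001", blocks, side = "a",
                                n_reps = 10, counting = "multiplicity", seed = 1)
  expect_equal(d$observed, 1L)
  expect_equal(m$observed, 2L)
})

test_that("tandem permutation test: scattered members give zero, one block gives all", {
  ann <- toy_annotation(100, "chr1")
  scattered <- ann$gene_id[seq(1, 100, by = 10)]  # 9 intervening genes
  res <- tandem_permutation_test(ann, scattered, n_reps = 100, seed = 3,
                                 max_intervening = 5)
  expect_equal(res$observed, 0)

  adjacent <- ann$gene_id[11:18]
  res2 <- tandem_permutation_test(ann, adjacent, n_reps = 100, seed = 3,
                                  max_intervening = 5)
  expect_equal(res2$observed, length(adjacent))
})

test_that("the tandem null covers its own draws (self-consistency)", {
  ann <- simulate_ancestor(2, 250, 0, seed = 321)
  inside <- 0L
  n_exp <- 40L
  for (i in seq_len(n_exp)) {
    members <- shuffle_labels_with_seed(ann, 25, seed = 1000 + i)
    res <- tandem_permutation_test(ann, members, n_reps = 400,
                                   seed = 2000 + i, max_intervening = 1)
    q <- stats::quantile(res$null_counts, c(0.025, 0.975), type = 1)
    if (res$observed >= q[1] && res$observed <= q[2]) inside <- inside + 1L
  }
  expect_gte(inside / n_exp, 0.9)
})

test_that("p_greater is super-uniform when members come from the null", {
  fix <- synteny_fixture(4, 125, seed = 331)  # 500 genes, half covered
  alpha <- 0.05
  n_exp <- 200L
  rejections <- 0L
  for (i in seq_len(n_exp)) {
    members <- shuffle_labels_with_seed(fix$annotation, 40, seed = 5000 + i)
    res <- synteny_permutation_test(fix$annotation, members, fix$blocks,
                                    side = "a", n_reps = 200, seed = 6000 + i)
    if (res$p_greater <= alpha) rejections <- rejections + 1L
  }
  se <- sqrt(alpha * (1 - alpha) / n_exp)
  expect_lte(rejections / n_exp, alpha + 3 * se)
})
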