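diag_anchors <- function(n, score = 10) {
  data.frame(gene_a = sprintf("a%d", 1:n), gene_b = sprintf("b%d", 1:n),
             chrom_a = "c1", chrom_b = "c2",
             rank_a = 1:n, rank_b = 1:n, score = score,
             stringsAsFactors = FALSE)
}

test_that("anchor scores are capped negative log e-values", {
  expect_equal(anchor_score(1e-10), 10)
  expect_equal(anchor_score(1e-80), 50)
  expect_equal(anchor_score(0), 50)
  expect_equal(anchor_score(c(1, 0.01)), c(0, 2))
  expect_error(anchor_score(-1), "non-negative")
})

test_that("a perfect diagonal chains into one block with the summed score", {
  blocks <- chain_anchors(diag_anchors(4))
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$chain_score, 40)
  expect_equal(blocks[[1]]$orientation, "same")
  expect_equal(blocks[[1]]$anchors$rank_a, 1:4)

  # three anchors cannot form a block at the 4-gene minimum
  expect_length(chain_anchors(diag_anchors(3)), 0L)
  expect_length(chain_anchors(diag_anchors(3), min_anchors = 3), 1L)
})

test_that("inverted blocks are found on the anti-diagonal", {
  a <- diag_anchors(5)
  a$rank_b <- 6 - a$rank_a
  blocks <- chain_anchors(a)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$orientation, "inverted")
  expect_equal(diff(blocks[[1]]$anchors$rank_b), rep(-1, 4))
})

test_that("gap penalties and the max_gap constraint shape chains", {
  a <- diag_anchors(4)
  a$rank_a <- c(1, 2, 3, 16)
  a$rank_b <- c(1, 2, 3, 16)
  # the 4th anchor is 12 ranks away: unreachable at max_gap = 10
  expect_length(chain_anchors(a, min_anchors = 4), 0L)
  b <- chain_anchors(a, min_anchors = 3)[[1]]
  expect_equal(nrow(b$anchors), 3L)

  # reachable gap: penalty of 1 per skipped rank on each axis
  a$rank_a <- c(1, 2, 3, 8)
  a$rank_b <- c(1, 2, 3, 8)
  blk <- chain_anchors(a)[[1]]
  expect_equal(blk$chain_score, 40 - 2 * 4)
})

test_that("mixed chromosome pairs are rejected; grouped wrapper handles them", {
  a <- diag_anchors(4)
  a$chrom_a[1] <- "other"
  expect_error(chain_anchors(a), "single chromosome pair")
})

test_that("DP score matches exhaustive enumeration on random instances", {
  set.seed(1201)
  for (i in 1:40) {
    inst <- random_anchor_instance(sample(2:9, 1))
    got <- chain_anchors(inst, min_anchors = 1)
    expect_equal(max(vapply(got, `[[`, numeric(1), "chain_score")),
                 brute_force_best_chain(inst),
                 tolerance = 1e-9, info = sprintf("instance %d", i))
  }
})

test_that("chaining is invariant to id relabeling and joint axis reversal", {
  set.seed(77)
  inst <- random_anchor_instance(10)
  base <- chain_anchors(inst, min_anchors = 2)
  relabeled <- inst
  relabeled$gene_a <- sprintf("x%s", inst$gene_a)
  relabeled$gene_b <- sprintf("y%s", inst$gene_b)
  expect_equal(vapply(chain_anchors(relabeled, min_anchors = 2),
                      `[[`, numeric(1), "chain_score"),
               vapply(base, `[[`, numeric(1), "chain_score"))
  flipped <- inst
  flipped$rank_a <- max(inst$rank_a) + 1 - inst$rank_a
  flipped$rank_b <- max(inst$rank_b) + 1 - inst$rank_b
  expect_equal(sort(vapply(chain_anchors(flipped, min_anchors = 2),
                           `[[`, numeric(1), "chain_score")),
               sort(vapply(base, `[[`, numeric(1), "chain_score")))
})

test_that("reported blocks satisfy monotonicity and anchor disjointness", {
  set.seed(88)
  inst <- random_anchor_instance(60, rank_max = 40)
  blocks <- chain_anchors(inst, min_anchors = 2)
  seen <- character(0)
  for (b in blocks) {
    expect_true(all(diff(b$anchors$rank_a) > 0))
    dr <- diff(b$anchors$rank_b)
    expect_true(all(dr > 0) || all(dr < 0))
    key <- paste(b$anchors$gene_a, b$anchors$gene_b)
    expect_length(intersect(key, seen), 0L)
    seen <- c(seen, key)
  }
})

test_that("tandem arrays follow adjacency, gap boundary and homology linkage", {
  fam <- c("chr1_g002", "chr1_g003", "chr1_g004", "chr1_g010", "chr1_g016")
  ann <- toy_annotation(20, "chr1", family = fam)
  hom <- toy_homology(data.frame(a = c("chr1_g002", "chr1_g003"),
                                 b = c("chr1_g003", "chr1_g004")))
  arrays <- detect_tandem_arrays(ann, fam, hom, max_intervening = 5)
  expect_length(arrays, 1L)
  expect_equal(arrays[[1]]$genes, c("chr1_g002", "chr1_g003", "chr1_g004"))
  expect_equal(arrays[[1]]$span_bp, 2501L)

  # g010 and g017 are separated by max_intervening + 1 = 6 genes: no array
  # even in positional mode; widening the gap allowance by one joins them
  pos <- detect_tandem_arrays(ann, c("chr1_g010", "chr1_g017"), NULL,
                              max_intervening = 5)
  expect_length(pos, 0L)
  pos2 <- detect_tandem_arrays(ann, c("chr1_g010", "chr1_g017"), NULL,
                               max_intervening = 6)
  expect_length(pos2, 1L)

  # without a homology link the run is not an array in homology mode
  lonely <- detect_tandem_arrays(ann, c("chr1_g002", "chr1_g003"),
                                 toy_homology(data.frame(a = character(),
                                                         b = character())[0, ]))
  expect_length(lonely, 0L)
})

test_that("simulated tandem arrays are recovered exactly in noiseless mode", {
  g <- simulate_ancestor(2, 250, 0.3, seed = 61)
  td <- apply_tandem_duplications(g, 20, seed = 62)
  pair <- list(genome_a = td$genome,
               genome_b = toy_annotation(2),
               true_orthologs = data.frame(gene_a = character(),
                                           gene_b = character()),
               true_segmental_pairs = data.frame(gene_a = character(),
                                                 gene_b = character()),
               true_tandem_arrays = list(a = td$arrays, b = list()),
               true_family_members = list(a = family_members(td$genome),
                                          b = character(0)))
  class(pair) <- "simulated_genome_pair"
  hom <- emit_homology_hits(pair, spurious_rate = 0, seed = 63)
  got <- detect_tandem_arrays(td$genome, family_members(td$genome), hom,
                              max_intervening = 0)
  expect_length(got, 20L)
  got_sets <- lapply(got, function(a) sort(a$genes))
  true_sets <- lapply(td$arrays, sort)
  expect_setequal(got_sets, true_sets)
})

test_that("segmental duplication detection separates WGD from tandem signal", {
  pair <- simulate_genome_pair(2, 60, 0.2, wgd_retention = 1.0, seed = 71)
  hom <- emit_homology_hits(pair, spurious_rate = 0, seed = 72)
  self_hom <- hom[hom$query_id %in% pair$genome_a$gene_id &
                    hom$subject_id %in% pair$genome_a$gene_id, ]
  segd <- detect_segmental_duplications(pair$genome_a, self_hom)
  expect_length(segd, 2L)  # one block per chromosome/duplicate pair
  sizes <- vapply(segd, function(s) nrow(s$block$anchors), integer(1))
  expect_equal(sort(sizes), c(60L, 60L))

  # a genome with only tandem duplications yields no segmental calls
  g <- simulate_ancestor(1, 100, 0.3, seed = 73)
  td <- apply_tandem_duplications(g, 10, seed = 74)
  tpair <- list(genome_a = td$genome, genome_b = toy_annotation(2),
                true_orthologs = data.frame(gene_a = character(),
                                            gene_b = character()),
                true_segmental_pairs = data.frame(gene_a = character(),
                                                  gene_b = character()),
                true_tandem_arrays = list(a = td$arrays, b = list()),
                true_family_members = list(a = character(0), b = character(0)))
  class(tpair) <- "simulated_genome_pair"
  thom <- emit_homology_hits(tpair, spurious_rate = 0, seed = 75)
  arrays <- detect_tandem_arrays(td$genome, family_members(td$genome), thom,
                                 max_intervening = 0)
  expect_length(detect_segmental_duplications(td$genome, thom,
                                              tandem_arrays = arrays), 0L)
})

test_that("genes_in_blocks counts distinct genes and incidences", {
  empty <- genes_in_blocks(list(), c("a1"), side = "a")
  expect_equal(empty, list(distinct_count = 0L, multiplicity_count = 0L))

  mk_block <- function(ga, gb) {
    structure(list(anchors = data.frame(gene_a = ga, gene_b = gb,
                                        rank_a = seq_along(ga),
                                        rank_b = seq_along(gb),
                                        score = 10),
                   orientation = "same", chain_score = 40,
                   chrom_a = "c1", chrom_b = "c2"),
              class = "synteny_block")
  }
  blocks <- list(mk_block(c("a1", "a2"), c("b1", "b2")),
                 mk_block(c("a1", "a3"), c("b3", "b4")))
  got <- genes_in_blocks(blocks, c("a1"), side = "a")
  expect_equal(got$distinct_count, 1L)
  expect_equal(got$multiplicity_count, 2L)
  expect_equal(genes_in_blocks(blocks, c("b2", "b9"), side = "b")$distinct_count, 1L)
})

test_that("block and array writers produce readable text outputs", {
  blocks <- chain_anchors(diag_anchors(4))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_blocks_tsv(blocks, p1)
  tab <- read.delim(p1)
  expect_equal(nrow(tab), 4L)
  expect_equal(unique(tab$block_id), 1L)
  p2 <- withr::local_tempfile(fileext = ".aligncoords")
  write_aligncoords(blocks, p2)
  lines <- readLines(p2)
  expect_match(lines[1], "^## alignment")
  expect_length(lines, 5L)
})
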