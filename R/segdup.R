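#' Detect segmental duplications within one genome
#'
#' Chains a genome's self-homology anchors into within-genome collinear
#' blocks — the signature that whole-genome or large segmental
#' duplication leaves behind. Before chaining, anchors that reflect local
#' rather than segmental duplication are excluded: pairs between genes of
#' the same tandem array, and same-chromosome pairs closer than
#' `max_intervening` ranks to the diagonal. Each unordered gene pair is
#' used once (the reciprocal BLAST hit is collapsed), and same-chromosome
#' blocks whose two rank windows overlap are discarded, so a region is
#' never reported as duplicated against itself.
#'
#' @param annotation a [genome_annotation()].
#' @param self_homology homology-hit data frame from an all-vs-all
#'   comparison of this genome against itself (self-hits are ignored).
#' @param tandem_arrays list of arrays from [detect_tandem_arrays()]
#'   whose within-array anchors are excluded.
#' @inheritParams chain_anchors
#' @param max_intervening near-diagonal exclusion radius (ranks), matched
#'   to the tandem-array definition.
#' @param max_evalue anchor e-value threshold.
#' @return List of `segmental_duplication` objects: each a list with
#'   `block` (a `synteny_block`) and `excludes_tandem = TRUE`.
#' @export
detect_segmental_duplications <- function(annotation, self_homology,
                                          tandem_arrays = list(),
                                          min_anchors = 4L, max_gap = 10L,
                                          gap_penalty = 1.0,
                                          max_intervening = 5L,
                                          max_evalue = 0.01) {
  anchors <- build_anchors(annotation, annotation, self_homology, max_evalue)
  if (nrow(anchors) == 0L) return(list())

  # canonical orientation: keep one of each reciprocal pair
  flip <- anchors$chrom_a > anchors$chrom_b |
    (anchors$chrom_a == anchors$chrom_b & anchors$rank_a > anchors$rank_b)
  if (any(flip)) {
    tmp <- anchors[flip, c("gene_b", "chrom_b", "rank_b",
                           "gene_a", "chrom_a", "rank_a")]
    anchors[flip, c("gene_a", "chrom_a", "rank_a",
                    "gene_b", "chrom_b", "rank_b")] <- tmp
  }
  anchors <- anchors[order(anchors$gene_a, anchors$gene_b, -anchors$score), ,
                     drop = FALSE]
  anchors <- anchors[!duplicated(paste(anchors$gene_a, anchors$gene_b)), ,
                     drop = FALSE]

  same_chrom <- anchors$chrom_a == anchors$chrom_b
  near_diag <- same_chrom &
    abs(anchors$rank_a - anchors$rank_b) <= max_intervening
  in_same_array <- rep(FALSE, nrow(anchors))
  if (length(tandem_arrays) > 0L) {
    array_of <- unlist(lapply(seq_along(tandem_arrays), function(i) {
      stats::setNames(rep(i, length(tandem_arrays[[i]]$genes)),
                      tandem_arrays[[i]]$genes)
    }))
    aa <- array_of[anchors$gene_a]
    ab <- array_of[anchors$gene_b]
    in_same_array <- !is.na(aa) & !is.na(ab) & aa == ab
  }
  anchors <- anchors[!near_diag & !in_same_array, , drop = FALSE]

  blocks <- chain_anchor_groups(anchors, min_anchors, max_gap, gap_penalty)
  blocks <- Filter(function(b) {
    if (b$chrom_a != b$chrom_b) return(TRUE)
    max(b$anchors$rank_a) < min(b$anchors$rank_b) ||
      max(b$anchors$rank_b) < min(b$anchors$rank_a)
  }, blocks)
  lapply(blocks, function(b) {
    structure(list(block = b, excludes_tandem = TRUE),
              class = "segmental_duplication")
  })
}

#' @export
print.segmental_duplication <- function(x, ...) {
  b <- x$block
  cat(sprintf("segmental_duplication: %s ~ %s, %d anchors, score %.1f\n",
              b$chrom_a, b$chrom_b, nrow(b$anchors), b$chain_score))
  invisible(x)
}
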