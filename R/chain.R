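#' Anchor score from a homology e-value
#'
#' DAGchainer-style scoring of a homologous gene pair: the negative
#' decimal logarithm of the e-value, floored at 1e-50 and capped at 50 so
#' a single overwhelming hit cannot dominate a chain.
#'
#' @param e_value non-negative numeric vector of e-values.
#' @return Positive scores, `min(50, -log10(max(e_value, 1e-50)))`.
#' @export
anchor_score <- function(e_value) {
  if (any(e_value < 0)) stop("e_value must be non-negative", call. = FALSE)
  pmin(50, -log10(pmax(e_value, 1e-50)))
}

#' Build collinearity anchors from homology hits
#'
#' Places filtered homology hits into gene-rank space: each retained hit
#' whose query is annotated in genome A and whose subject is annotated in
#' genome B becomes one anchor. Reciprocal duplicates of a gene pair are
#' collapsed, keeping the best (highest-scoring) hit.
#'
#' @param annotation_a,annotation_b [genome_annotation()] objects. For a
#'   self comparison, pass the same annotation twice (see
#'   [detect_segmental_duplications()] which also applies the required
#'   exclusions).
#' @param homology homology-hit data frame (outfmt-6 columns).
#' @param max_evalue anchor e-value threshold (0.01 for the all-vs-all
#'   protein comparisons this analysis consumes).
#' @return Anchor data frame: `gene_a`, `gene_b`, `chrom_a`, `chrom_b`,
#'   `rank_a`, `rank_b`, `score`.
#' @export
build_anchors <- function(annotation_a, annotation_b, homology, max_evalue = 0.01) {
  stopifnot(inherits(annotation_a, "genome_annotation"),
            inherits(annotation_b, "genome_annotation"))
  h <- homology[homology$e_value <= max_evalue &
                  homology$query_id != homology$subject_id, , drop = FALSE]
  ia <- match(h$query_id, annotation_a$gene_id)
  ib <- match(h$subject_id, annotation_b$gene_id)
  ok <- !is.na(ia) & !is.na(ib)
  h <- h[ok, , drop = FALSE]; ia <- ia[ok]; ib <- ib[ok]
  anchors <- data.frame(gene_a = h$query_id, gene_b = h$subject_id,
                        chrom_a = annotation_a$chrom[ia],
                        chrom_b = annotation_b$chrom[ib],
                        rank_a = annotation_a$rank[ia],
                        rank_b = annotation_b$rank[ib],
                        score = anchor_score(h$e_value),
                        stringsAsFactors = FALSE)
  ord <- order(anchors$gene_a, anchors$gene_b, -anchors$score)
  anchors <- anchors[ord, , drop = FALSE]
  anchors <- anchors[!duplicated(paste(anchors$gene_a, anchors$gene_b)), , drop = FALSE]
  rownames(anchors) <- NULL
  anchors
}

#' Chain anchors into syntenic blocks by dynamic programming
#'
#' Finds maximal-scoring chains of anchors collinear in gene-rank space,
#' the operation at the heart of DAGchainer-style synteny detection. A
#' chain is a sequence of anchors strictly increasing in `rank_a` and
#' strictly increasing (same orientation) or strictly decreasing
#' (inverted) in `rank_b`, with at most `max_gap` skipped gene ranks
#' between consecutive anchors on either axis. The chain score is the sum
#' of anchor scores minus `gap_penalty` per skipped rank. Chains are
#' extracted greedily in descending score order (anchors are disjoint
#' across reported blocks); chains with fewer than `min_anchors` anchors
#' are discarded. Requiring four aligned gene pairs to call a block is
#' the convention this analysis follows.
#'
#' @param anchors anchor data frame from [build_anchors()]; all rows must
#'   come from a single (chrom_a, chrom_b) pair.
#' @param min_anchors minimum anchors per reported block.
#' @param max_gap maximum skipped gene ranks between consecutive anchors.
#' @param gap_penalty score deducted per skipped rank.
#' @return List of `synteny_block` objects, each with `anchors` (rows in
#'   chain order), `orientation` (`"same"` or `"inverted"`),
#'   `chain_score`, `chrom_a`, `chrom_b`.
#' @export
chain_anchors <- function(anchors, min_anchors = 4L, max_gap = 10L,
                          gap_penalty = 1.0) {
  if (nrow(anchors) == 0L) return(list())
  if (length(unique(anchors$chrom_a)) > 1L || length(unique(anchors$chrom_b)) > 1L) {
    stop("chain_anchors expects anchors from a single chromosome pair; ",
         "split by (chrom_a, chrom_b) first", call. = FALSE)
  }
  stopifnot(min_anchors >= 1L, max_gap >= 0L, gap_penalty >= 0)
  remaining <- anchors
  blocks <- list()
  repeat {
    if (nrow(remaining) == 0L) break
    cand <- best_chain(remaining, max_gap, gap_penalty, min_anchors)
    if (is.null(cand)) break
    block <- structure(list(anchors = remaining[cand$index, , drop = FALSE],
                            orientation = cand$orientation,
                            chain_score = cand$score,
                            chrom_a = remaining$chrom_a[1],
                            chrom_b = remaining$chrom_b[1]),
                       class = "synteny_block")
    rownames(block$anchors) <- NULL
    blocks[[length(blocks) + 1L]] <- block
    remaining <- remaining[-cand$index, , drop = FALSE]
  }
  blocks
}

# Best chain (score, then smaller starting rank_a) with >= min_anchors
# anchors over both orientations; NULL if none. Returns row indices into
# `anchors` in chain order.
best_chain <- function(anchors, max_gap, gap_penalty, min_anchors) {
  fwd <- chain_dp(anchors$rank_a, anchors$rank_b, anchors$score,
                  max_gap, gap_penalty, min_anchors)
  rev <- chain_dp(anchors$rank_a, -anchors$rank_b, anchors$score,
                  max_gap, gap_penalty, min_anchors)
  pick <- NULL
  if (!is.null(fwd)) pick <- c(fwd, orientation = "same")
  if (!is.null(rev)) {
    better <- is.null(pick) || rev$score > pick$score ||
      (rev$score == pick$score &&
         anchors$rank_a[rev$index[1]] < anchors$rank_a[pick$index[[1]]])
    if (better) pick <- c(rev, orientation = "inverted")
  }
  pick
}

# Longest-path DP over anchors sorted by (ra, rb); strict increase on
# both axes, gap constraint and linear gap penalty on consecutive links.
chain_dp <- function(ra, rb, score, max_gap, gap_penalty, min_anchors) {
  n <- length(ra)
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]; sc <- score[ord]
  best <- sc
  len <- rep(1L, n)
  pred <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    j <- seq_len(i - 1L)
    da <- ra[i] - ra[j]
    db <- rb[i] - rb[j]
    valid <- da >= 1L & db >= 1L & (da - 1L) <= max_gap & (db - 1L) <= max_gap
    if (!any(valid)) next
    gain <- best[j][valid] - gap_penalty * (da[valid] - 1L + db[valid] - 1L)
    k <- which.max(gain)
    if (gain[k] > 0) {
      jj <- j[valid][k]
      best[i] <- sc[i] + gain[k]
      len[i] <- len[jj] + 1L
      pred[i] <- jj
    }
  }
  eligible <- which(len >= min_anchors)
  if (length(eligible) == 0L) return(NULL)
  end <- eligible[order(-best[eligible], ra[eligible])][1]
  chain <- integer(0)
  i <- end
  while (!is.na(i)) {
    chain <- c(i, chain)
    i <- pred[i]
  }
  list(score = best[end], index = ord[chain])
}

#' @export
print.synteny_block <- function(x, ...) {
  cat(sprintf("synteny_block: %s ~ %s, %d anchors, %s orientation, score %.1f\n",
              x$chrom_a, x$chrom_b, nrow(x$anchors), x$orientation, x$chain_score))
  invisible(x)
}

#' Detect syntenic blocks between two genomes
#'
#' Builds anchors from filtered homology hits and chains them separately
#' within every chromosome pair. Blocks are returned sorted by
#' (chrom_a, chrom_b, first rank_a).
#'
#' @inheritParams build_anchors
#' @inheritParams chain_anchors
#' @return List of `synteny_block` objects.
#' @export
detect_synteny_blocks <- function(annotation_a, annotation_b, homology,
                                  min_anchors = 4L, max_gap = 10L,
                                  gap_penalty = 1.0, max_evalue = 0.01) {
  anchors <- build_anchors(annotation_a, annotation_b, homology, max_evalue)
  chain_anchor_groups(anchors, min_anchors, max_gap, gap_penalty)
}

chain_anchor_groups <- function(anchors, min_anchors, max_gap, gap_penalty) {
  if (nrow(anchors) == 0L) return(list())
  groups <- split(seq_len(nrow(anchors)),
                  paste(anchors$chrom_a, anchors$chrom_b, sep = "\r"))
  blocks <- list()
  for (g in groups) {
    blocks <- c(blocks, chain_anchors(anchors[g, , drop = FALSE],
                                      min_anchors, max_gap, gap_penalty))
  }
  if (length(blocks) == 0L) return(blocks)
  key <- vapply(blocks, function(b)
    sprintf("%s\r%s\r%012d", b$chrom_a, b$chrom_b, b$anchors$rank_a[1]),
    character(1))
  blocks[order(key)]
}

#' Count family genes inside syntenic blocks
#'
#' @param blocks list of `synteny_block` objects (or of segmental
#'   duplications, whose `$block` is used).
#' @param members character vector of family gene ids.
#' @param side which anchor endpoint to count on: `"a"` or `"b"`. For a
#'   within-genome (segmental) comparison use `"both"`.
#' @return List with `distinct_count` (member genes appearing as an
#'   anchor endpoint in at least one block) and `multiplicity_count`
#'   (one per gene-block incidence, so a gene inside two blocks counts
#'   twice).
#' @export
genes_in_blocks <- function(blocks, members, side = c("a", "b", "both")) {
  side <- match.arg(side)
  inc <- block_incidence(blocks, side)
  inc <- inc[names(inc) %in% members]
  list(distinct_count = length(inc), multiplicity_count = sum(inc))
}

# named integer vector: gene id -> number of blocks it occurs in (as an
# anchor endpoint on the requested side)
block_incidence <- function(blocks, side) {
  per_block <- lapply(blocks, function(b) {
    if (inherits(b, "segmental_duplication")) b <- b$block
    switch(side,
           a = unique(b$anchors$gene_a),
           b = unique(b$anchors$gene_b),
           both = unique(c(b$anchors$gene_a, b$anchors$gene_b)))
  })
  ids <- unlist(per_block)
  if (length(ids) == 0L) return(structure(integer(0), names = character(0)))
  tab <- table(ids)
  structure(as.integer(tab), names = names(tab))
}

#' Write synteny blocks as TSV (one anchor per row)
#'
#' @param blocks list of `synteny_block` or `segmental_duplication`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blocks_tsv <- function(blocks, path) {
  rows <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (inherits(b, "segmental_duplication")) b <- b$block
    data.frame(block_id = i, orientation = b$orientation,
               chain_score = b$chain_score, b$anchors,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows) == 0L) {
    data.frame(block_id = integer(), orientation = character(),
               chain_score = numeric())
  } else {
    do.call(rbind, rows)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write blocks in a DAGchainer-style aligncoords text layout
#'
#' A header line per block (chromosome pair, anchor count, chain score)
#' followed by one indented line per anchor.
#'
#' @param blocks list of `synteny_block` or `segmental_duplication`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aligncoords <- function(blocks, path) {
  out <- character(0)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (inherits(b, "segmental_duplication")) b <- b$block
    out <- c(out,
             sprintf("## alignment %s vs. %s (block %d, %s): %d aligned pairs, score %.1f",
                     b$chrom_a, b$chrom_b, i, b$orientation,
                     nrow(b$anchors), b$chain_score),
             sprintf("%s\t%s\t%d\t%s\t%s\t%d\t%.1f",
                     b$chrom_a, b$anchors$gene_a, b$anchors$rank_a,
                     b$chrom_b, b$anchors$gene_b, b$anchors$rank_b,
                     b$anchors$score))
  }
  writeLines(out, path)
  invisible(path)
}
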