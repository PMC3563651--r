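#' Draw a random family-label assignment
#'
#' Samples `n_labels` genes uniformly without replacement from the
#' annotation — one shuffled relabelling of the genome, the unit of the
#' permutation null. Uses the current RNG state; the permutation tests
#' seed it once per test so the whole null is reproducible.
#'
#' @param annotation a [genome_annotation()].
#' @param n_labels number of labels to place (0..number of genes).
#' @return Character vector of sampled gene ids.
#' @export
shuffle_labels <- function(annotation, n_labels) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (n_labels > nrow(annotation)) {
    stop(sprintf("n_labels (%d) exceeds the %d annotated genes",
                 n_labels, nrow(annotation)), call. = FALSE)
  }
  if (n_labels == 0L) return(character(0))
  annotation$gene_id[sample.int(nrow(annotation), n_labels)]
}

#' Permutation test for family enrichment in syntenic blocks
#'
#' Tests whether family genes sit inside syntenic blocks more (or less)
#' often than expected by chance. Block membership is a fixed property of
#' gene positions: the observed statistic counts family genes occurring
#' as block anchor endpoints, and each null replicate recomputes the same
#' statistic after shuffling the family labels over all annotated genes —
#' relabelled copies of the same synteny map, so homology search and
#' chaining are not re-run. Where one-to-many relationships place a gene
#' in several blocks, the `multiplicity` counting distributes its label
#' across all of them; the default `distinct` counting counts each gene
#' once.
#'
#' @param annotation the [genome_annotation()] the blocks were computed
#'   against (the side being tested).
#' @param members character vector of family gene ids.
#' @param blocks list of `synteny_block` (or `segmental_duplication`)
#'   objects.
#' @param side anchor endpoint counted: `"a"`, `"b"`, or `"both"` for
#'   within-genome blocks.
#' @param n_reps number of label shuffles (10,000 in the full analysis).
#' @param counting `"distinct"` or `"multiplicity"`.
#' @param seed integer seed; the result is bit-identical under a fixed
#'   seed.
#' @return A `permutation_result`: list with `observed`, `null_counts`,
#'   `null_mean`, `null_sd`, `p_greater`, `p_less`, `n_reps`, `seed`.
#'   P-values use the add-one estimator
#'   `(1 + #(null >= observed)) / (n_reps + 1)`, so they are never zero.
#' @export
synteny_permutation_test <- function(annotation, members, blocks,
                                     side = c("a", "b", "both"),
                                     n_reps = 10000L,
                                     counting = c("distinct", "multiplicity"),
                                     seed = 1L) {
  side <- match.arg(side)
  counting <- match.arg(counting)
  stopifnot(inherits(annotation, "genome_annotation"))
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (length(members) < 1L) stop("members must be non-empty", call. = FALSE)
  unknown <- setdiff(members, annotation$gene_id)
  if (length(unknown) > 0L) {
    stop("member gene(s) absent from annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  inc <- block_incidence(blocks, side)
  per_gene <- integer(nrow(annotation))
  hit <- match(names(inc), annotation$gene_id)
  per_gene[hit[!is.na(hit)]] <- inc[!is.na(hit)]

  stat <- function(idx) {
    if (counting == "distinct") sum(per_gene[idx] > 0L) else sum(per_gene[idx])
  }
  observed <- stat(match(members, annotation$gene_id))
  n <- length(members)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_reps),
           function(i) stat(sample.int(nrow(annotation), n)), numeric(1))
  })
  permutation_result(observed, null_counts, n_reps, seed)
}

#' Permutation test for family enrichment in tandem arrays
#'
#' Observed statistic: the number of family genes inside detected tandem
#' arrays. Null replicates shuffle the family label over all gene
#' positions and re-detect arrays as positional runs with the same
#' spacing parameter; homology connectivity is dropped in replicates
#' (shuffled labels have no homology structure), a deliberate
#' approximation that makes the null slightly liberal about what counts
#' as an array. For a like-for-like comparison the observed statistic is
#' also computed positionally unless a homology table is supplied.
#'
#' @param annotation a [genome_annotation()].
#' @param members character vector of family gene ids.
#' @param n_reps number of label shuffles.
#' @param seed integer seed.
#' @param homology optional homology table for the observed arrays.
#' @param max_intervening,max_evalue array detection parameters, shared
#'   by observed and null detections.
#' @return A `permutation_result` (see [synteny_permutation_test()]).
#' @export
tandem_permutation_test <- function(annotation, members, n_reps = 10000L,
                                    seed = 1L, homology = NULL,
                                    max_intervening = 5L, max_evalue = 0.01) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (length(members) < 1L) stop("members must be non-empty", call. = FALSE)
  obs_arrays <- detect_tandem_arrays(annotation, members, homology,
                                     max_intervening, max_evalue)
  observed <- genes_in_arrays(obs_arrays)

  ai <- annotation_index(annotation)
  n <- length(members)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      idx <- sample.int(length(ai$rank), n)
      count_positional_run_genes(ai$chrom_code[idx], ai$rank[idx], max_intervening)
    }, numeric(1))
  })
  permutation_result(observed, null_counts, n_reps, seed)
}

# number of labelled genes lying in positional runs of >= 2 labelled
# genes with <= max_intervening unlabelled genes between neighbours
count_positional_run_genes <- function(chrom_code, ranks, max_intervening) {
  n <- length(ranks)
  if (n < 2L) return(0)
  o <- order(chrom_code, ranks)
  r <- ranks[o]; cc <- chrom_code[o]
  linked <- c(FALSE, diff(r) <= max_intervening + 1L & diff(cc) == 0L)
  grp <- cumsum(!linked)
  sizes <- tabulate(grp)
  sum(sizes[sizes >= 2L])
}

permutation_result <- function(observed, null_counts, n_reps, seed) {
  structure(list(observed = observed,
                 null_counts = null_counts,
                 null_mean = mean(null_counts),
                 null_sd = stats::sd(null_counts),
                 p_greater = (1 + sum(null_counts >= observed)) / (n_reps + 1),
                 p_less = (1 + sum(null_counts <= observed)) / (n_reps + 1),
                 n_reps = n_reps,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("permutation_result: observed %g, null %.2f +/- %.2f ",
                     "(%d reps), p_greater = %.4g, p_less = %.4g\n"),
              x$observed, x$null_mean, x$null_sd, x$n_reps,
              x$p_greater, x$p_less))
  invisible(x)
}

#' Write a permutation result as JSON (and optionally the null as TSV)
#'
#' @param result a `permutation_result`.
#' @param path JSON output path.
#' @param null_tsv optional path for the full null distribution
#'   (one count per line).
#' @return `path`, invisibly.
#' @export
write_permutation_json <- function(result, path, null_tsv = NULL) {
  stopifnot(inherits(result, "permutation_result"))
  jsonlite::write_json(
    list(observed = result$observed, null_mean = result$null_mean,
         null_sd = result$null_sd, p_greater = result$p_greater,
         p_less = result$p_less, n_reps = result$n_reps, seed = result$seed),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(null_tsv)) {
    utils::write.table(data.frame(null_count = result$null_counts), null_tsv,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
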