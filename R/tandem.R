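#' Detect tandem arrays of family genes
#'
#' A tandem array is a run of at least two family genes on one chromosome
#' in which consecutive members are separated by at most `max_intervening`
#' non-member genes in rank space and, when a homology table is supplied,
#' are linked by protein similarity at `e <= max_evalue` — transitively
#' within the run (single linkage), since local duplication chains decay
#' unevenly. With `homology = NULL` arrays are purely positional runs,
#' the mode the permutation null uses (shuffled labels carry no homology
#' structure).
#'
#' @param annotation a [genome_annotation()].
#' @param members character vector of family gene ids (must all be
#'   annotated).
#' @param homology optional homology-hit data frame; `NULL` for
#'   positional-run mode.
#' @param max_intervening maximum non-member genes between consecutive
#'   array members.
#' @param max_evalue homology threshold for array connectivity.
#' @return List of tandem arrays, each a list with `chrom`, `genes`
#'   (ids in rank order) and `span_bp` (first start to last end).
#' @export
detect_tandem_arrays <- function(annotation, members, homology = NULL,
                                 max_intervening = 5L, max_evalue = 0.01) {
  stopifnot(inherits(annotation, "genome_annotation"))
  unknown <- setdiff(members, annotation$gene_id)
  if (length(unknown) > 0L) {
    stop("member gene(s) absent from annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  idx <- which(annotation$gene_id %in% members)
  if (length(idx) < 2L) return(list())
  df <- annotation[idx, , drop = FALSE]
  df <- df[order(df$chrom, df$rank), , drop = FALSE]

  homo_pairs <- NULL
  if (!is.null(homology)) {
    good <- homology[homology$e_value <= max_evalue &
                       homology$query_id != homology$subject_id, , drop = FALSE]
    homo_pairs <- unique(paste(pmin(good$query_id, good$subject_id),
                               pmax(good$query_id, good$subject_id), sep = "\r"))
  }

  arrays <- list()
  for (cc in unique(df$chrom)) {
    cdf <- df[df$chrom == cc, , drop = FALSE]
    # positional runs: split where more than max_intervening genes intervene
    run_id <- cumsum(c(TRUE, diff(cdf$rank) > max_intervening + 1L))
    for (r in split(seq_len(nrow(cdf)), run_id)) {
      if (length(r) < 2L) next
      run <- cdf[r, , drop = FALSE]
      groups <- if (is.null(homo_pairs)) {
        list(seq_len(nrow(run)))
      } else {
        homology_components(run$gene_id, homo_pairs)
      }
      for (g in groups) {
        g <- sort(g)  # rank order within the run
        # re-apply the positional constraint inside a component: skipped
        # run members count as intervening genes
        seg_id <- cumsum(c(TRUE, diff(run$rank[g]) > max_intervening + 1L))
        for (s in split(g, seg_id)) {
          if (length(s) < 2L) next
          arrays[[length(arrays) + 1L]] <-
            list(chrom = cc,
                 genes = run$gene_id[s],
                 span_bp = max(run$end[s]) - min(run$start[s]) + 1L)
        }
      }
    }
  }
  arrays
}

# connected components (union-find) of the run's genes under the
# homologous-pair relation; returns list of index vectors into `ids`
homology_components <- function(ids, homo_pairs) {
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      key <- paste(min(ids[i], ids[j]), max(ids[i], ids[j]), sep = "\r")
      if (key %in% homo_pairs) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

#' Count genes inside tandem arrays
#'
#' @param arrays list of arrays from [detect_tandem_arrays()].
#' @return Number of distinct genes across all arrays.
#' @export
genes_in_arrays <- function(arrays) {
  length(unique(unlist(lapply(arrays, `[[`, "genes"))))
}

#' Write tandem arrays as TSV
#'
#' @param arrays list of arrays from [detect_tandem_arrays()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_arrays_tsv <- function(arrays, path) {
  df <- if (length(arrays) == 0L) {
    data.frame(array_id = integer(), chrom = character(), n_genes = integer(),
               span_bp = integer(), genes = character())
  } else {
    data.frame(array_id = seq_along(arrays),
               chrom = vapply(arrays, `[[`, character(1), "chrom"),
               n_genes = vapply(arrays, function(a) length(a$genes), integer(1)),
               span_bp = vapply(arrays, function(a) as.integer(a$span_bp), integer(1)),
               genes = vapply(arrays, function(a) paste(a$genes, collapse = ","),
                              character(1)),
               stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
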