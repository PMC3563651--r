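#' Genome annotation: ordered genes with per-chromosome ranks
#'
#' A `genome_annotation` is the coordinate system for every downstream
#' operation in the package. It is a data frame with one row per gene and
#' columns `gene_id`, `chrom`, `start`, `end`, `strand` plus a derived
#' `rank` column: the gene's 1-based position along its chromosome in
#' start-coordinate order. All base-pair coordinates are 1-based inclusive
#' (the GFF3 convention). Optionally a logical `family` column marks
#' members of the gene family under study (simulated genomes carry it;
#' real annotations usually get membership from [call_family_members()]).
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (and optionally `family`).
#' @return A `genome_annotation` object: the validated data frame, sorted
#'   by chromosome and start, with a `rank` column added.
#'
#' @details Rank is assigned by start coordinate; ties are broken by end
#'   coordinate, then gene id, so ranking is total and reproducible.
#'   Duplicate gene ids, reversed coordinates (`start > end`) and genes
#'   duplicated at identical (chrom, start, end) are rejected rather than
#'   repaired.
#' @export
genome_annotation <- function(genes) {
  required <- c("gene_id", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0L) {
    stop("annotation is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)

  if (anyNA(genes$start) || anyNA(genes$end)) {
    stop("annotation has missing coordinates", call. = FALSE)
  }
  if (any(genes$start > genes$end)) {
    bad <- genes$gene_id[genes$start > genes$end]
    stop("start > end for gene(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    bad <- unique(genes$gene_id[duplicated(genes$gene_id)])
    stop("duplicate gene id(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  key <- paste(genes$chrom, genes$start, genes$end)
  if (anyDuplicated(key)) {
    stop("two genes share identical (chrom, start, end)", call. = FALSE)
  }

  ord <- order(genes$chrom, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(genes)), genes$chrom, FUN = seq_along)
  genes$rank <- as.integer(rank)
  rownames(genes) <- NULL

  keep <- c(required, "rank",
            intersect("family", names(genes)))
  genes <- genes[, keep, drop = FALSE]
  class(genes) <- c("genome_annotation", "data.frame")
  genes
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if ("family" %in% names(x)) {
    cat(sprintf("  family members: %d\n", sum(x$family)))
  }
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... and %d more genes\n", nrow(x) - 6L))
  invisible(x)
}

#' Family member ids of an annotation
#'
#' @param annotation a [genome_annotation()] carrying a `family` column.
#' @return Character vector of family gene ids.
#' @export
family_members <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (!"family" %in% names(annotation)) {
    stop("annotation has no 'family' column", call. = FALSE)
  }
  annotation$gene_id[annotation$family]
}

# Run code with a private RNG stream seeded by `seed`; the caller's
# .Random.seed is restored afterwards so no global state leaks.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Integer chromosome codes + ranks, used by the permutation fast paths.
annotation_index <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  list(gene_id = annotation$gene_id,
       chrom_code = as.integer(factor(annotation$chrom)),
       rank = annotation$rank)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(name, " must be a single finite value in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
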