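#' Gene-by-tissue expression matrix
#'
#' A numeric matrix with gene ids as row names and tissue names as column
#' names, tagged with whether it holds raw values or per-gene z-scores.
#'
#' @param values numeric matrix; rows are genes, columns tissues. Raw
#'   values must be non-negative and free of missing values.
#' @param standardized whether values are already z-scores.
#' @return An `expression_matrix`.
#' @export
expression_matrix <- function(values, standardized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene row names and tissue column names", call. = FALSE)
  }
  if (anyNA(values)) stop("expression matrix contains missing values", call. = FALSE)
  if (!standardized && any(values < 0)) {
    stop("raw expression values must be non-negative", call. = FALSE)
  }
  structure(values, standardized = standardized,
            class = c("expression_matrix", class(values)))
}

is_standardized <- function(matrix) isTRUE(attr(matrix, "standardized"))

#' Z-score standardize each gene across tissues
#'
#' Each row is transformed to `(x - mean(x)) / sd(x)` using the
#' population (divide-by-n) standard deviation, the convention used when
#' comparing expression profiles rather than estimating a variance.
#' Constant rows (zero sd) are set to all-zero and reported in the
#' `"degenerate_rows"` attribute.
#'
#' @param matrix a raw [expression_matrix()] with at least two tissues.
#' @param population use the population sd (default); `FALSE` switches to
#'   the sample (n-1) sd.
#' @return A standardized [expression_matrix()].
#' @export
zscore_rows <- function(matrix, population = TRUE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (ncol(matrix) < 2L) {
    stop("z-score standardization needs at least two tissues", call. = FALSE)
  }
  values <- unclass(matrix)
  attr(values, "standardized") <- NULL
  mu <- rowMeans(values)
  centred <- values - mu
  denom <- if (population) ncol(values) else ncol(values) - 1L
  sd_row <- sqrt(rowSums(centred^2) / denom)
  degenerate <- sd_row == 0
  sd_row[degenerate] <- 1
  z <- centred / sd_row
  z[degenerate, ] <- 0
  out <- expression_matrix(z, standardized = TRUE)
  attr(out, "degenerate_rows") <- rownames(values)[degenerate]
  out
}

#' Call transcribed genes from a raw expression matrix
#'
#' A gene is called transcribed when its value exceeds `threshold` in at
#' least one tissue (strictly greater: a gene exactly at the threshold is
#' not called). The 10.0 default is the normalized-intensity cutoff used
#' for microarray-style matrices; for data already restricted to
#' author-reported transcribed genes use `threshold = 0`.
#'
#' @param matrix a raw [expression_matrix()].
#' @param threshold strict lower bound on the maximum expression.
#' @return Character vector of transcribed gene ids.
#' @export
call_transcribed <- function(matrix, threshold = 10.0) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (is_standardized(matrix)) {
    stop("call_transcribed needs raw values, not z-scores", call. = FALSE)
  }
  maxima <- apply(unclass(matrix), 1L, max)
  names(maxima)[maxima > threshold]
}

#' Hierarchically cluster genes by expression profile
#'
#' Agglomerative clustering of standardized gene profiles, by default
#' with Pearson-correlation distance (`1 - r` between gene rows) and
#' average linkage — the customary choice for tissue expression heatmaps.
#' All-zero (degenerate) rows have no defined correlation and are
#' excluded with a warning under the Pearson metric.
#'
#' @param matrix a standardized [expression_matrix()] with >= 2 genes.
#' @param distance `"pearson"` or `"euclidean"`.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An `expression_clustering`: list with `hclust` (the merge
#'   tree), `leaf_order` (gene ids in dendrogram order), `cut` (function
#'   `k -> named cluster labels`) and `excluded` (ids of dropped rows).
#' @export
hierarchical_cluster <- function(matrix,
                                 distance = c("pearson", "euclidean"),
                                 linkage = c("average", "complete", "single")) {
  stopifnot(inherits(matrix, "expression_matrix"))
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (!is_standardized(matrix)) {
    stop("cluster standardized profiles; run zscore_rows() first", call. = FALSE)
  }
  values <- unclass(matrix)
  excluded <- character(0)
  if (distance == "pearson") {
    degenerate <- apply(values, 1L, function(x) stats::sd(x) == 0)
    if (any(degenerate)) {
      excluded <- rownames(values)[degenerate]
      warning(sprintf("excluding %d degenerate (constant) row(s) from Pearson clustering",
                      length(excluded)))
      values <- values[!degenerate, , drop = FALSE]
    }
  }
  if (nrow(values) < 2L) stop("need at least two genes to cluster", call. = FALSE)
  d <- if (distance == "pearson") {
    stats::as.dist(1 - stats::cor(t(values)))
  } else {
    stats::dist(values)
  }
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc,
                 leaf_order = hc$labels[hc$order],
                 cut = function(k) stats::cutree(hc, k = k),
                 excluded = excluded,
                 distance = distance, linkage = linkage),
            class = "expression_clustering")
}

#' @export
print.expression_clustering <- function(x, ...) {
  cat(sprintf("expression_clustering: %d genes, %s distance, %s linkage\n",
              length(x$leaf_order), x$distance, x$linkage))
  invisible(x)
}

#' Write a clustering dendrogram as Newick
#'
#' @param clustering an `expression_clustering`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  stopifnot(inherits(clustering, "expression_clustering"))
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}

#' Assign each gene a preferred tissue
#'
#' A gene's preference is the tissue of its maximum z-score, provided
#' that z-score reaches `min_z`; genes below the threshold, and exact
#' ties for the maximum, get no preference (`NA`). This operationalizes
#' "preferentially expressed in tissue X" from a standardized profile.
#'
#' @param matrix a standardized [expression_matrix()].
#' @param min_z minimum z-score for a preference call (default 1.5, i.e.
#'   one and a half standard deviations above the gene's own mean).
#' @return Named character vector, gene id -> tissue or `NA`.
#' @export
tissue_preference <- function(matrix, min_z = 1.5) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!is_standardized(matrix)) {
    stop("tissue_preference needs z-scores; run zscore_rows() first", call. = FALSE)
  }
  values <- unclass(matrix)
  pref <- apply(values, 1L, function(x) {
    top <- max(x)
    if (top < min_z) return(NA_character_)
    at <- which(x == top)
    if (length(at) > 1L) return(NA_character_)
    colnames(values)[at]
  })
  stats::setNames(as.character(pref), rownames(values))
}

#' Classify transcriptional divergence within tandem arrays
#'
#' For each tandem array, compares the preferred tissues of its member
#' genes: an array is `divergent` when at least two members prefer
#' different tissues (the signature of post-duplication regulatory
#' divergence), `concordant` when at least two members share the single
#' preferred tissue, `untranscribed` when no member has a preference, and
#' `indeterminate` when exactly one does.
#'
#' @param preferences named vector from [tissue_preference()]; array
#'   genes absent from it count as having no preference.
#' @param arrays list of arrays from [detect_tandem_arrays()].
#' @return Data frame with one row per array: `array_id`, `chrom`,
#'   `n_genes`, `n_with_preference`, `classification`.
#' @export
divergence_within_arrays <- function(preferences, arrays) {
  rows <- lapply(seq_along(arrays), function(i) {
    a <- arrays[[i]]
    pref <- preferences[a$genes]
    pref <- pref[!is.na(pref)]
    classification <- if (length(pref) == 0L) {
      "untranscribed"
    } else if (length(unique(pref)) > 1L) {
      "divergent"
    } else if (length(pref) >= 2L) {
      "concordant"
    } else {
      "indeterminate"
    }
    data.frame(array_id = i, chrom = a$chrom, n_genes = length(a$genes),
               n_with_preference = length(pref),
               classification = classification, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(array_id = integer(), chrom = character(),
                      n_genes = integer(), n_with_preference = integer(),
                      classification = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
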