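#' Percentage with half-away-from-zero rounding
#'
#' `round(100 * numerator / denominator, decimals)` with halves rounded
#' away from zero — the convention under which 186 of 480 prints as
#' 38.8 (38.75 rounds up), unlike R's banker's rounding.
#'
#' @param numerator,denominator counts, `0 <= numerator <= denominator`,
#'   `denominator > 0`.
#' @param decimals decimal places to keep.
#' @return The rounded percentage.
#' @export
percentage <- function(numerator, denominator, decimals = 1L) {
  if (any(denominator <= 0)) stop("denominator must be positive", call. = FALSE)
  if (any(numerator < 0 | numerator > denominator)) {
    stop("numerator must lie in [0, denominator]", call. = FALSE)
  }
  x <- 100 * numerator / denominator
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Assemble the per-genome architecture summary
#'
#' Aggregates everything the pipeline computed for one genome (optionally
#' against a comparison genome) into a single reproducible summary:
#' family size, how many members sit in syntenic blocks, in segmentally
#' duplicated regions and in tandem arrays, how many tandem members are
#' transcribed, with the corresponding percentages and any permutation
#' results. All gene ids are validated against the annotation; offenders
#' are listed in the error.
#'
#' @param annotation the genome's [genome_annotation()].
#' @param calls a `family_call_set` for the genome.
#' @param blocks list of `synteny_block` objects (genome as side "a"),
#'   or `NULL`.
#' @param segdups list of `segmental_duplication` objects, or `NULL`.
#' @param arrays list of tandem arrays, or `NULL`.
#' @param transcribed character vector of transcribed gene ids, or
#'   `NULL` if no expression data is attached.
#' @param permutations named list of `permutation_result` objects to
#'   embed (e.g. `list(synteny = ..., tandem = ...)`).
#' @param genome_label name used in the report.
#' @return An `architecture_summary` (a nested list, ready for
#'   [write_summary()]).
#' @export
build_summary <- function(annotation, calls, blocks = NULL, segdups = NULL,
                          arrays = NULL, transcribed = NULL,
                          permutations = list(), genome_label = "genome") {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(calls, "family_call_set"))
  universe <- annotation$gene_id
  offenders <- list(
    members = setdiff(calls$members, universe),
    arrays = setdiff(unlist(lapply(arrays, `[[`, "genes")), universe),
    transcribed = if (is.null(transcribed)) character(0)
                  else setdiff(transcribed, universe))
  bad <- unlist(offenders)
  if (length(bad) > 0L) {
    stop("inconsistent gene-id universes; offender(s): ",
         paste(utils::head(unique(bad), 10), collapse = ", "), call. = FALSE)
  }

  family_size <- length(calls$members)
  summary <- list(genome = genome_label,
                  n_genes = nrow(annotation),
                  family_size = family_size,
                  n_inactive_candidates = length(calls$inactive_candidates))

  pct <- function(n) if (family_size > 0L) percentage(n, family_size) else NULL

  if (!is.null(blocks)) {
    syn <- genes_in_blocks(blocks, calls$members, side = "a")
    summary$n_syntenic <- syn$distinct_count
    summary$n_syntenic_incidences <- syn$multiplicity_count
    summary$pct_syntenic <- pct(syn$distinct_count)
    if (!is.null(segdups) && syn$distinct_count > 0L) {
      syntenic_members <- intersect(names(block_incidence(blocks, "a")),
                                    calls$members)
      seg <- genes_in_blocks(segdups, syntenic_members, side = "both")
      summary$n_syntenic_in_segdup <- seg$distinct_count
      summary$pct_syntenic_in_segdup <- percentage(seg$distinct_count,
                                                   syn$distinct_count)
    }
  }
  if (!is.null(segdups)) {
    seg_all <- genes_in_blocks(segdups, calls$members, side = "both")
    summary$n_in_segdup <- seg_all$distinct_count
    summary$pct_in_segdup <- pct(seg_all$distinct_count)
  }
  if (!is.null(arrays)) {
    tandem_genes <- intersect(unique(unlist(lapply(arrays, `[[`, "genes"))),
                              calls$members)
    summary$n_tandem <- length(tandem_genes)
    summary$pct_tandem <- pct(length(tandem_genes))
    if (!is.null(transcribed)) {
      n_tt <- length(intersect(tandem_genes, transcribed))
      summary$n_tandem_transcribed <- n_tt
      if (length(tandem_genes) > 0L) {
        summary$pct_tandem_transcribed <- percentage(n_tt, length(tandem_genes), 2L)
      }
    }
  }
  if (length(permutations) > 0L) {
    summary$permutations <- lapply(permutations, function(p) {
      stopifnot(inherits(p, "permutation_result"))
      list(observed = p$observed, null_mean = p$null_mean, null_sd = p$null_sd,
           p_greater = p$p_greater, p_less = p$p_less,
           n_reps = p$n_reps, seed = p$seed)
    })
  }
  structure(summary, class = "architecture_summary")
}

#' @export
print.architecture_summary <- function(x, ...) {
  cat(sprintf("architecture_summary for %s: %d genes, %d family members\n",
              x$genome, x$n_genes, x$family_size))
  for (f in c("pct_syntenic", "pct_syntenic_in_segdup", "pct_tandem",
              "pct_tandem_transcribed")) {
    if (!is.null(x[[f]])) cat(sprintf("  %s: %s%%\n", f, format(x[[f]])))
  }
  invisible(x)
}

#' Write an architecture summary as JSON (canonical) and TSV (flattened)
#'
#' @param summary an `architecture_summary` from [build_summary()].
#' @param json_path output JSON path.
#' @param tsv_path optional flattened TSV path (scalar fields only).
#' @return `json_path`, invisibly.
#' @export
write_summary <- function(summary, json_path, tsv_path = NULL) {
  stopifnot(inherits(summary, "architecture_summary"))
  jsonlite::write_json(unclass(summary), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(tsv_path)) {
    scalars <- Filter(function(v) is.atomic(v) && length(v) == 1L,
                      unclass(summary))
    df <- data.frame(field = names(scalars),
                     value = vapply(scalars, function(v) format(v, digits = 12),
                                    character(1)),
                     stringsAsFactors = FALSE)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(json_path)
}
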