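#' Fraction of the domain model covered by a hit
#'
#' Coverage is measured on the HMM model span: the aligned match states
#' `(hmm_to - hmm_from + 1)` over the model length. This is the quantity
#' thresholded by the family filter ("half of the domain aligned").
#'
#' @param hits domain-hit data frame (or a single row).
#' @return Numeric vector of coverages in (0, 1].
#' @export
domain_coverage <- function(hits) {
  if (any(hits$model_length == 0L)) {
    stop("model_length must be positive", call. = FALSE)
  }
  validate_domain_hits(hits)
  (hits$hmm_to - hits$hmm_from + 1) / hits$model_length
}

#' Call family members from a domain-hit table
#'
#' A gene is a family member iff it carries at least one hit to a clan
#' domain with e-value at or below `max_evalue` and model coverage at or
#' above `min_coverage`. The defaults are the family filter used for
#' F-box detection: a deliberately permissive e-value of 1.0 (so rapidly
#' diverging members are not missed) balanced by requiring half of the
#' domain model aligned (so spurious partial matches are excluded).
#'
#' @param hits domain-hit data frame (see [read_domtblout()]).
#' @param clan_domains character vector of domain names defining the clan,
#'   e.g. `c("F-box", "F-box-like", "F-box-like_2")`.
#' @param max_evalue,min_coverage filter thresholds.
#' @param annotation optional [genome_annotation()]; when supplied, hit
#'   gene ids absent from it raise a validation error rather than being
#'   silently dropped.
#' @return A `family_call_set`: list with `members` (sorted ids),
#'   `inactive_candidates` (empty until [detect_inactive_members()] is
#'   run) and `evidence` (one best qualifying hit per member: minimum
#'   e-value, ties broken by larger coverage then domain name).
#' @export
call_family_members <- function(hits, clan_domains,
                                max_evalue = 1.0, min_coverage = 0.5,
                                annotation = NULL) {
  if (length(clan_domains) == 0L) stop("clan_domains must be non-empty", call. = FALSE)
  if (!is.null(annotation)) {
    unknown <- setdiff(unique(hits$gene_id), annotation$gene_id)
    if (length(unknown) > 0L) {
      stop("domain hits reference gene id(s) absent from the annotation: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(hits) == 0L) {
    return(structure(list(members = character(),
                          inactive_candidates = character(),
                          evidence = hits),
                     class = "family_call_set"))
  }
  cov <- domain_coverage(hits)
  qualifies <- hits$domain_name %in% clan_domains &
    hits$e_value <= max_evalue & cov >= min_coverage
  q <- hits[qualifies, , drop = FALSE]
  q$coverage <- cov[qualifies]
  ord <- order(q$gene_id, q$e_value, -q$coverage, q$domain_name)
  q <- q[ord, , drop = FALSE]
  best <- q[!duplicated(q$gene_id), , drop = FALSE]
  rownames(best) <- NULL
  structure(list(members = sort(unique(q$gene_id)),
                 inactive_candidates = character(),
                 evidence = best),
            class = "family_call_set")
}

#' @export
print.family_call_set <- function(x, ...) {
  cat(sprintf("family_call_set: %d member(s), %d potentially inactive candidate(s)\n",
              length(x$members), length(x$inactive_candidates)))
  invisible(x)
}

#' Flag potentially inactive family members
#'
#' Genes that are not called members (they lack a qualifying domain hit —
#' e.g. the domain degenerated beyond recognition) but retain protein
#' similarity to at least one called member are flagged as potentially
#' inactive family genes.
#'
#' @param calls a `family_call_set` from [call_family_members()].
#' @param homology homology-hit data frame (outfmt-6 columns).
#' @param max_evalue similarity threshold on the homology e-value.
#' @return The `family_call_set` with `inactive_candidates` filled in
#'   (sorted ids; always disjoint from `members`).
#' @export
detect_inactive_members <- function(calls, homology, max_evalue = 0.01) {
  stopifnot(inherits(calls, "family_call_set"))
  good <- homology[homology$e_value <= max_evalue, , drop = FALSE]
  to_member <- good$query_id[good$subject_id %in% calls$members]
  from_member <- good$subject_id[good$query_id %in% calls$members]
  candidates <- setdiff(unique(c(to_member, from_member)), calls$members)
  calls$inactive_candidates <- sort(candidates)
  calls
}

#' Write family calls as TSV
#'
#' One row per gene with status (`member` / `inactive_candidate`) and the
#' best supporting domain evidence for members.
#'
#' @param calls a `family_call_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_family_calls <- function(calls, path) {
  stopifnot(inherits(calls, "family_call_set"))
  ev <- calls$evidence
  i <- match(calls$members, ev$gene_id)
  df <- data.frame(gene_id = c(calls$members, calls$inactive_candidates),
                   status = c(rep("member", length(calls$members)),
                              rep("inactive_candidate",
                                  length(calls$inactive_candidates))),
                   domain_name = c(ev$domain_name[i],
                                   rep(NA, length(calls$inactive_candidates))),
                   e_value = c(ev$e_value[i],
                               rep(NA, length(calls$inactive_candidates))),
                   coverage = c(round(ev$coverage[i], 4),
                                rep(NA, length(calls$inactive_candidates))),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
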