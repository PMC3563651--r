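blast_columns <- c("query_id", "subject_id", "pct_identity", "aln_len",
                   "mismatches", "gap_opens", "q_start", "q_end",
                   "s_start", "s_end", "e_value", "bit_score")

#' Read BLAST tabular (outfmt 6) homology hits
#'
#' Reads the standard 12-column tab-separated BLAST output. Rows above the
#' e-value threshold and self-hits (query equal to subject) are dropped;
#' the numbers dropped are recorded in the `"validation"` attribute.
#'
#' @param path path to a 12-column tab-separated file.
#' @param max_evalue retain rows with `e_value <= max_evalue`. The
#'   all-vs-all protein comparisons feeding synteny detection use 0.01.
#' @return A data frame with the 12 standard columns.
#' @export
read_blast_tab <- function(path, max_evalue = 0.01) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[lines != ""]
  if (length(lines) == 0L) {
    tab <- empty_homology_table()
    attr(tab, "validation") <- list(n_dropped_evalue = 0L, n_dropped_self = 0L)
    return(tab)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    stop(sprintf("BLAST tabular parse error at line %d: expected 12 columns, got %d",
                 bad, nf[bad]), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  tab <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                    pct_identity = as.numeric(m[, 3]),
                    aln_len = as.integer(m[, 4]),
                    mismatches = as.integer(m[, 5]),
                    gap_opens = as.integer(m[, 6]),
                    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
                    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
                    e_value = as.numeric(m[, 11]),
                    bit_score = as.numeric(m[, 12]),
                    stringsAsFactors = FALSE)
  if (anyNA(tab$e_value)) {
    bad <- which(is.na(tab$e_value))[1]
    stop(sprintf("BLAST tabular parse error at line %d: unparseable e-value", bad),
         call. = FALSE)
  }
  is_self <- tab$query_id == tab$subject_id
  too_weak <- tab$e_value > max_evalue
  kept <- tab[!is_self & !too_weak, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "validation") <- list(n_dropped_evalue = sum(too_weak & !is_self),
                                   n_dropped_self = sum(is_self))
  kept
}

empty_homology_table <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), aln_len = integer(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             e_value = numeric(), bit_score = numeric(),
             stringsAsFactors = FALSE)
}

#' Write homology hits as BLAST tabular (outfmt 6)
#'
#' @param hits homology hit data frame (12 standard columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  stopifnot(all(blast_columns %in% names(hits)))
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.1f",
                   hits$query_id, hits$subject_id, hits$pct_identity,
                   hits$aln_len, hits$mismatches, hits$gap_opens,
                   hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                   hits$e_value, hits$bit_score)
  writeLines(lines, path)
  invisible(path)
}

#' Read HMMER per-domain hits (domtblout)
#'
#' Parses the whitespace-delimited HMMER3 `--domtblout` layout (`#`
#' comment lines ignored) into the columns the family filter consumes:
#' gene id, domain name, the domain's independent e-value, the aligned
#' HMM span and the model length. A plain 6-column tab-separated dialect
#' with exactly those columns is accepted as well.
#'
#' @param path path to a domtblout file or the 6-column TSV dialect.
#' @return Data frame with columns `gene_id`, `domain_name`, `e_value`,
#'   `hmm_from`, `hmm_to`, `model_length`.
#' @export
read_domtblout <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !(lines == "" | startsWith(lines, "#"))
  rows <- vector("list", sum(keep))
  k <- 0L
  for (i in which(keep)) {
    fields <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(fields) >= 23L) {
      # full HMMER3 domtblout: target name [1], query (domain) name [4],
      # qlen [6], i-Evalue [13], hmm_from [16], hmm_to [17]
      row <- list(gene_id = fields[1], domain_name = fields[4],
                  e_value = fields[13], hmm_from = fields[16],
                  hmm_to = fields[17], model_length = fields[6])
    } else if (length(fields) == 6L) {
      row <- list(gene_id = fields[1], domain_name = fields[2],
                  e_value = fields[3], hmm_from = fields[4],
                  hmm_to = fields[5], model_length = fields[6])
    } else {
      stop(sprintf("domtblout parse error at line %d: %d fields (expected >= 23 or exactly 6)",
                   i, length(fields)), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(row$e_value))
    from <- suppressWarnings(as.integer(row$hmm_from))
    to <- suppressWarnings(as.integer(row$hmm_to))
    len <- suppressWarnings(as.integer(row$model_length))
    if (is.na(num) || is.na(from) || is.na(to) || is.na(len)) {
      stop(sprintf("domtblout parse error at line %d: unparseable numeric field", i),
           call. = FALSE)
    }
    k <- k + 1L
    rows[[k]] <- data.frame(gene_id = row$gene_id, domain_name = row$domain_name,
                            e_value = num, hmm_from = from, hmm_to = to,
                            model_length = len, stringsAsFactors = FALSE)
  }
  tab <- if (k == 0L) {
    data.frame(gene_id = character(), domain_name = character(),
               e_value = numeric(), hmm_from = integer(), hmm_to = integer(),
               model_length = integer(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows[seq_len(k)])
  }
  validate_domain_hits(tab)
  tab
}

validate_domain_hits <- function(hits) {
  bad <- hits$hmm_from < 1L | hits$hmm_from > hits$hmm_to |
    hits$hmm_to > hits$model_length | hits$e_value < 0
  if (any(bad)) {
    stop("invalid domain hit(s) for gene(s): ",
         paste(utils::head(unique(hits$gene_id[bad]), 5), collapse = ", "),
         " (need 1 <= hmm_from <= hmm_to <= model_length and e_value >= 0)",
         call. = FALSE)
  }
  invisible(hits)
}

#' Write domain hits in the 6-column TSV dialect read by [read_domtblout()]
#'
#' @param hits domain hit data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  lines <- c("# gene_id\tdomain_name\te_value\thmm_from\thmm_to\tmodel_length",
             sprintf("%s\t%s\t%.4g\t%d\t%d\t%d",
                     hits$gene_id, hits$domain_name, hits$e_value,
                     hits$hmm_from, hits$hmm_to, hits$model_length))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Genes in rows, tissues in columns; first column holds gene ids, header
#' row holds tissue names.
#'
#' @param path path to a TSV file.
#' @param standardized whether the stored values are already z-scores.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, standardized = FALSE) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  expression_matrix(values, standardized = standardized)
}

#' Write an expression matrix as TSV
#'
#' @param matrix an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), unclass(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
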