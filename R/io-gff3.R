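#' Read gene features from a GFF3 file
#'
#' Reads `gene` features (only) from a GFF3 file into a
#' [genome_annotation()]. Coordinates are kept 1-based inclusive. Features
#' of other types are ignored; `gene` features lacking usable coordinates
#' (`.` in the start/end columns) or lacking an `ID=` attribute are
#' dropped and counted, mirroring the analysis rule that genes with
#' unknown genomic loci are excluded rather than guessed at.
#'
#' @param path path to a GFF3 file.
#' @return A [genome_annotation()]. The attribute `"validation"` is a list
#'   with `n_dropped_no_coords` and `n_dropped_no_id` counts.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  n_no_coords <- 0L
  n_no_id <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (line == "" || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9L) {
      stop(sprintf("GFF3 parse error at line %d: expected 9 tab-separated fields, got %d",
                   i, length(fields)), call. = FALSE)
    }
    if (fields[3] != "gene") next
    if (fields[4] == "." || fields[5] == ".") {
      n_no_coords <- n_no_coords + 1L
      next
    }
    start <- suppressWarnings(as.integer(fields[4]))
    end <- suppressWarnings(as.integer(fields[5]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("GFF3 parse error at line %d: non-numeric coordinates '%s'..'%s'",
                   i, fields[4], fields[5]), call. = FALSE)
    }
    id <- gff3_attribute(fields[9], "ID")
    if (is.na(id)) {
      n_no_id <- n_no_id + 1L
      next
    }
    strand <- if (fields[7] %in% c("+", "-")) fields[7] else "+"
    rows[[i]] <- data.frame(gene_id = id, chrom = fields[1],
                            start = start, end = end, strand = strand,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  genes <- if (length(rows) == 0L) {
    data.frame(gene_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  ann <- genome_annotation(genes)
  attr(ann, "validation") <- list(n_dropped_no_coords = n_no_coords,
                                  n_dropped_no_id = n_no_id)
  if (n_no_coords + n_no_id > 0L) {
    message(sprintf("read_gff3: dropped %d feature(s) without coordinates and %d without ID",
                    n_no_coords, n_no_id))
  }
  ann
}

gff3_attribute <- function(attrs, key) {
  parts <- strsplit(attrs, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  hit <- grep(paste0("^", key, "="), parts, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  sub(paste0("^", key, "="), "", hit[[1]])
}

#' Write a genome annotation as GFF3
#'
#' Writes gene features only, 1-based inclusive coordinates, with an
#' `ID=` attribute. Inverse of [read_gff3()] on valid records.
#'
#' @param annotation a [genome_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  lines <- c("##gff-version 3",
             sprintf("%s\tsyndup\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     annotation$chrom, annotation$start, annotation$end,
                     annotation$strand, annotation$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Write tandem arrays as BED
#'
#' BED is 0-based half-open; the inclusive 1-based gene coordinates of the
#' first and last array member become `start-1` and `end`.
#'
#' @param arrays list of tandem arrays from [detect_tandem_arrays()].
#' @param annotation the [genome_annotation()] the arrays were called on.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_arrays_bed <- function(arrays, annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (length(arrays) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  idx <- match(unlist(lapply(arrays, `[[`, "genes")), annotation$gene_id)
  if (anyNA(idx)) stop("array gene absent from annotation", call. = FALSE)
  lines <- vapply(seq_along(arrays), function(i) {
    a <- arrays[[i]]
    j <- match(a$genes, annotation$gene_id)
    sprintf("%s\t%d\t%d\tarray_%d\t%d\t.",
            a$chrom, min(annotation$start[j]) - 1L, max(annotation$end[j]),
            i, length(a$genes))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
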