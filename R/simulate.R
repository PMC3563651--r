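#' Simulate an ancestral genome annotation
#'
#' Generates a multi-chromosome gene order with non-overlapping 1-based
#' coordinates, random strands, and a labelled gene family scattered over
#' the genome. Gene lengths and intergenic gaps are drawn uniformly from
#' fixed ranges; nothing downstream depends on base-pair geometry beyond
#' order, so these are deliberately simple.
#'
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param genes_per_chromosome genes on each chromosome (>= 1).
#' @param family_fraction fraction of genes carrying the family label;
#'   exactly `floor(family_fraction * total)` genes are labelled.
#' @param seed integer seed; all simulator functions are deterministic
#'   under a fixed seed and restore the caller's RNG state.
#' @param gene_length_range,intergenic_range uniform sampling bounds (bp).
#' @return A [genome_annotation()] with a logical `family` column.
#' @export
simulate_ancestor <- function(n_chromosomes, genes_per_chromosome,
                              family_fraction, seed,
                              gene_length_range = c(500L, 5000L),
                              intergenic_range = c(200L, 2000L)) {
  stopifnot(n_chromosomes >= 1L, genes_per_chromosome >= 1L)
  check_proportion(family_fraction, "family_fraction")
  with_seed(seed, {
    total <- n_chromosomes * genes_per_chromosome
    rows <- vector("list", n_chromosomes)
    g <- 0L
    for (c in seq_len(n_chromosomes)) {
      lens <- sample(gene_length_range[1]:gene_length_range[2],
                     genes_per_chromosome, replace = TRUE)
      gaps <- sample(intergenic_range[1]:intergenic_range[2],
                     genes_per_chromosome, replace = TRUE)
      starts <- cumsum(gaps) + c(0L, cumsum(lens[-genes_per_chromosome]))
      ids <- sprintf("g%02d_%04d", c, g + seq_len(genes_per_chromosome))
      g <- g + genes_per_chromosome
      rows[[c]] <- data.frame(gene_id = ids,
                              chrom = sprintf("chr%02d", c),
                              start = as.integer(starts),
                              end = as.integer(starts + lens - 1L),
                              strand = sample(c("+", "-"),
                                              genes_per_chromosome, replace = TRUE),
                              stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, rows)
    n_family <- floor(family_fraction * total)
    genes$family <- FALSE
    if (n_family > 0L) {
      genes$family[sample.int(total, n_family)] <- TRUE
    }
    genome_annotation(genes)
  })
}

#' Apply a whole-genome duplication with stochastic gene loss
#'
#' Every chromosome is duplicated as a new chromosome (suffix `_d`); each
#' duplicated gene copy is independently retained with probability
#' `retention_rate`, emulating post-polyploidy fractionation (without a
#' bias between the two subgenomes). Original genes are always kept.
#'
#' @param genome a [genome_annotation()].
#' @param retention_rate per-gene copy survival probability in [0, 1].
#' @param seed integer seed.
#' @return A list with `genome` (the post-WGD annotation, ranks
#'   recomputed) and `paralog_map` (data frame `gene_a` original /
#'   `gene_b` retained copy).
#' @export
apply_wgd <- function(genome, retention_rate, seed) {
  stopifnot(inherits(genome, "genome_annotation"))
  check_proportion(retention_rate, "retention_rate")
  with_seed(seed, {
    copies <- as.data.frame(genome)
    keep <- stats::runif(nrow(copies)) < retention_rate
    copies <- copies[keep, , drop = FALSE]
    if (nrow(copies) > 0L) {
      paralog_map <- data.frame(gene_a = copies$gene_id,
                                gene_b = paste0(copies$gene_id, "_w"),
                                stringsAsFactors = FALSE)
      copies$gene_id <- paralog_map$gene_b
      copies$chrom <- paste0(copies$chrom, "_d")
    } else {
      paralog_map <- data.frame(gene_a = character(), gene_b = character(),
                                stringsAsFactors = FALSE)
    }
    copies$rank <- NULL
    orig <- as.data.frame(genome)
    orig$rank <- NULL
    out <- genome_annotation(rbind(orig, copies))
    list(genome = out, paralog_map = paralog_map)
  })
}

#' Apply local (tandem) duplication events
#'
#' Each event picks a source gene — a family gene when `family_only` —
#' and inserts `k - 1` adjacent copies immediately downstream of it,
#' where `k` is drawn from `array_size_sampler`. Coordinates of
#' downstream genes are shifted; copies inherit the source's length,
#' strand and family label. Source genes are chosen with at least two
#' intervening genes between sources on a chromosome, so distinct events
#' never produce abutting arrays and the returned ground truth is
#' recoverable as-is by [detect_tandem_arrays()].
#'
#' @param genome a [genome_annotation()].
#' @param n_events number of duplication events (>= 0).
#' @param array_size_sampler function(n) returning n integers >= 2 (total
#'   array sizes); default samples uniformly from 2:4.
#' @param family_only restrict sources to family-labelled genes.
#' @param seed integer seed.
#' @return List with `genome` (annotation with copies inserted) and
#'   `arrays` (list of character vectors, each the ground-truth array in
#'   rank order, source first).
#' @export
apply_tandem_duplications <- function(genome, n_events,
                                      array_size_sampler = function(n)
                                        sample(2:4, n, replace = TRUE),
                                      family_only = TRUE, seed) {
  stopifnot(inherits(genome, "genome_annotation"), n_events >= 0L)
  if (n_events == 0L) {
    return(list(genome = genome, arrays = list()))
  }
  with_seed(seed, {
    df <- as.data.frame(genome)
    candidates <- if (family_only && "family" %in% names(df)) {
      which(df$family)
    } else {
      seq_len(nrow(df))
    }
    # greedy spaced selection: no two sources within 2 ranks on a chromosome
    pool <- sample(candidates)
    chosen <- integer(0)
    for (i in pool) {
      ok <- !any(df$chrom[chosen] == df$chrom[i] &
                   abs(df$rank[chosen] - df$rank[i]) <= 2L)
      if (ok) chosen <- c(chosen, i)
      if (length(chosen) == n_events) break
    }
    if (length(chosen) < n_events) {
      stop(sprintf("n_events = %d exceeds the %d adequately spaced source gene(s) available",
                   n_events, length(chosen)), call. = FALSE)
    }
    sizes <- array_size_sampler(n_events)
    if (any(sizes < 2L)) stop("array_size_sampler must return sizes >= 2", call. = FALSE)

    copy_gap <- 150L
    arrays <- vector("list", n_events)
    names(sizes) <- df$gene_id[chosen]
    has_family <- "family" %in% names(df)

    # rebuild each affected chromosome: splice copies into the rank order,
    # then lay coordinates out again, preserving original gene lengths and
    # each original gene's preceding intergenic gap
    out_rows <- list()
    for (cc in unique(df$chrom)) {
      cdf <- df[df$chrom == cc, , drop = FALSE]
      cdf <- cdf[order(cdf$rank), , drop = FALSE]
      prev_end <- c(0L, cdf$end[-nrow(cdf)])
      cdf$pre_gap <- cdf$start - prev_end  # gap before each gene (>= 1)
      pieces <- vector("list", nrow(cdf))
      for (i in seq_len(nrow(cdf))) {
        row <- cdf[i, , drop = FALSE]
        pieces[[i]] <- row
        gid <- row$gene_id
        if (!is.na(sizes[gid])) {
          k <- sizes[[gid]]
          cp_ids <- sprintf("%s_t%d", gid, seq_len(k - 1L))
          cp <- row[rep(1L, k - 1L), , drop = FALSE]
          cp$gene_id <- cp_ids
          cp$pre_gap <- copy_gap
          pieces[[i]] <- rbind(row, cp)
          arrays[[match(gid, names(sizes))]] <- c(gid, cp_ids)
        }
      }
      new_c <- do.call(rbind, pieces)
      lens <- new_c$end - new_c$start + 1L
      starts <- cumsum(new_c$pre_gap) + c(0L, cumsum(lens[-nrow(new_c)]))
      new_c$start <- as.integer(starts)
      new_c$end <- as.integer(starts + lens - 1L)
      new_c$pre_gap <- NULL
      out_rows[[cc]] <- new_c
    }
    out <- do.call(rbind, out_rows)
    out$rank <- NULL
    if (!has_family) out$family <- NULL
    list(genome = genome_annotation(out), arrays = arrays)
  })
}

#' Simulate a genome pair with a known duplication history
#'
#' Builds an ancestral genome, derives two descendant genomes from it
#' (gene-for-gene orthologs, with optional ortholog loss in genome B),
#' then applies a whole-genome duplication to genome A and tandem
#' duplication events to either genome. The returned object carries the
#' complete ground truth every detection stage is tested against.
#'
#' @param n_chromosomes,genes_per_chromosome,family_fraction ancestor
#'   parameters, see [simulate_ancestor()].
#' @param wgd_retention retention rate of the WGD applied to genome A;
#'   `NA` skips the WGD.
#' @param n_tandem_a,n_tandem_b tandem duplication events per genome.
#' @param ortholog_retention_b probability that an ancestral gene keeps
#'   its ortholog in genome B (1 = perfectly conserved gene content).
#' @param seed integer seed (sub-seeds for each event are derived from it).
#' @return A `simulated_genome_pair`: list with `genome_a`, `genome_b`,
#'   `true_orthologs` (data frame gene_a/gene_b), `true_tandem_arrays`
#'   (list with `a` and `b`, each a list of id vectors),
#'   `true_segmental_pairs` (data frame, genome A), `true_family_members`
#'   (list `a`, `b`), and `event_log`.
#' @export
simulate_genome_pair <- function(n_chromosomes = 3L, genes_per_chromosome = 100L,
                                 family_fraction = 0.1, wgd_retention = 0.6,
                                 n_tandem_a = 0L, n_tandem_b = 0L,
                                 ortholog_retention_b = 1.0, seed = 1L) {
  check_proportion(ortholog_retention_b, "ortholog_retention_b")
  anc <- simulate_ancestor(n_chromosomes, genes_per_chromosome,
                           family_fraction, seed = seed)
  event_log <- list(list(event = "ancestor",
                         params = list(n_chromosomes = n_chromosomes,
                                       genes_per_chromosome = genes_per_chromosome,
                                       family_fraction = family_fraction)))

  a_df <- as.data.frame(anc); a_df$rank <- NULL
  a_df$gene_id <- paste0("a_", a_df$gene_id)
  b_df <- as.data.frame(anc); b_df$rank <- NULL
  b_df$gene_id <- paste0("b_", b_df$gene_id)
  orthologs <- data.frame(gene_a = a_df$gene_id, gene_b = b_df$gene_id,
                          stringsAsFactors = FALSE)
  if (ortholog_retention_b < 1) {
    keep <- with_seed(seed + 101L, stats::runif(nrow(b_df)) < ortholog_retention_b)
    b_df <- b_df[keep, , drop = FALSE]
    orthologs <- orthologs[keep, , drop = FALSE]
    event_log <- c(event_log, list(list(event = "ortholog_loss_b",
                                        params = list(retention = ortholog_retention_b))))
  }
  genome_a <- genome_annotation(a_df)
  genome_b <- genome_annotation(b_df)

  segmental <- data.frame(gene_a = character(), gene_b = character(),
                          stringsAsFactors = FALSE)
  if (!is.na(wgd_retention)) {
    wgd <- apply_wgd(genome_a, wgd_retention, seed = seed + 202L)
    genome_a <- wgd$genome
    segmental <- wgd$paralog_map
    # retained WGD copies in A are also orthologous to the B counterpart
    extra <- merge(orthologs, segmental, by = "gene_a")
    if (nrow(extra) > 0L) {
      orthologs <- rbind(orthologs,
                         data.frame(gene_a = extra$gene_b.y,
                                    gene_b = extra$gene_b.x,
                                    stringsAsFactors = FALSE))
    }
    event_log <- c(event_log, list(list(event = "wgd_a",
                                        params = list(retention = wgd_retention))))
  }

  arrays_a <- list(); arrays_b <- list()
  if (n_tandem_a > 0L) {
    td <- apply_tandem_duplications(genome_a, n_tandem_a, seed = seed + 303L)
    genome_a <- td$genome
    arrays_a <- td$arrays
    event_log <- c(event_log, list(list(event = "tandem_a",
                                        params = list(n_events = n_tandem_a))))
  }
  if (n_tandem_b > 0L) {
    td <- apply_tandem_duplications(genome_b, n_tandem_b, seed = seed + 404L)
    genome_b <- td$genome
    arrays_b <- td$arrays
    event_log <- c(event_log, list(list(event = "tandem_b",
                                        params = list(n_events = n_tandem_b))))
  }

  out <- list(genome_a = genome_a, genome_b = genome_b,
              true_orthologs = orthologs,
              true_tandem_arrays = list(a = arrays_a, b = arrays_b),
              true_segmental_pairs = segmental,
              true_family_members = list(a = family_members(genome_a),
                                         b = family_members(genome_b)),
              event_log = event_log)
  class(out) <- "simulated_genome_pair"
  out
}

#' @export
print.simulated_genome_pair <- function(x, ...) {
  cat(sprintf(paste0("simulated_genome_pair: %d + %d genes; %d ortholog pairs; ",
                     "%d segmental pairs; %d/%d tandem arrays (A/B)\n"),
              nrow(x$genome_a), nrow(x$genome_b), nrow(x$true_orthologs),
              nrow(x$true_segmental_pairs),
              length(x$true_tandem_arrays$a), length(x$true_tandem_arrays$b)))
  invisible(x)
}

#' Emit a domain-hit table for a simulated genome
#'
#' Family genes receive a clan-domain hit passing the family filter
#' (e-value below the threshold, model coverage at least one half) with
#' probability `true_positive_rate`. Non-family genes receive, with
#' probability `decoy_rate`, a decoy hit that fails exactly one of the two
#' criteria — either the e-value is too large or the aligned model span is
#' too short — so both branches of the filter are exercised.
#'
#' @param genome a simulated [genome_annotation()] with a `family` column.
#' @param true_positive_rate,decoy_rate probabilities in [0, 1].
#' @param model_length length of the domain model in match states
#'   (default 48, typical of the F-box domain).
#' @param seed integer seed.
#' @param clan_domains domain names to sample hit labels from.
#' @return Domain-hit data frame (`gene_id`, `domain_name`, `e_value`,
#'   `hmm_from`, `hmm_to`, `model_length`).
#' @export
emit_domain_hits <- function(genome, true_positive_rate = 1.0, decoy_rate = 0.0,
                             model_length = 48L, seed = 1L,
                             clan_domains = c("F-box", "F-box-like", "F-box-like_2")) {
  stopifnot(inherits(genome, "genome_annotation"))
  check_proportion(true_positive_rate, "true_positive_rate")
  check_proportion(decoy_rate, "decoy_rate")
  fam <- family_members(genome)
  nonfam <- setdiff(genome$gene_id, fam)
  with_seed(seed, {
    rows <- list()
    hit_fam <- fam[stats::runif(length(fam)) < true_positive_rate]
    if (length(hit_fam) > 0L) {
      cov <- stats::runif(length(hit_fam), 0.5, 1.0)
      span <- pmin(model_length, ceiling(cov * model_length))
      from <- vapply(span, function(s) sample.int(model_length - s + 1L, 1L), integer(1))
      rows$true <- data.frame(gene_id = hit_fam,
                              domain_name = sample(clan_domains, length(hit_fam),
                                                   replace = TRUE),
                              e_value = 10^stats::runif(length(hit_fam), -30, -1),
                              hmm_from = from, hmm_to = from + span - 1L,
                              model_length = model_length,
                              stringsAsFactors = FALSE)
    }
    decoys <- nonfam[stats::runif(length(nonfam)) < decoy_rate]
    if (length(decoys) > 0L) {
      fail_evalue <- stats::runif(length(decoys)) < 0.5
      e <- ifelse(fail_evalue,
                  10^stats::runif(length(decoys), 0.05, 1),   # e in (1.1, 10]
                  10^stats::runif(length(decoys), -10, -1))   # passes e-value
      covs <- ifelse(fail_evalue,
                     stats::runif(length(decoys), 0.6, 1.0),  # passes coverage
                     stats::runif(length(decoys), 0.1, 0.45)) # too short
      span <- pmax(1L, pmin(model_length, floor(covs * model_length)))
      # a floor()ed span must stay strictly below half the model
      span <- ifelse(!fail_evalue, pmin(span, ceiling(model_length / 2) - 1L), span)
      from <- vapply(span, function(s) sample.int(model_length - s + 1L, 1L), integer(1))
      rows$decoy <- data.frame(gene_id = decoys,
                               domain_name = sample(clan_domains, length(decoys),
                                                    replace = TRUE),
                               e_value = e,
                               hmm_from = from, hmm_to = from + span - 1L,
                               model_length = model_length,
                               stringsAsFactors = FALSE)
    }
    tab <- if (length(rows) == 0L) {
      data.frame(gene_id = character(), domain_name = character(),
                 e_value = numeric(), hmm_from = integer(), hmm_to = integer(),
                 model_length = integer(), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, rows)
    }
    rownames(tab) <- NULL
    tab
  })
}

#' Emit an all-vs-all homology table for a simulated genome pair
#'
#' Every ground-truth gene pair — orthologs across the genomes, segmental
#' (WGD) paralogs, and all within-array tandem pairs — yields a reciprocal
#' pair of hits with e-values well below the 0.01 anchor threshold.
#' Spurious hits between uniformly random gene pairs are added at
#' `spurious_rate` (relative to the number of true pairs), with e-values
#' straddling the threshold so the filter is exercised on both sides.
#'
#' @param pair a [simulate_genome_pair()] result.
#' @param spurious_rate spurious pairs per true pair, in [0, 1].
#' @param seed integer seed.
#' @return Homology-hit data frame in BLAST outfmt-6 column layout.
#' @export
emit_homology_hits <- function(pair, spurious_rate = 0.0, seed = 1L) {
  stopifnot(inherits(pair, "simulated_genome_pair"))
  check_proportion(spurious_rate, "spurious_rate")
  within_array_pairs <- function(arrays) {
    do.call(rbind, c(list(data.frame(gene_a = character(), gene_b = character(),
                                     stringsAsFactors = FALSE)),
                     lapply(arrays, function(g) {
                       if (length(g) < 2L) return(NULL)
                       cmb <- utils::combn(g, 2L)
                       data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                                  stringsAsFactors = FALSE)
                     })))
  }
  true_pairs <- rbind(pair$true_orthologs,
                      pair$true_segmental_pairs,
                      within_array_pairs(pair$true_tandem_arrays$a),
                      within_array_pairs(pair$true_tandem_arrays$b))
  true_pairs <- unique(true_pairs)
  all_ids <- c(pair$genome_a$gene_id, pair$genome_b$gene_id)
  with_seed(seed, {
    n_true <- nrow(true_pairs)
    e_true <- 10^stats::runif(n_true, -50, -3)
    fwd <- homology_rows(true_pairs$gene_a, true_pairs$gene_b, e_true)
    rev <- homology_rows(true_pairs$gene_b, true_pairs$gene_a, e_true)
    tab <- rbind(fwd, rev)
    n_spur <- floor(spurious_rate * n_true)
    if (n_spur > 0L) {
      qa <- sample(all_ids, n_spur, replace = TRUE)
      sa <- sample(all_ids, n_spur, replace = TRUE)
      ok <- qa != sa
      # e-values straddle 0.01: half pass the anchor filter, half fail
      e_spur <- ifelse(stats::runif(n_spur) < 0.5,
                       10^stats::runif(n_spur, -3, log10(0.01)),
                       10^stats::runif(n_spur, log10(0.011), 0))
      tab <- rbind(tab, homology_rows(qa[ok], sa[ok], e_spur[ok]))
    }
    rownames(tab) <- NULL
    tab
  })
}

# fill the non-essential outfmt-6 columns with plausible values derived
# from the e-value, so written tables survive a read round trip
homology_rows <- function(query, subject, e_value) {
  n <- length(query)
  aln <- as.integer(180 + round(-log10(pmax(e_value, 1e-50))))
  data.frame(query_id = query, subject_id = subject,
             pct_identity = round(55 + pmin(40, -log10(pmax(e_value, 1e-50))), 2),
             aln_len = aln, mismatches = as.integer(round(aln * 0.2)),
             gap_opens = 1L, q_start = 1L, q_end = aln,
             s_start = 1L, s_end = aln,
             e_value = e_value,
             bit_score = round(30 + 2 * -log10(pmax(e_value, 1e-50)), 1),
             stringsAsFactors = FALSE)
}

#' Simulate a gene-by-tissue expression matrix with planted clusters
#'
#' Each gene assigned to a cluster is elevated by `effect_size` in that
#' cluster's preferred tissue on top of a flat baseline, with Gaussian
#' noise everywhere; values are floored at zero. Unassigned genes are
#' baseline plus noise in every tissue.
#'
#' @param genes character vector of gene ids (rows).
#' @param tissues character vector of tissue names (columns).
#' @param cluster_assignments named character vector, gene id -> cluster
#'   label; genes absent from it carry no signal.
#' @param cluster_tissues named character vector, cluster label ->
#'   preferred tissue; every tissue named here must be in `tissues`.
#' @param effect_size expression increment in the preferred tissue.
#' @param noise_sd Gaussian noise standard deviation.
#' @param baseline flat expression level added everywhere.
#' @param seed integer seed.
#' @return A raw [expression_matrix()].
#' @export
simulate_expression <- function(genes, tissues, cluster_assignments,
                                cluster_tissues, effect_size, noise_sd,
                                baseline = 20, seed = 1L) {
  stopifnot(effect_size >= 0, noise_sd >= 0, baseline >= 0)
  if (length(cluster_assignments) > 0L) {
    if (is.null(names(cluster_assignments)) ||
        !all(names(cluster_assignments) %in% genes)) {
      stop("cluster_assignments must be named by gene ids present in `genes`",
           call. = FALSE)
    }
    clusters <- unique(unname(cluster_assignments))
    if (!all(clusters %in% names(cluster_tissues))) {
      stop("every cluster needs a preferred tissue in cluster_tissues", call. = FALSE)
    }
    if (!all(cluster_tissues[clusters] %in% tissues)) {
      bad <- setdiff(cluster_tissues[clusters], tissues)
      stop("unknown tissue(s) in cluster map: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  with_seed(seed, {
    values <- matrix(stats::rnorm(length(genes) * length(tissues),
                                  mean = baseline, sd = noise_sd),
                     nrow = length(genes), ncol = length(tissues),
                     dimnames = list(genes, tissues))
    for (g in names(cluster_assignments)) {
      tis <- cluster_tissues[[cluster_assignments[[g]]]]
      values[g, tis] <- values[g, tis] + effect_size
    }
    values[values < 0] <- 0
    expression_matrix(values, standardized = FALSE)
  })
}

#' Write the ground truth of a simulated pair as a JSON sidecar
#'
#' @param pair a [simulate_genome_pair()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(pair, path) {
  stopifnot(inherits(pair, "simulated_genome_pair"))
  jsonlite::write_json(
    list(true_orthologs = pair$true_orthologs,
         true_tandem_arrays = pair$true_tandem_arrays,
         true_segmental_pairs = pair$true_segmental_pairs,
         true_family_members = pair$true_family_members,
         event_log = pair$event_log),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
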