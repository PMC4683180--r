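# Seeded generators for every input the pipeline consumes, each returning
# its dataset together with a ground-truth manifest that fully determines
# the expected pipeline output. Backgrounds are scrubbed of accidental
# motifs so planted counts are exact rather than lower bounds — a
# deliberate unrealism that buys exact parameter-recovery tests.

# One global seed fans out to fixed per-stream sub-seeds so adding a
# generator call does not perturb earlier streams.
.derive_seed <- function(seed, stream) {
  offset <- c(proteome = 1L, contigs = 2L, counts = 3L, alignments = 4L)
  (as.integer(seed) %% 1000003L) * 2011L + offset[[stream]] * 101L
}

# Replace the start residue of every motif hit with G (which can satisfy no
# anchor position of any default pattern) until the sequence is motif-free.
.scrub_motifs <- function(res, patterns) {
  repeat {
    hits <- scan_motifs(list(locus_id = "bg",
                             sequence = paste(res, collapse = "")),
                        patterns)
    if (!nrow(hits)) return(res)
    res[unique(hits$start)] <- "G"
  }
}

.motif_instance <- function(name) {
  switch(name,
         CXXCH = "CAACH", CXXCK = "CAACK", CXXXCH = "CAAACH",
         CXXXXCH = "CAAAACH", HEMATITE = "SFSPS",
         stop("unknown motif class: ", name))
}

#' Generate a synthetic proteome with planted motif occurrences
#'
#' Background residues are drawn uniformly from the 20 standard amino acids
#' and scrubbed of accidental motif windows; the requested motif instances
#' are then planted at non-overlapping random positions and the assembly is
#' re-scanned, so the realized per-class counts equal the planted counts
#' exactly.
#'
#' @param n_proteins Number of proteins.
#' @param motif_counts Either a numeric vector of per-protein CXXCH counts
#'   (length `n_proteins`), or a named list of such vectors per motif class
#'   (`CXXCH`, `CXXCK`, `CXXXCH`, `CXXXXCH`, `HEMATITE`). `NULL` plants
#'   nothing.
#' @param protein_length Background length of each protein in residues.
#' @param seed Integer seed; identical seed and parameters give identical
#'   output.
#' @return List with `proteome` (data.frame as from
#'   [read_protein_fasta()]) and `truth` (data.frame of planted per-class
#'   counts per locus) plus `seed`.
#' @export
generate_proteome <- function(n_proteins, motif_counts = NULL,
                              protein_length = 300L, seed = 1L) {
  patterns <- default_motif_patterns()
  counts <- list(CXXCH = rep(0L, n_proteins), CXXCK = rep(0L, n_proteins),
                 CXXXCH = rep(0L, n_proteins),
                 CXXXXCH = rep(0L, n_proteins),
                 HEMATITE = rep(0L, n_proteins))
  if (!is.null(motif_counts)) {
    if (!is.list(motif_counts)) motif_counts <- list(CXXCH = motif_counts)
    for (nm in names(motif_counts)) {
      stopifnot(nm %in% names(counts),
                length(motif_counts[[nm]]) == n_proteins)
      counts[[nm]] <- as.integer(motif_counts[[nm]])
    }
  }
  set.seed(.derive_seed(seed, "proteome"))
  seqs <- character(n_proteins)
  for (i in seq_len(n_proteins)) {
    planted <- vapply(names(counts), function(nm) counts[[nm]][i],
                      integer(1))
    inst <- unlist(mapply(function(nm, k) rep(nm, k), names(planted),
                          planted, SIMPLIFY = FALSE), use.names = FALSE)
    w <- vapply(inst, function(nm) nchar(.motif_instance(nm)), integer(1))
    k <- length(inst)
    # instances are separated by >= 6 scrubbed background residues so no
    # scan window (max 7 residues) can span two planted instances
    min_gap <- 6L
    slack <- protein_length - sum(w) - if (k > 1L) min_gap * (k - 1L) else 0L
    if (slack < 0L) {
      stop("protein ", i, " too short (", protein_length,
           " aa) to host ", k, " planted motifs")
    }
    ok <- FALSE
    for (attempt in 1:100) {
      inst_i <- sample(inst)
      extra <- if (slack > 0L) {
        stats::rmultinom(1, slack, rep(1, k + 1L))[, 1]
      } else rep(0L, k + 1L)
      gaps <- extra + c(0L, rep(min_gap, max(k - 1L, 0L)), 0L)[
        seq_len(k + 1L)]
      pieces <- character(2L * k + 1L)
      for (j in seq_len(k + 1L)) {
        bg <- if (gaps[j] > 0L) {
          paste(.scrub_motifs(sample(.AA_STANDARD, gaps[j], replace = TRUE),
                              patterns), collapse = "")
        } else ""
        pieces[2L * j - 1L] <- bg
        if (j <= k) pieces[2L * j] <- .motif_instance(inst_i[j])
      }
      seq <- paste(pieces, collapse = "")
      hits <- scan_motifs(list(locus_id = "p", sequence = seq), patterns)
      realized <- vapply(names(counts),
                         function(nm) sum(hits$motif_name == nm),
                         integer(1))
      if (identical(unname(realized), unname(planted))) {
        seqs[i] <- seq; ok <- TRUE; break
      }
    }
    if (!ok) stop("could not realize planted motif counts for protein ", i)
  }
  ids <- sprintf("SYN_%04d", seq_len(n_proteins))
  list(proteome = data.frame(locus_id = ids, description = "synthetic",
                             sequence = seqs, stringsAsFactors = FALSE),
       truth = data.frame(locus_id = ids,
                          n_cxxch = counts$CXXCH, n_cxxck = counts$CXXCK,
                          n_cxxxch = counts$CXXXCH,
                          n_cxxxxch = counts$CXXXXCH,
                          n_hematite = counts$HEMATITE,
                          stringsAsFactors = FALSE),
       seed = seed)
}

#' Default synthetic contig cluster parameters
#'
#' Two well-separated (GC, coverage) clusters emulating a dominant
#' high-coverage genome at 43% GC, 100x against a second community member
#' at 60% GC, 30x.
#'
#' @return data.frame of per-cluster parameters.
#' @export
default_contig_clusters <- function() {
  data.frame(gc_mean = c(0.43, 0.60), gc_sd = c(0.01, 0.01),
             cov_mean = c(100, 30), cov_sd = c(5, 3),
             len_min = c(500L, 500L), len_max = c(2000L, 2000L))
}

#' Generate synthetic contigs in (GC, coverage) clusters
#'
#' Per-contig GC is realized by biased base sampling and resampled until
#' the realized GC is within 0.02 of the drawn target; the truth manifest
#' records both.
#'
#' @param n Total number of contigs (split evenly across clusters).
#' @param clusters Cluster parameter data.frame
#'   ([default_contig_clusters()]).
#' @param seed Integer seed.
#' @return List with `contigs` (data.frame `contig_id`, `sequence`,
#'   `coverage`) and `truth` (per-contig cluster id, target and realized
#'   GC, coverage, length) plus `seed`.
#' @export
generate_contigs <- function(n, clusters = default_contig_clusters(),
                             seed = 1L) {
  set.seed(.derive_seed(seed, "contigs"))
  if (n == 0L) {
    empty <- data.frame(contig_id = character(0), sequence = character(0),
                        coverage = numeric(0), stringsAsFactors = FALSE)
    return(list(contigs = empty,
                truth = data.frame(contig_id = character(0),
                                   cluster = integer(0)),
                seed = seed))
  }
  cl <- rep(seq_len(nrow(clusters)), length.out = n)
  rows <- lapply(seq_len(n), function(i) {
    p <- clusters[cl[i], ]
    target_gc <- min(0.95, max(0.05, stats::rnorm(1, p$gc_mean, p$gc_sd)))
    coverage <- max(0, stats::rnorm(1, p$cov_mean, p$cov_sd))
    len <- sample(p$len_min:p$len_max, 1L)
    probs <- c(A = (1 - target_gc) / 2, C = target_gc / 2,
               G = target_gc / 2, T = (1 - target_gc) / 2)
    for (try in 1:50) {
      s <- paste(sample(names(probs), len, replace = TRUE, prob = probs),
                 collapse = "")
      realized <- gc_content(s)
      if (abs(realized - target_gc) <= 0.02) break
    }
    list(seq = s, cov = coverage, target_gc = target_gc,
         realized_gc = realized, len = len)
  })
  ids <- sprintf("contig_%04d", seq_len(n))
  list(contigs = data.frame(contig_id = ids,
                            sequence = vapply(rows, `[[`, "", "seq"),
                            coverage = vapply(rows, `[[`, 0, "cov"),
                            stringsAsFactors = FALSE),
       truth = data.frame(contig_id = ids, cluster = cl,
                          target_gc = vapply(rows, `[[`, 0, "target_gc"),
                          realized_gc = vapply(rows, `[[`, 0, "realized_gc"),
                          coverage = vapply(rows, `[[`, 0, "cov"),
                          length = vapply(rows, `[[`, 0L, "len"),
                          stringsAsFactors = FALSE),
       seed = seed)
}

#' Generate a count table hitting target RPKM values
#'
#' Integer counts are chosen so the realized RPKM (with the table sum as
#' denominator) matches each target up to rounding. A filler gene absorbs
#' the remaining reads so the table sums exactly to `total_reads`, making
#' the realized values closed-form:
#' `1e9 * round(target * length * total / 1e9) / (length * total)`.
#'
#' @param gene_lengths Numeric vector of gene lengths (bp).
#' @param target_rpkm Numeric vector of target RPKM values, same length.
#' @param total_reads Total mapped reads of the table (including filler).
#' @param seed Integer seed (kept for interface uniformity; the
#'   construction is deterministic).
#' @return List with `counts` (data.frame `gene_id`, `gene_length`,
#'   `read_count`; last row is the filler gene) and `truth` (`gene_id`,
#'   `target_rpkm`, `realized_rpkm`; filler target is `NA`) plus `seed`.
#' @export
generate_counts <- function(gene_lengths, target_rpkm, total_reads = 1e6,
                            seed = 1L) {
  stopifnot(length(gene_lengths) == length(target_rpkm),
            all(gene_lengths >= 1), all(target_rpkm >= 0))
  set.seed(.derive_seed(seed, "counts"))
  counts <- round(target_rpkm * gene_lengths * total_reads / 1e9)
  filler <- total_reads - sum(counts)
  if (filler < 0) {
    stop("target RPKM values require more than total_reads reads")
  }
  ids <- c(sprintf("gene_%04d", seq_along(gene_lengths)), "gene_filler")
  lens <- c(gene_lengths, 1000)
  counts <- c(counts, filler)
  realized <- 1e9 * counts / (lens * total_reads)
  list(counts = data.frame(gene_id = ids, gene_length = lens,
                           read_count = as.integer(counts),
                           stringsAsFactors = FALSE),
       truth = data.frame(gene_id = ids,
                          target_rpkm = c(target_rpkm, NA_real_),
                          realized_rpkm = realized,
                          stringsAsFactors = FALSE),
       seed = seed)
}

#' Generate an alignment hit table with known pass/fail structure
#'
#' Exactly `round(pass_fraction * n_queries)` queries receive a hit sampled
#' strictly inside the profile's acceptance region; every other query's hit
#' violates one criterion (which one is recorded), with some violations
#' placed exactly on the boundary — boundary values fail because every
#' profile bound is strict.
#'
#' @param n_queries Number of queries (one hit each).
#' @param pass_fraction Fraction of queries whose hit passes.
#' @param profile A [threshold_profile()].
#' @param seed Integer seed.
#' @return List with `hits` (12-column data.frame as from
#'   [read_alignment_table()], plus `query_length`), `query_lengths`
#'   (data.frame) and `truth` (`query_id`, `pass`, `violated`) plus
#'   `seed`.
#' @export
generate_alignment_table <- function(n_queries, pass_fraction,
                                     profile = profile_genome_wide(),
                                     seed = 1L) {
  stopifnot(pass_fraction >= 0, pass_fraction <= 1)
  set.seed(.derive_seed(seed, "alignments"))
  k <- round(pass_fraction * n_queries)
  pass <- sample(c(rep(TRUE, k), rep(FALSE, n_queries - k)))
  needs_cov <- !is.null(profile$min_query_coverage)
  criteria <- c("evalue", "identity", if (needs_cov) "coverage")
  rows <- lapply(seq_len(n_queries), function(i) {
    qlen <- sample(150:400, 1L)
    # start from strictly-passing values
    evalue <- profile$max_evalue * 10^(-stats::runif(1, 0.5, 6))
    pid <- stats::runif(1, profile$min_identity + 1, 99.9)
    cov_floor <- if (needs_cov) profile$min_query_coverage else 30
    frac <- stats::runif(1, min(cov_floor + 1, 99) / 100, 1)
    aln <- min(qlen, ceiling(frac * qlen))
    violated <- NA_character_
    if (!pass[i]) {
      violated <- sample(criteria, 1L)
      boundary <- stats::runif(1) < 0.3
      if (violated == "evalue") {
        evalue <- if (boundary) profile$max_evalue else
          profile$max_evalue * 10^stats::runif(1, 0.5, 4)
      } else if (violated == "identity") {
        pid <- if (boundary) profile$min_identity else
          stats::runif(1, 1, profile$min_identity - 1)
      } else {
        tf <- if (boundary) profile$min_query_coverage / 100 else
          stats::runif(1, 0.1, (profile$min_query_coverage - 2) / 100)
        aln <- max(1L, floor(tf * qlen))
      }
    }
    qstart <- sample.int(qlen - aln + 1L, 1L)
    data.frame(query_id = sprintf("q%04d", i),
               subject_id = sprintf("s%04d", i),
               percent_identity = round(pid, 2), alignment_length = aln,
               mismatches = round((1 - pid / 100) * aln), gap_opens = 0,
               query_start = qstart, query_end = qstart + aln - 1L,
               subject_start = 1, subject_end = aln,
               evalue = evalue, bitscore = round(stats::runif(1, 50, 900), 1),
               query_length = qlen, violated = violated,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  truth <- data.frame(query_id = hits$query_id, pass = pass,
                      violated = hits$violated, stringsAsFactors = FALSE)
  hits$violated <- NULL
  list(hits = hits,
       query_lengths = data.frame(query_id = hits$query_id,
                                  length = hits$query_length,
                                  stringsAsFactors = FALSE),
       truth = truth, seed = seed)
}
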