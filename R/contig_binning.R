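# Contig binning on the (GC content, coverage) plane. The study genome was
# recovered from a metagenome by gating contigs on exactly these two axes,
# so bins are axis-aligned boxes ("gates") applied in order.

#' GC content of nucleotide sequences
#'
#' Computes (G + C) / (A + C + G + T), case-insensitively. Ambiguity codes
#' (N, R, Y, ...) are excluded from both numerator and denominator. A
#' sequence with no unambiguous base yields `NA`.
#'
#' @param sequence Character vector of nucleotide sequences.
#' @return Numeric vector of GC fractions in `[0, 1]` (or `NA`).
#' @examples
#' gc_content(c("ATAT", "GCGC", "ACGTN"))
#' @export
gc_content <- function(sequence) {
  if (any(!nzchar(sequence))) stop("empty sequence")
  s <- toupper(sequence)
  gc <- nchar(gsub("[^GC]", "", s))
  denom <- nchar(gsub("[^ACGT]", "", s))
  ifelse(denom == 0L, NA_real_, gc / denom)
}

#' Filter contigs by length
#'
#' The study genome was described on contigs "longer than 500 bp"; whether
#' that bound is strict is not recorded, so the default keeps contigs with
#' length >= `min_length` and `strict_gt = TRUE` switches to a strict bound.
#'
#' @param contigs data.frame with a `sequence` column.
#' @param min_length Minimum length in bp.
#' @param strict_gt Keep only contigs strictly longer than `min_length`.
#' @return The filtered data.frame.
#' @export
filter_contigs <- function(contigs, min_length = 500L, strict_gt = FALSE) {
  stopifnot(min_length >= 0)
  len <- nchar(contigs$sequence)
  keep <- if (strict_gt) len > min_length else len >= min_length
  contigs[keep, , drop = FALSE]
}

#' Construct a bin gate
#'
#' A gate is an inclusive axis-aligned box in (GC fraction, coverage) space.
#'
#' @param bin_id Bin label.
#' @param gc_min,gc_max GC bounds as fractions in `[0, 1]`.
#' @param cov_min,cov_max Coverage bounds (x, read depth).
#' @return One-row data.frame describing the gate.
#' @export
bin_gate <- function(bin_id, gc_min, gc_max, cov_min, cov_max) {
  stopifnot(gc_min <= gc_max, cov_min <= cov_max,
            gc_min >= 0, gc_max <= 1, cov_min >= 0)
  data.frame(bin_id = bin_id, gc_min = gc_min, gc_max = gc_max,
             cov_min = cov_min, cov_max = cov_max, stringsAsFactors = FALSE)
}

#' Assign contigs to bins by (GC, coverage) gates
#'
#' Each contig is assigned to the first gate (in `gates` row order) whose
#' box contains its (GC, coverage) point; gate bounds are inclusive.
#' Contigs matching no gate are labelled `UNBINNED`. Every input contig
#' appears exactly once in the result.
#'
#' @param contigs data.frame with `contig_id`, `sequence`, `coverage`.
#' @param gates data.frame of gates as produced by [bin_gate()] (rows may
#'   be concatenated with `rbind`).
#' @return data.frame with `contig_id`, `bin_id`, `gc`, `coverage`, `length`.
#' @export
bin_contigs <- function(contigs, gates) {
  gc <- gc_content(contigs$sequence)
  bin <- rep("UNBINNED", nrow(contigs))
  for (g in rev(seq_len(nrow(gates)))) {  # reverse order => first match wins
    inside <- !is.na(gc) &
      gc >= gates$gc_min[g] & gc <= gates$gc_max[g] &
      contigs$coverage >= gates$cov_min[g] & contigs$coverage <= gates$cov_max[g]
    bin[inside] <- gates$bin_id[g]
  }
  data.frame(contig_id = contigs$contig_id, bin_id = bin, gc = gc,
             coverage = contigs$coverage, length = nchar(contigs$sequence),
             stringsAsFactors = FALSE)
}

#' Suggest two bin gates by 2-means clustering
#'
#' Helper for proposing gates when none are given: clusters contigs into two
#' groups in (GC, log10(coverage + 1)) space and returns the per-cluster
#' bounding boxes, expressed in linear coverage. Coverage is log-transformed
#' for clustering only, because read depth is multiplicative. If all points
#' coincide the function falls back to a single gate with a warning.
#'
#' @param contigs data.frame with `sequence` and `coverage`.
#' @param seed Integer seed; the same seed yields identical gates.
#' @return data.frame of gates (one or two rows).
#' @export
kmeans2_suggest_gates <- function(contigs, seed = 1L) {
  if (nrow(contigs) < 2L) stop("need at least 2 contigs")
  gc <- gc_content(contigs$sequence)
  if (anyNA(gc)) stop("cannot cluster contigs with undefined GC")
  x <- cbind(gc = gc, logcov = log10(contigs$coverage + 1))
  if (nrow(unique(x)) < 2L) {
    warning("all contigs identical in (GC, coverage); returning one gate")
    return(bin_gate("bin1", min(gc), max(gc),
                    min(contigs$coverage), max(contigs$coverage)))
  }
  km <- local({
    set.seed(seed)
    stats::kmeans(x, centers = 2L, nstart = 10L)
  })
  gates <- do.call(rbind, lapply(1:2, function(k) {
    sel <- km$cluster == k
    bin_gate(paste0("bin", k), min(gc[sel]), max(gc[sel]),
             min(contigs$coverage[sel]), max(contigs$coverage[sel]))
  }))
  # stable labelling regardless of kmeans' arbitrary cluster numbering
  ord <- order(gates$gc_min, gates$cov_min)
  gates <- gates[ord, , drop = FALSE]
  gates$bin_id <- paste0("bin", seq_len(nrow(gates)))
  rownames(gates) <- NULL
  gates
}
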