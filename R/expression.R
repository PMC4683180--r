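# RPKM transcript quantification: reads per kilobase of feature per million
# mapped reads, the length- and depth-normalized expression measure used for
# all expression values in this reconstruction.

#' RPKM from a read count
#'
#' `10^9 * read_count / (gene_length * total_mapped)`.
#'
#' @param read_count Mapped reads for the gene (vectorized).
#' @param gene_length Gene length in bp, >= 1.
#' @param total_mapped Total mapped reads in the library, >= 1.
#' @return RPKM value(s).
#' @examples
#' rpkm(1000, 1000, 1e6)  # 1000
#' @export
rpkm <- function(read_count, gene_length, total_mapped) {
  if (any(total_mapped < 1)) stop("total_mapped must be >= 1")
  if (any(gene_length < 1)) stop("gene_length must be >= 1")
  if (any(read_count < 0)) stop("read_count must be >= 0")
  1e9 * read_count / (gene_length * total_mapped)
}

#' Per-gene expression table
#'
#' Computes RPKM for every gene in a count table. By default the "million
#' mapped reads" denominator is the sum of the supplied table (reads mapped
#' to annotated features); `total_mapped` overrides it with a library-level
#' total when that is preferred.
#'
#' @param counts data.frame from [read_count_table()] (`gene_id`,
#'   `gene_length`, `read_count`).
#' @param total_mapped Optional denominator override.
#' @return data.frame with `gene_id`, `gene_length`, `read_count`, `rpkm`.
#' @export
expression_table <- function(counts, total_mapped = NULL) {
  if (anyDuplicated(counts$gene_id)) {
    stop("duplicate gene id: '",
         counts$gene_id[duplicated(counts$gene_id)][1], "'")
  }
  total <- if (is.null(total_mapped)) sum(counts$read_count) else total_mapped
  if (total < 1) stop("total mapped reads is zero; cannot compute RPKM")
  out <- counts[, c("gene_id", "gene_length", "read_count")]
  out$rpkm <- rpkm(counts$read_count, counts$gene_length, total)
  out
}

#' Keep abundantly expressed genes
#'
#' Retains records with RPKM strictly greater than `cutoff` (the study's
#' abundance filter is "RPKM value > 500").
#'
#' @param records data.frame with an `rpkm` column.
#' @param cutoff Strict RPKM cutoff.
#' @return Filtered data.frame.
#' @export
filter_abundant <- function(records, cutoff = 500) {
  records[!is.na(records$rpkm) & records$rpkm > cutoff, , drop = FALSE]
}
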