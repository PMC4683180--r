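# Readers and writers for every external format the pipeline touches.
# All downstream stages consume only the data frames defined here.

# Residues accepted in a normalized protein sequence: the 20 standard amino
# acids plus ambiguity/selenocysteine codes and the stop character.
.AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AA_ALLOWED <- c(.AA_STANDARD, "X", "U", "B", "Z", "*")

#' Read a protein FASTA file
#'
#' Parses a protein FASTA file into one row per record. Sequences are
#' uppercased; stop characters (`*`) are stripped from the sequence ends but
#' retained mid-sequence, where they act as non-matching residues in motif
#' scans. The first whitespace-delimited token of each header is the locus
#' identifier; the remainder is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `locus_id`, `description`, `sequence`.
#' @examples
#' tf <- tempfile(fileext = ".faa")
#' writeLines(c(">A demo", "MKC"), tf)
#' read_protein_fasta(tf)
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  headers <- names(set)
  locus_id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  # canonical form: terminal stops removed, internal ones kept
  seqs <- sub("\\*+$", "", sub("^\\*+", "", seqs))
  if (any(locus_id == "")) {
    stop("malformed FASTA header (empty id) at record ",
         which(locus_id == "")[1])
  }
  empty <- which(nchar(seqs) == 0L)
  if (length(empty)) {
    stop("empty sequence for record '", locus_id[empty[1]], "'")
  }
  dup <- locus_id[duplicated(locus_id)]
  if (length(dup)) {
    stop("duplicate locus id in ", path, ": '", dup[1], "'")
  }
  bad <- vapply(seqs, function(s) {
    res <- unique(strsplit(s, "", fixed = TRUE)[[1]])
    any(!res %in% .AA_ALLOWED)
  }, logical(1))
  if (any(bad)) {
    stop("record '", locus_id[which(bad)[1]],
         "' contains residues outside the accepted protein alphabet")
  }
  data.frame(locus_id = locus_id, description = description,
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a protein FASTA file
#'
#' Writes records in canonical form: headers are `locus_id description`,
#' sequences wrapped at 60 columns.
#'
#' @param proteins data.frame with `locus_id`, `description`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  stopifnot(all(c("locus_id", "sequence") %in% names(proteins)))
  desc <- if ("description" %in% names(proteins)) proteins$description else ""
  set <- Biostrings::BStringSet(proteins$sequence)
  names(set) <- trimws(paste(proteins$locus_id, desc))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a nucleotide FASTA file with per-contig coverage
#'
#' Joins a contig FASTA with a coverage table (columns `contig_id`,
#' `coverage`) into the contig data frame used by the binning stage.
#'
#' @param fasta_path Nucleotide FASTA.
#' @param coverage_path TSV with header columns `contig_id` and `coverage`.
#' @return data.frame with `contig_id`, `sequence`, `coverage`.
#' @export
read_contig_fasta <- function(fasta_path, coverage_path) {
  set <- Biostrings::readDNAStringSet(fasta_path)
  contig_id <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(contig_id)) {
    stop("duplicate contig id: '", contig_id[duplicated(contig_id)][1], "'")
  }
  cov <- read_tsv_table(coverage_path, required = c("contig_id", "coverage"))
  cov$coverage <- .parse_numeric_col(cov$coverage, "coverage")
  if (any(!is.finite(cov$coverage)) || any(cov$coverage < 0)) {
    stop("coverage values must be finite and non-negative")
  }
  m <- match(contig_id, cov$contig_id)
  if (anyNA(m)) {
    stop("no coverage entry for contig '", contig_id[which(is.na(m))[1]], "'")
  }
  data.frame(contig_id = contig_id,
             sequence = toupper(unname(as.character(set))),
             coverage = cov$coverage[m],
             stringsAsFactors = FALSE)
}

# Shared TSV reader: header line required, '#' comment lines skipped,
# unknown columns ignored, missing required columns rejected.
#' Read a headered TSV table
#'
#' @param path TSV path; a header line is required and lines starting with
#'   `#` are skipped.
#' @param required Character vector of column names that must be present.
#' @return data.frame of character columns (callers coerce as needed).
#' @export
read_tsv_table <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no header line in ", path)
  df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                          quote = "", comment.char = "",
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  df
}

.parse_numeric_col <- function(x, name) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out) && !all(is.na(x) == is.na(out))) {
    stop("non-numeric value in column '", name, "': '",
         x[which(is.na(out) & !is.na(x))[1]], "'")
  }
  out
}

#' Read a 12-column tabular pairwise-alignment hit file
#'
#' Expects the conventional tab-separated 12-column layout of protein
#' pairwise-search output: query, subject, percent identity, alignment
#' length, mismatches, gap opens, query start/end, subject start/end,
#' e-value, bit score. Rows are preserved in file order. Lines starting
#' with `#` are skipped.
#'
#' @param path Path to the hit table.
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`, `evalue`,
#'   `bitscore`.
#' @export
read_alignment_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "query_start", "query_end",
            "subject_start", "subject_end", "evalue", "bitscore")
  if (!length(lines)) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 10)), cols),
      stringsAsFactors = FALSE)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1]
    stop("line ", lineno[i], ": expected 12 tab-separated columns, found ",
         nf[i])
  }
  mat <- do.call(rbind, parts)
  out <- data.frame(query_id = mat[, 1], subject_id = mat[, 2],
                    stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(mat[, j]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop("line ", lineno[i], ": non-numeric value '", mat[i, j],
           "' in column ", j, " (", cols[j], ")")
    }
    out[[cols[j]]] <- v
  }
  if (any(out$percent_identity < 0 | out$percent_identity > 100)) {
    stop("percent_identity outside [0, 100]")
  }
  if (any(out$evalue < 0)) stop("negative e-value")
  if (any(out$query_start > out$query_end)) {
    stop("query_start > query_end at line ",
         lineno[which(out$query_start > out$query_end)[1]])
  }
  out
}

#' Read a per-gene read-count table
#'
#' TSV with header columns `gene_id`, `gene_length` (bp) and `read_count`.
#'
#' @param path TSV path.
#' @return data.frame with those three columns, numerics parsed.
#' @export
read_count_table <- function(path) {
  df <- read_tsv_table(path, required = c("gene_id", "gene_length",
                                          "read_count"))
  out <- data.frame(gene_id = df$gene_id, stringsAsFactors = FALSE)
  out$gene_length <- .parse_numeric_col(df$gene_length, "gene_length")
  out$read_count <- .parse_numeric_col(df$read_count, "read_count")
  if (any(out$gene_length < 1)) stop("gene_length must be >= 1")
  if (any(out$read_count < 0) || any(out$read_count != round(out$read_count))) {
    stop("read_count must be a non-negative integer")
  }
  out
}

#' Read a redox-couple table
#'
#' TSV with header columns `name`, `e0_prime_mv` (standard redox potential
#' at pH 7, millivolts) and `n_electrons`.
#'
#' @param path TSV path.
#' @return data.frame with those columns.
#' @export
read_redox_table <- function(path) {
  df <- read_tsv_table(path, required = c("name", "e0_prime_mv",
                                          "n_electrons"))
  out <- data.frame(name = df$name, stringsAsFactors = FALSE)
  out$e0_prime_mv <- .parse_numeric_col(df$e0_prime_mv, "e0_prime_mv")
  out$n_electrons <- .parse_numeric_col(df$n_electrons, "n_electrons")
  if (any(out$n_electrons < 1)) stop("n_electrons must be >= 1")
  if (anyDuplicated(out$name)) {
    stop("duplicate couple name: '", out$name[duplicated(out$name)][1], "'")
  }
  out
}

#' Read an annotation side-table
#'
#' TSV with header columns `locus_id`, `signal_peptide` and `n_tmh`.
#' `signal_peptide` holds a 1-based inclusive residue span such as `1-42`
#' (an en dash is also accepted) or is empty when no signal peptide was
#' predicted. These values come from external predictors and are consumed
#' as given.
#'
#' @param path TSV path.
#' @return data.frame with `locus_id`, `sp_start`, `sp_end` (NA when no
#'   span) and `n_tmh`.
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv_table(path, required = c("locus_id", "signal_peptide",
                                          "n_tmh"))
  span <- gsub("–", "-", df$signal_peptide)
  has <- nzchar(trimws(span))
  sp_start <- sp_end <- rep(NA_real_, nrow(df))
  if (any(has)) {
    parts <- strsplit(trimws(span[has]), "-", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("malformed signal peptide span: '", span[has][lengths(parts) != 2][1],
           "' (expected start-end)")
    }
    sp_start[has] <- as.numeric(vapply(parts, `[`, "", 1))
    sp_end[has] <- as.numeric(vapply(parts, `[`, "", 2))
    if (anyNA(sp_start[has]) || anyNA(sp_end[has])) {
      stop("non-numeric signal peptide span")
    }
    if (any(sp_start[has] < 1) || any(sp_start[has] > sp_end[has])) {
      stop("signal peptide span must satisfy 1 <= start <= end")
    }
  }
  n_tmh <- .parse_numeric_col(df$n_tmh, "n_tmh")
  if (any(n_tmh < 0)) stop("n_tmh must be >= 0")
  if (anyDuplicated(df$locus_id)) {
    stop("duplicate locus id in annotation table: '",
         df$locus_id[duplicated(df$locus_id)][1], "'")
  }
  data.frame(locus_id = df$locus_id, sp_start = sp_start, sp_end = sp_end,
             n_tmh = n_tmh, stringsAsFactors = FALSE)
}

#' Write a data.frame as a headered TSV
#'
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
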