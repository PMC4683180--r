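# Independent oracles, kept deliberately naive: exhaustive enumeration and
# filter-and-sort over plain vectors, sharing no code with the package
# implementations they check.

# exhaustive window enumeration for the default motif classes
oracle_scan <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  std <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  st <- c("S", "T"); bulky <- c("A", "V", "I", "L", "M", "F", "Y", "W")
  checks <- list(
    CXXCH = function(w) w[1] == "C" && all(w[2:3] %in% std) &&
      w[4] == "C" && w[5] == "H",
    CXXCK = function(w) w[1] == "C" && all(w[2:3] %in% std) &&
      w[4] == "C" && w[5] == "K",
    CXXXCH = function(w) w[1] == "C" && all(w[2:4] %in% std) &&
      w[5] == "C" && w[6] == "H",
    CXXXXCH = function(w) w[1] == "C" && all(w[2:5] %in% std) &&
      w[6] == "C" && w[7] == "H",
    HEMATITE = function(w) w[1] %in% st && w[2] %in% bulky &&
      w[3] %in% st && w[4] == "P" && w[5] %in% st
  )
  wlen <- c(CXXCH = 5L, CXXCK = 5L, CXXXCH = 6L, CXXXXCH = 7L,
            HEMATITE = 5L)
  out <- list()
  for (nm in names(checks)) {
    L <- wlen[[nm]]
    if (length(s) < L) next
    for (i in seq_len(length(s) - L + 1L)) {
      w <- s[i:(i + L - 1L)]
      if (all(w %in% std) && checks[[nm]](w)) {
        out[[length(out) + 1L]] <- data.frame(motif_name = nm, start = i,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(motif_name = character(0), start = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$motif_name), , drop = FALSE]
}

# brute-force homolog calling: filter every hit row, then sort and pick
oracle_call_homologs <- function(hits, max_evalue, min_identity,
                                 min_query_coverage = NULL) {
  pass <- hits$evalue < max_evalue & hits$percent_identity > min_identity
  if (!is.null(min_query_coverage)) {
    cov <- 100 * (hits$query_end - hits$query_start + 1) / hits$query_length
    pass <- pass & cov > min_query_coverage
  }
  res <- lapply(sort(unique(hits$query_id)), function(q) {
    h <- hits[hits$query_id == q & pass, , drop = FALSE]
    if (!nrow(h)) {
      return(data.frame(query_id = q, subject_id = NA_character_,
                        passed = FALSE, stringsAsFactors = FALSE))
    }
    h <- h[order(h$evalue, -h$bitscore, h$subject_id), , drop = FALSE]
    data.frame(query_id = q, subject_id = h$subject_id[1], passed = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

random_protein <- function(len, p_ambig = 0.05) {
  alpha <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  ambig <- c("X", "B", "Z", "U", "*")
  paste(sample(c(alpha, ambig), len, replace = TRUE,
               prob = c(rep((1 - p_ambig) / 20, 20),
                        rep(p_ambig / 5, 5))),
        collapse = "")
}

random_dna <- function(len, p_ambig = 0.1) {
  paste(sample(c("A", "C", "G", "T", "a", "c", "g", "t", "N", "R", "Y"),
               len, replace = TRUE,
               prob = c(rep((1 - p_ambig) / 8, 8), rep(p_ambig / 3, 3))),
        collapse = "")
}

# the 23 "Number of CxxCH" integers and RPKM values of the abundantly
# expressed cytochrome table, in row order
table2_cxxch <- c(4, 1, 4, 5, 5, 2, 13, 11, 5, 5, 5, 1, 12, 21, 3, 4, 5,
                  1, 1, 21, 18, 1, 2)
table2_rpkm <- c(9148, 4802, 3683, 1747, 1739, 1496, 1472, 1394, 1138,
                 1073, 993, 932, 907, 771, 767, 610, 578, 560, 1775,
                 1102, 925, 776, 625)
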