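# Homolog calling from tabular pairwise-alignment hits. Two threshold
# profiles are built in because the study applied different criteria in
# different analyses: a genome-wide definition (e-value < 1e-10, identity
# > 40%) and a stricter per-table definition (e-value < 1e-20, identity
# > 40%, alignment covering > 90% of the query). All bounds are strict.

#' Construct a homolog-calling threshold profile
#'
#' @param name Profile label, recorded in every call.
#' @param max_evalue Strict upper bound on the e-value.
#' @param min_identity Strict lower bound on percent identity, in `[0, 100]`.
#' @param min_query_coverage Optional strict lower bound on the percentage
#'   of the query covered by the aligned segment; `NULL` disables the
#'   coverage criterion.
#' @return List of class `threshold_profile`.
#' @export
threshold_profile <- function(name, max_evalue, min_identity,
                              min_query_coverage = NULL) {
  stopifnot(is.finite(max_evalue), max_evalue >= 0,
            min_identity >= 0, min_identity <= 100)
  if (!is.null(min_query_coverage)) {
    stopifnot(is.finite(min_query_coverage))
  }
  structure(list(name = name, max_evalue = max_evalue,
                 min_identity = min_identity,
                 min_query_coverage = min_query_coverage),
            class = "threshold_profile")
}

#' @rdname threshold_profile
#' @details `profile_genome_wide()` is the genome-wide homolog definition
#'   (e-value < 1e-10, identity > 40%, no coverage requirement);
#'   `profile_table_strict()` is the stricter per-table footnote criterion
#'   (e-value < 1e-20, identity > 40%, query coverage > 90%).
#' @export
profile_genome_wide <- function() {
  threshold_profile("genome_wide", 1e-10, 40)
}

#' @rdname threshold_profile
#' @export
profile_table_strict <- function() {
  threshold_profile("table_strict", 1e-20, 40, 90)
}

#' Percent of the query covered by a hit
#'
#' `100 * (query_end - query_start + 1) / query_length`, from the single
#' best-scoring aligned segment (no segment union).
#'
#' @param hits data.frame of alignment hits carrying `query_start`,
#'   `query_end` and `query_length`.
#' @return Numeric vector of coverage percentages.
#' @export
query_coverage <- function(hits) {
  if (!"query_length" %in% names(hits) || anyNA(hits$query_length)) {
    stop("query_length is required to compute query coverage")
  }
  stopifnot(all(hits$query_length >= 1))
  100 * (hits$query_end - hits$query_start + 1) / hits$query_length
}

#' Attach query lengths to a hit table
#'
#' @param hits data.frame from [read_alignment_table()].
#' @param query_lengths data.frame with `query_id` and `length` (residues).
#' @return `hits` with a `query_length` column.
#' @export
join_query_lengths <- function(hits, query_lengths) {
  m <- match(hits$query_id, query_lengths$query_id)
  if (anyNA(m)) {
    stop("no length for query '", hits$query_id[which(is.na(m))[1]], "'")
  }
  hits$query_length <- query_lengths$length[m]
  hits
}

#' Call homologs from alignment hits under a threshold profile
#'
#' A hit passes when its e-value is strictly below `max_evalue`, its percent
#' identity strictly above `min_identity`, and (when the profile requires
#' it) its query coverage strictly above `min_query_coverage`. Per query the
#' best passing hit is reported, ordered by lowest e-value, then highest bit
#' score, then lexicographic subject id; queries with no passing hit are
#' reported with `passed = FALSE` and no subject. Output rows are sorted by
#' query id, so the result is invariant to the input row order.
#'
#' @param hits data.frame of hits; must carry `query_length` (see
#'   [join_query_lengths()]) when the profile has a coverage criterion.
#' @param profile A [threshold_profile()].
#' @return data.frame with `query_id`, `subject_id`, `percent_identity`,
#'   `evalue`, `query_coverage`, `profile_name`, `passed` — one row per
#'   distinct query in `hits`.
#' @export
call_homologs <- function(hits, profile = profile_genome_wide()) {
  stopifnot(inherits(profile, "threshold_profile"))
  needs_cov <- !is.null(profile$min_query_coverage)
  qcov <- if ("query_length" %in% names(hits) && !anyNA(hits$query_length)) {
    query_coverage(hits)
  } else if (needs_cov) {
    stop("profile '", profile$name,
         "' requires query coverage but query_length is missing")
  } else {
    rep(NA_real_, nrow(hits))
  }
  pass <- hits$evalue < profile$max_evalue &
    hits$percent_identity > profile$min_identity
  if (needs_cov) pass <- pass & qcov > profile$min_query_coverage

  queries <- sort(unique(hits$query_id))
  rows <- lapply(queries, function(q) {
    sel <- which(hits$query_id == q & pass)
    if (!length(sel)) {
      return(data.frame(query_id = q, subject_id = NA_character_,
                        percent_identity = NA_real_, evalue = NA_real_,
                        query_coverage = NA_real_,
                        profile_name = profile$name, passed = FALSE,
                        stringsAsFactors = FALSE))
    }
    sel <- sel[order(hits$evalue[sel], -hits$bitscore[sel],
                     hits$subject_id[sel])]
    b <- sel[1]
    data.frame(query_id = q, subject_id = hits$subject_id[b],
               percent_identity = hits$percent_identity[b],
               evalue = hits$evalue[b], query_coverage = qcov[b],
               profile_name = profile$name, passed = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(query_id = character(0), subject_id = character(0),
                      percent_identity = numeric(0), evalue = numeric(0),
                      query_coverage = numeric(0),
                      profile_name = character(0), passed = logical(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
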