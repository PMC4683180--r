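# End-to-end orchestration: binning -> census/homolog/expression joins ->
# energetics, emitting the consolidated metabolic-model evidence report
# (census table, homolog table, energetics ledger, summary). Each stage is
# also callable standalone through its own exported function with identical
# results.

# tiny FNV-1a hash over a string, for the provenance block
.fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Build a pipeline configuration
#'
#' @param proteome Path to the protein FASTA.
#' @param contig_fasta,coverage Paths to the contig FASTA and coverage TSV
#'   (both `NULL` to skip the binning stage).
#' @param counts Path to the read-count TSV (`NULL` to skip expression).
#' @param hits,query_lengths Paths to the alignment hit table and query
#'   length TSV (`hits = NULL` skips homolog calling).
#' @param annotations Path to the annotation TSV, or `NULL`.
#' @param couples Path to a redox-couple TSV; default uses the packaged
#'   table.
#' @param gates Bin gate data.frame ([bin_gate()]); `NULL` derives gates by
#'   2-means clustering.
#' @param profile Homolog threshold profile name, `"genome_wide"` or
#'   `"table_strict"`.
#' @param min_contig_length,strict_gt Contig length filter settings.
#' @param multiheme_threshold Minimum CXXCH count for the multiheme flag.
#' @param abundance_cutoff Strict RPKM abundance cutoff.
#' @param stages Character vector of stages to run, a subset of
#'   `c("binning", "expression", "homologs", "census", "energetics")`.
#' @param out_dir Output directory for the report bundle (`NULL` for none).
#' @param seed Integer seed recorded in the provenance block and used by
#'   gate suggestion.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(proteome = NULL, contig_fasta = NULL,
                            coverage = NULL, counts = NULL, hits = NULL,
                            query_lengths = NULL, annotations = NULL,
                            couples = NULL, gates = NULL,
                            profile = "genome_wide",
                            min_contig_length = 500L, strict_gt = FALSE,
                            multiheme_threshold = 3L,
                            abundance_cutoff = 500,
                            stages = c("binning", "expression", "homologs",
                                       "census", "energetics"),
                            out_dir = NULL, seed = 1L) {
  paths <- Filter(Negate(is.null),
                  list(proteome = proteome, contig_fasta = contig_fasta,
                       coverage = coverage, counts = counts, hits = hits,
                       query_lengths = query_lengths,
                       annotations = annotations, couples = couples))
  missing <- names(paths)[!vapply(paths, file.exists, logical(1))]
  if (length(missing)) {
    stop("configured input does not exist: ",
         paste(missing, collapse = ", "))
  }
  structure(list(proteome = proteome, contig_fasta = contig_fasta,
                 coverage = coverage, counts = counts, hits = hits,
                 query_lengths = query_lengths, annotations = annotations,
                 couples = couples, gates = gates, profile = profile,
                 min_contig_length = min_contig_length,
                 strict_gt = strict_gt,
                 multiheme_threshold = multiheme_threshold,
                 abundance_cutoff = abundance_cutoff, stages = stages,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

.stage_msg <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the full reconstruction pipeline
#'
#' Executes the configured stages in order (binning, expression, homolog
#' calling, cytochrome census, energetics), logging inputs and record
#' counts, and returns the report bundle. When `config$out_dir` is set the
#' bundle is also written: `census.tsv`, `homologs.tsv`, `bins.tsv`,
#' `energetics.json` and `summary.json`. Everything except the single
#' timestamp field in the provenance block is deterministic given the
#' configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @return List with elements `bins`, `expression`, `homologs`, `census`,
#'   `census_summary`, `energetics` (present only for enabled stages) and
#'   `summary`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list()
  err_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("binning" %in% config$stages && !is.null(config$contig_fasta)) {
    out$bins <- err_stage("binning", {
      contigs <- read_contig_fasta(config$contig_fasta, config$coverage)
      .stage_msg("binning", nrow(contigs), " contigs read; min length ",
                 config$min_contig_length)
      contigs <- filter_contigs(contigs, config$min_contig_length,
                                config$strict_gt)
      gates <- if (is.null(config$gates)) {
        kmeans2_suggest_gates(contigs, seed = config$seed)
      } else config$gates
      bin_contigs(contigs, gates)
    })
    .stage_msg("binning", nrow(out$bins), " contigs assigned")
  }

  expr_tbl <- NULL
  if ("expression" %in% config$stages && !is.null(config$counts)) {
    expr_tbl <- err_stage("expression", {
      counts <- read_count_table(config$counts)
      .stage_msg("expression", nrow(counts), " genes; total mapped reads ",
                 sum(counts$read_count))
      expression_table(counts)
    })
    out$expression <- expr_tbl
  }

  calls <- NULL
  if ("homologs" %in% config$stages && !is.null(config$hits)) {
    calls <- err_stage("homologs", {
      hits <- read_alignment_table(config$hits)
      if (!is.null(config$query_lengths)) {
        ql <- read_tsv_table(config$query_lengths,
                             required = c("query_id", "length"))
        ql$length <- .parse_numeric_col(ql$length, "length")
        hits <- join_query_lengths(hits, ql)
      }
      prof <- switch(config$profile,
                     genome_wide = profile_genome_wide(),
                     table_strict = profile_table_strict(),
                     stop("unknown profile: ", config$profile))
      .stage_msg("homologs", nrow(hits), " hits under profile '",
                 prof$name, "'")
      call_homologs(hits, prof)
    })
    out$homologs <- calls
  }

  if ("census" %in% config$stages && !is.null(config$proteome)) {
    out$census <- err_stage("census", {
      proteome <- read_protein_fasta(config$proteome)
      annots <- if (!is.null(config$annotations)) {
        read_annotation_table(config$annotations)
      }
      .stage_msg("census", nrow(proteome), " proteins; multiheme threshold ",
                 config$multiheme_threshold)
      census(proteome, expression = expr_tbl, annotations = annots,
             homologs = calls,
             multiheme_threshold = config$multiheme_threshold)
    })
    out$census_summary <- census_summary(out$census,
                                         config$abundance_cutoff)
    .stage_msg("census", out$census_summary$n_total,
               " proteins with >= 1 heme motif")
  }

  if ("energetics" %in% config$stages) {
    out$energetics <- err_stage("energetics", {
      couples <- if (is.null(config$couples)) default_redox_couples()
                 else read_redox_table(config$couples)
      headline <- delta_g(8, get_couple(couples, "CO2/CH4"),
                          get_couple(couples, "NO3-/NO2-"))
      ledger <- reverse_methanogenesis_ledger()
      pmf <- pmf_balance(ledger)
      confurcation <- coupled_reaction_dg(list(
        list(2, get_couple(couples, "CoM-S-S-CoB/CoM-SH+CoB-SH"),
             get_couple(couples, "F420")),
        list(2, get_couple(couples, "ferredoxin"),
             get_couple(couples, "F420"))))
      list(headline = headline, ledger = ledger, pmf = pmf,
           confurcation = confurcation)
    })
    .stage_msg("energetics", "headline deltaG0' = ",
               round(out$energetics$headline$delta_g0_kj), " kJ/mol CH4")
  }

  out$summary <- list(
    n_cxxch_proteins = if (!is.null(out$census))
      sum(out$census$n_cxxch >= 1) else NA,
    n_abundant = if (!is.null(out$census_summary))
      out$census_summary$n_abundant else NA,
    fraction_multiheme_pct = if (!is.null(out$census_summary))
      out$census_summary$fraction_multiheme_pct else NA,
    max_cxxch = if (!is.null(out$census_summary))
      out$census_summary$max_cxxch else NA,
    delta_g0_kj_per_ch4 = if (!is.null(out$energetics))
      round(out$energetics$headline$delta_g0_kj) else NA,
    net_pmf_charges = if (!is.null(out$energetics))
      out$energetics$pmf$net_charges else NA
  )
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  out$provenance <- list(
    tool = "methanoredox",
    version = as.character(utils::packageVersion("methanoredox")),
    seed = config$seed,
    config_hash = .fnv1a(jsonlite::toJSON(unclass(cfg_for_hash),
                                          auto_unbox = TRUE, null = "null")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, f) write_tsv_table(df, file.path(config$out_dir, f))
    if (!is.null(out$bins)) w(out$bins, "bins.tsv")
    if (!is.null(out$census)) w(out$census, "census.tsv")
    if (!is.null(out$homologs)) w(out$homologs, "homologs.tsv")
    if (!is.null(out$energetics)) {
      en <- out$energetics
      jsonlite::write_json(
        list(headline = unclass(en$headline),
             ledger = list(flows = en$ledger$flows,
                           total_donated = en$ledger$total_donated,
                           total_accepted = en$ledger$total_accepted),
             pmf = list(steps = en$pmf$steps,
                        mtr_charges = en$pmf$mtr_charges,
                        net_charges = en$pmf$net_charges),
             confurcation = en$confurcation),
        file.path(config$out_dir, "energetics.json"),
        auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(c(out$summary, list(provenance = out$provenance)),
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
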