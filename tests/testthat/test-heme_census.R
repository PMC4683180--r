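test_that("motif scanning handles anchors, wildcards and voided windows", {
  hit <- scan_motifs(list(locus_id = "p", sequence = "AACAACHAA"))
  expect_equal(hit$motif_name, "CXXCH")
  expect_equal(hit$start, 3L)
  expect_equal(hit$match, "CAACH")

  # wildcard positions may themselves be C (or H)
  hit <- scan_motifs(list(locus_id = "p", sequence = "CCACH"))
  expect_equal(hit$start, 1L)

  # hematite motif class membership
  expect_equal(nrow(scan_motifs(list(locus_id = "p", sequence = "TATPA"))), 0L)
  hit <- scan_motifs(list(locus_id = "p", sequence = "SFSPS"))
  expect_equal(hit$motif_name, "HEMATITE")

  # ambiguity codes and stops void the window
  expect_equal(nrow(scan_motifs(list(locus_id = "p", sequence = "CXACH"))), 0L)
  expect_equal(nrow(scan_motifs(list(locus_id = "p", sequence = "C*ACH"))), 0L)

  # overlapping hits within and across classes are all reported
  hits <- scan_motifs(list(locus_id = "p", sequence = "CCACCHCH"))
  expect_true(all(c("CXXCH", "CXXXCH") %in% hits$motif_name))

  # case-insensitive
  expect_equal(nrow(scan_motifs(list(locus_id = "p", sequence = "caach"))), 1L)
})

test_that("scanner equals the exhaustive window oracle on random sequences", {
  set.seed(101)
  for (i in 1:1000) {
    s <- random_protein(sample(20:80, 1))
    got <- scan_motifs(list(locus_id = "r", sequence = s))
    want <- oracle_scan(s)
    expect_equal(got$motif_name, want$motif_name,
                 info = paste("sequence:", s))
    expect_equal(got$start, want$start, info = paste("sequence:", s))
  }
})

test_that("census recovers planted counts and applies the multiheme flag", {
  gen <- generate_proteome(4, c(0, 1, 3, 21), protein_length = 300, seed = 2)
  cen <- census(gen$proteome)
  expect_equal(cen$locus_id, gen$truth$locus_id[-1])  # zero-hit protein absent
  expect_equal(cen$n_cxxch, c(1L, 3L, 21L))
  expect_equal(cen$is_multiheme, c(FALSE, TRUE, TRUE))

  # raising the threshold never increases the multiheme count
  n_multi <- vapply(1:22, function(thr) {
    sum(census(gen$proteome, multiheme_threshold = thr)$is_multiheme)
  }, integer(1))
  expect_true(all(diff(n_multi) <= 0))

  empty <- census(gen$proteome[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("census recovers mixed planted classes exactly", {
  counts <- list(CXXCH = c(2L, 0L, 4L), CXXCK = c(1L, 1L, 0L),
                 CXXXCH = c(0L, 2L, 1L), CXXXXCH = c(1L, 0L, 0L),
                 HEMATITE = c(0L, 1L, 2L))
  gen <- generate_proteome(3, counts, protein_length = 250, seed = 8)
  cen <- census(gen$proteome)
  expect_equal(cen$n_cxxch, counts$CXXCH)
  expect_equal(cen$n_cxxck, counts$CXXCK)
  expect_equal(cen$n_cxxxch, counts$CXXXCH)
  expect_equal(cen$n_cxxxxch, counts$CXXXXCH)
  expect_equal(cen$hematite_motif_hits, counts$HEMATITE)
})

test_that("census joins side tables by locus and rejects duplicates", {
  gen <- generate_proteome(2, c(1, 3), protein_length = 100, seed = 4)
  expr <- data.frame(gene_id = gen$proteome$locus_id, rpkm = c(600, 80),
                     stringsAsFactors = FALSE)
  cen <- census(gen$proteome, expression = expr)
  expect_equal(cen$rpkm, c(600, 80))

  dup <- rbind(expr, expr[1, ])
  expect_error(census(gen$proteome, expression = dup), "duplicate")
})

test_that("census summary reproduces the abundant-cytochrome statistics", {
  entries <- data.frame(n_cxxch = table2_cxxch,
                        is_multiheme = table2_cxxch >= 3,
                        rpkm = table2_rpkm)
  s <- census_summary(entries)
  expect_equal(s$n_total, 23L)
  expect_equal(s$n_abundant, 23L)
  expect_equal(s$fraction_multiheme_pct, 70)
  expect_equal(s$max_cxxch, 21)

  # boundary: RPKM exactly at the cutoff is not abundant
  low <- data.frame(n_cxxch = c(3, 5), is_multiheme = c(TRUE, TRUE),
                    rpkm = c(500, 499))
  expect_equal(census_summary(low)$n_abundant, 0L)

  set.seed(6)
  planted <- data.frame(n_cxxch = rep(1, 40), is_multiheme = FALSE,
                        rpkm = c(rep(1000, 10), rep(10, 30)))
  expect_equal(census_summary(planted)$n_abundant, 10L)
})

test_that("full-scale reproduction machinery runs on a synthetic stand-in", {
  gen <- generate_proteome(6, c(0, 1, 2, 3, 4, 5), protein_length = 200,
                           seed = 12)
  faa <- tempfile(fileext = ".faa")
  write_protein_fasta(gen$proteome, faa)
  ctg <- generate_contigs(20, seed = 12)
  fa <- tempfile(fileext = ".fa")
  cov <- tempfile(fileext = ".tsv")
  writeLines(c(rbind(paste0(">", ctg$contigs$contig_id),
                     ctg$contigs$sequence)), fa)
  write_tsv_table(data.frame(contig_id = ctg$contigs$contig_id,
                             coverage = ctg$contigs$coverage), cov)
  res <- reproduce_fullscale(faa, fa, cov, nrfa_locus = "SYN_0006")
  expect_equal(res$n_cxxch_proteins, 5L)
  expect_equal(res$n_contigs_min500,
               sum(nchar(ctg$contigs$sequence) >= 500))
  expect_equal(res$nrfa_heme_motifs, 5L)  # CXXCH + CXXCK count for that locus
})
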