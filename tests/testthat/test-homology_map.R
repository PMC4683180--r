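test_that("query coverage is the covered fraction of the query in percent", {
  h <- data.frame(query_start = c(1, 11, 1), query_end = c(100, 100, 1),
                  query_length = c(100, 100, 200))
  expect_equal(query_coverage(h), c(100, 90, 0.5))
  h$query_length <- NULL
  expect_error(query_coverage(h), "query_length")
})

test_that("homolog calls apply strict bounds per profile", {
  mk <- function(evalue, pid, qstart = 1, qend = 95, qlen = 100) {
    data.frame(query_id = "q", subject_id = "s", percent_identity = pid,
               alignment_length = qend - qstart + 1, mismatches = 0,
               gap_opens = 0, query_start = qstart, query_end = qend,
               subject_start = 1, subject_end = qend - qstart + 1,
               evalue = evalue, bitscore = 100, query_length = qlen,
               stringsAsFactors = FALSE)
  }
  gw <- profile_genome_wide()
  expect_true(call_homologs(mk(1e-12, 50), gw)$passed)
  expect_false(call_homologs(mk(1e-5, 80), gw)$passed)
  # strictness at the exact bounds
  expect_false(call_homologs(mk(1e-10, 50), gw)$passed)
  expect_false(call_homologs(mk(1e-12, 40), gw)$passed)

  ts <- profile_table_strict()
  expect_true(call_homologs(mk(1e-25, 50, 1, 95), ts)$passed)    # cov 95
  expect_false(call_homologs(mk(1e-25, 50, 1, 90), ts)$passed)   # cov 90, strict
  expect_false(call_homologs(mk(1e-15, 50, 1, 95), ts)$passed)   # evalue
  expect_error(call_homologs(transform(mk(1e-25, 50), query_length = NA), ts),
               "query coverage")
  # the profile used is recorded in every call
  expect_equal(call_homologs(mk(1e-25, 50), ts)$profile_name, "table_strict")
})

test_that("best-hit selection equals the brute-force oracle and is order-invariant", {
  set.seed(23)
  for (rep in 1:20) {
    n <- 120
    hits <- data.frame(
      query_id = sample(sprintf("q%02d", 1:30), n, replace = TRUE),
      subject_id = sample(sprintf("s%02d", 1:40), n, replace = TRUE),
      percent_identity = runif(n, 10, 95),
      alignment_length = 50, mismatches = 0, gap_opens = 0,
      query_start = 1, query_end = sample(40:100, n, replace = TRUE),
      subject_start = 1, subject_end = 50,
      evalue = 10^runif(n, -40, 0), bitscore = round(runif(n, 30, 500)),
      query_length = 100, stringsAsFactors = FALSE)
    got <- call_homologs(hits, profile_genome_wide())
    want <- oracle_call_homologs(hits, 1e-10, 40)
    expect_equal(got$query_id, want$query_id)
    expect_equal(got$passed, want$passed)
    expect_equal(got$subject_id, want$subject_id)

    shuffled <- hits[sample(nrow(hits)), ]
    expect_equal(call_homologs(shuffled, profile_genome_wide()), got)
  }
})

test_that("relaxing any single threshold never fails a passing call", {
  gen <- generate_alignment_table(80, 0.5, profile_table_strict(), seed = 31)
  base <- call_homologs(gen$hits, profile_table_strict())
  relaxed <- list(
    threshold_profile("e", 1e-10, 40, 90),   # looser e-value
    threshold_profile("i", 1e-20, 20, 90),   # looser identity
    threshold_profile("c", 1e-20, 40, 50),   # looser coverage
    threshold_profile("n", 1e-20, 40, NULL)  # coverage dropped
  )
  for (p in relaxed) {
    calls <- call_homologs(gen$hits, p)
    expect_true(all(calls$passed[base$passed]),
                info = paste("profile", p$name))
  }
})

test_that("planted pass/fail structure is recovered exactly", {
  for (prof in list(profile_genome_wide(), profile_table_strict())) {
    gen <- generate_alignment_table(100, 0.6, prof, seed = 13)
    calls <- call_homologs(gen$hits, prof)
    expect_equal(sum(calls$passed), 60L)
    m <- match(calls$query_id, gen$truth$query_id)
    expect_equal(calls$passed, gen$truth$pass[m])
  }
  gen0 <- generate_alignment_table(50, 0, profile_genome_wide(), seed = 13)
  expect_equal(sum(call_homologs(gen0$hits, profile_genome_wide())$passed), 0L)
})
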