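test_that("gc_content matches a brute-force character count", {
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content("ACGTN"), 0.5)   # N excluded from both sides
  expect_true(is.na(gc_content("NNNN")))
  expect_error(gc_content(""), "empty")

  set.seed(11)
  for (i in 1:100) {
    s <- random_dna(sample(10:300, 1))
    chars <- strsplit(toupper(s), "")[[1]]
    num <- sum(chars %in% c("G", "C"))
    den <- sum(chars %in% c("A", "C", "G", "T"))
    expect_equal(gc_content(s), if (den == 0) NA_real_ else num / den)
  }
})

test_that("length filter keeps >= min by default and supports a strict bound", {
  contigs <- data.frame(contig_id = c("a", "b", "c"),
                        sequence = c(strrep("A", 499), strrep("A", 500),
                                     strrep("A", 501)),
                        coverage = c(1, 1, 1), stringsAsFactors = FALSE)
  expect_equal(filter_contigs(contigs, 500)$contig_id, c("b", "c"))
  expect_equal(filter_contigs(contigs, 500, strict_gt = TRUE)$contig_id, "c")
  expect_equal(filter_contigs(contigs, 0), contigs)
})

test_that("gate assignment is total, inclusive and first-match-wins", {
  contigs <- data.frame(
    contig_id = c("in", "edge", "out"),
    sequence = c(paste(rep(c("G", "C", "A", "T"), c(45, 45, 55, 55)),
                       collapse = ""),          # gc = 0.45
                 paste(rep(c("G", "A"), c(40, 60)), collapse = ""),  # 0.40
                 strrep("A", 100)),             # 0.0
    coverage = c(80, 50, 80), stringsAsFactors = FALSE)
  gates <- rbind(bin_gate("MPE", 0.4, 0.5, 50, 150),
                 bin_gate("wide", 0.0, 1.0, 0, 1e6))
  ba <- bin_contigs(contigs, gates)
  expect_equal(nrow(ba), nrow(contigs))            # total function
  expect_equal(ba$bin_id, c("MPE", "MPE", "wide")) # inclusive + first match
  ba2 <- bin_contigs(contigs, gates[1, ])
  expect_equal(ba2$bin_id, c("MPE", "MPE", "UNBINNED"))
})

test_that("well-separated clusters are recovered through suggested gates", {
  gen <- generate_contigs(200, seed = 17)
  gates <- kmeans2_suggest_gates(gen$contigs, seed = 17)
  ba <- bin_contigs(gen$contigs, gates)
  expect_equal(nrow(ba), 200L)
  # map recovered bins to generating clusters by majority, then score
  tab <- table(ba$bin_id, gen$truth$cluster)
  accuracy <- sum(apply(tab, 2, max)) / 200
  expect_gte(accuracy, 0.99)

  # 6-sigma separation on both axes => zero misassignment here
  expect_equal(accuracy, 1)
})

test_that("gate suggestion is seed-deterministic and degenerates gracefully", {
  gen <- generate_contigs(60, seed = 3)
  g1 <- kmeans2_suggest_gates(gen$contigs, seed = 5)
  g2 <- kmeans2_suggest_gates(gen$contigs, seed = 5)
  expect_identical(g1, g2)

  same <- data.frame(contig_id = c("a", "b"),
                     sequence = c("ACGT", "ACGT"), coverage = c(10, 10),
                     stringsAsFactors = FALSE)
  expect_warning(g <- kmeans2_suggest_gates(same, seed = 1), "identical")
  expect_equal(nrow(g), 1L)
})
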