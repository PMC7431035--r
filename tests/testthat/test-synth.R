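test_that("evolve_sequence is identity-preserving and deterministic", {
  s <- with_seed(1, random_dna(200))
  expect_identical(evolve_sequence(s, 1.0, 0.1, seed = 4), s)
  e1 <- evolve_sequence(s, 0.7, 0.05, seed = 9)
  e2 <- evolve_sequence(s, 0.7, 0.05, seed = 9)
  expect_identical(e1, e2)
  expect_false(identical(e1, evolve_sequence(s, 0.7, 0.05, seed = 10)))
})

test_that("evolved sequences hit the target identity in expectation", {
  # identity measured by global alignment, as the classifier consumes it
  s <- with_seed(2, random_dna(1000))
  ids <- vapply(1:100, function(seed) {
    e <- evolve_sequence(s, 0.62, 0, seed = seed)
    needleman_wunsch(s, e)$identity
  }, numeric(1))
  expect_lt(abs(mean(ids) - 0.62), 0.02)
})

test_that("plant_motif writes consensus-biased instances respecting strand", {
  pfm <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm[cbind(c(1, 2, 3, 4), 1:4)] <- 10  # unanimous ACGT
  s <- with_seed(3, random_dna(50))
  res <- plant_motif(s, pfm, 10, "+", seed = 1)
  expect_equal(substr(res$seq, 11, 14), "ACGT")
  expect_equal(nchar(res$seq), 50L)

  resm <- plant_motif(s, pfm, 10, "-", seed = 1)
  expect_equal(substr(resm$seq, 11, 14), revcomp("ACGT"))

  expect_identical(plant_motif(s, pfm, 10, "+", seed = 5)$seq,
                   plant_motif(s, pfm, 10, "+", seed = 5)$seq)
  expect_error(plant_motif(s, pfm, 48, "+", seed = 1), "fit")
})

test_that("generated pairs keep exact truth bookkeeping", {
  spec <- synthetic_spec(seed = 21L)
  pair <- generate_locus_pair(spec)
  # truth coordinates exact: element sequence in A is element-length long
  ta <- pair$truth$a
  expect_equal(nrow(ta), 1L)
  expect_equal(ta$end - ta$start, spec$element_length)
  tb <- pair$truth$b
  expect_equal(nrow(tb), 1L)
  # element copy in B really aligns at the recorded identity
  ea <- substr(pair$locus_a$seq, ta$start + 1, ta$end)
  eb <- substr(pair$locus_b$seq, tb$start + 1, tb$end)
  expect_equal(needleman_wunsch(ea, eb)$identity,
               unname(pair$truth$realized_identity["element1"]))
  # no truth element overlaps exons or repeats
  other <- pair$annotations_a[pair$annotations_a$kind %in% c("exon", "repeat"), ]
  for (i in seq_len(nrow(other)))
    expect_equal(interval_overlap(ta$start, ta$end,
                                  other$start[i], other$end[i]), 0L)
})

test_that("target identity 0.85 yields realized identity >= 0.75", {
  for (seed in 1:10) {
    pair <- generate_locus_pair(synthetic_spec(element_length = 150L,
                                               target_identity = 0.85,
                                               seed = seed))
    expect_gte(unname(pair$truth$realized_identity["element1"]), 0.75)
  }
})

test_that("generator degenerate and error cases behave", {
  pair0 <- generate_locus_pair(synthetic_spec(n_conserved_elements = 0L,
                                              seed = 2L))
  expect_equal(nrow(pair0$truth$a), 0L)
  expect_error(synthetic_spec(locus_length = 900L),
               "do not fit")
  expect_error(synthetic_spec(target_identity = 0.3,
                              background_identity = 0.4), "exceed")
  # determinism: same spec twice gives identical loci
  p1 <- generate_locus_pair(synthetic_spec(seed = 8L))
  p2 <- generate_locus_pair(synthetic_spec(seed = 8L))
  expect_identical(p1$locus_a$seq, p2$locus_a$seq)
  expect_identical(p1$locus_b$seq, p2$locus_b$seq)
})

test_that("planted elements separate from background at screening settings", {
  # best element-vs-element local score dominates background-vs-background
  for (seed in 1:20) {
    pair <- generate_locus_pair(synthetic_spec(
      locus_length = 2000L, element_length = 120L, target_identity = 0.8,
      background_identity = 0.3, n_exons = 0L, n_repeats = 0L, seed = seed))
    ta <- pair$truth$a; tb <- pair$truth$b
    ea <- substr(pair$locus_a$seq, ta$start + 1, ta$end)
    eb <- substr(pair$locus_b$seq, tb$start + 1, tb$end)
    el_score <- smith_waterman(ea, eb)$score
    bg_a <- substr(pair$locus_a$seq, ta$end + 101, ta$end + 800)
    bg_b <- substr(pair$locus_b$seq, tb$end + 101, tb$end + 800)
    bg_score <- smith_waterman(bg_a, bg_b)$score
    expect_gt(el_score, bg_score)
  }
})

test_that("synthetic pairs write and re-read through the io layer", {
  pair <- generate_locus_pair(synthetic_spec(seed = 14L))
  dir <- tempfile()
  paths <- write_synthetic_pair(pair, dir)
  expect_true(all(file.exists(paths)))
  expect_true(grepl("seed14", basename(paths[["fa_a"]])))
  back <- read_fasta(paths[["fa_a"]], species = "speciesA")
  expect_equal(back[["chrA"]]$seq, pair$locus_a$seq)
  ann <- read_bed(paths[["bed_a"]])
  expect_equal(as.data.frame(ann), as.data.frame(pair$annotations_a))
  hom <- read_homology(paths[["hom"]])
  expect_equal(hom$gene_a, "geneA")
})
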