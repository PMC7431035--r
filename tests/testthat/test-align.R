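test_that("local alignment handles exact, derived and degenerate cases", {
  a <- smith_waterman("ACGT", "ACGT", scoring_scheme(5, -4, 10, 1))
  expect_equal(a$score, 20)
  expect_equal(a$identity, 1.0)

  # linear-gap example: verified against the naive DP oracle
  sch <- scoring_scheme(3, -3, 2, 2)
  b <- smith_waterman("TGTTACGG", "GGTTGACTA", sch)
  expect_equal(b$score, 13)
  expect_equal(naive_local_score("TGTTACGG", "GGTTGACTA", sch), 13)

  e <- smith_waterman("AAAA", "TTTT", scoring_scheme(1, -1, 5, 1))
  expect_equal(e$score, 0)
  expect_equal(e$n_columns, 0)
})

test_that("global alignment matches trivial expectations", {
  g <- needleman_wunsch("ACGT", "ACGT")
  expect_equal(g$identity, 1.0)
  expect_false(grepl("-", g$a_gapped, fixed = TRUE))

  g2 <- needleman_wunsch("ACGT", "ACG")
  gaps <- sum(strsplit(g2$b_gapped, "")[[1]] == "-")
  expect_equal(gaps, 1L)
  expect_equal(g2$n_columns, 4L)
})

test_that("aligners agree with the naive full-matrix DP on random instances", {
  set.seed(42)
  schemes <- list(scoring_scheme(), scoring_scheme(1, -1, 3, 1),
                  scoring_scheme(3, -2, 5, 2))
  for (i in 1:120) {
    sch <- schemes[[1L + i %% 3L]]
    a <- rand_dna(sample(3:64, 1)); b <- rand_dna(sample(3:64, 1))
    expect_equal(smith_waterman(a, b, sch)$score, naive_local_score(a, b, sch))
    expect_equal(needleman_wunsch(a, b, sch)$score, naive_global_score(a, b, sch))
  }
})

test_that("alignment scores are symmetric and reconstructible", {
  set.seed(7)
  for (i in 1:25) {
    a <- rand_dna(sample(10:80, 1)); b <- rand_dna(sample(10:80, 1))
    sw_ab <- smith_waterman(a, b); sw_ba <- smith_waterman(b, a)
    expect_equal(sw_ab$score, sw_ba$score)
    nw_ab <- needleman_wunsch(a, b)
    expect_equal(nw_ab$score, needleman_wunsch(b, a)$score)
    if (sw_ab$n_columns > 0)
      expect_equal(alignment_score(sw_ab), sw_ab$score)
    expect_equal(alignment_score(nw_ab), nw_ab$score)
  }
})

test_that("waterman_eggert declumps into disjoint suboptimal alignments", {
  set.seed(11)
  blk <- rand_dna(30)
  a <- paste0(rand_dna(20), blk, rand_dna(20))
  b <- paste0(blk, rand_dna(25), blk)
  alns <- waterman_eggert(a, b, k_max = 2, min_score = 50)
  expect_length(alns, 2L)
  expect_gte(alns[[1]]$score, alns[[2]]$score)
  # non-overlapping in b
  expect_true(alns[[1]]$b_end <= alns[[2]]$b_start ||
                alns[[2]]$b_end <= alns[[1]]$b_start)
  # each alignment covers one planted copy
  for (al in alns) expect_gte(al$b_end - al$b_start, 25)

  # identical sequences, k_max = 1: single full-length self alignment
  s <- rand_dna(40)
  self <- waterman_eggert(s, s, k_max = 1)
  expect_length(self, 1L)
  expect_equal(self[[1]]$identity, 1.0)
  expect_equal(self[[1]]$n_columns, 40L)

  # unrelated 50-mers with min_score above the optimum: empty list
  a2 <- rand_dna(50); b2 <- rand_dna(50)
  best <- naive_local_score(a2, b2, scoring_scheme())
  expect_length(waterman_eggert(a2, b2, k_max = 3, min_score = best + 1), 0L)
})

test_that("declumped alignments never share an aligned residue pair", {
  set.seed(23)
  for (rep in 1:5) {
    a <- rand_dna(120); b <- paste0(substr(a, 20, 90), rand_dna(50))
    alns <- waterman_eggert(a, b, k_max = 4, min_score = 15)
    pairs <- character()
    for (al in alns) {
      ga <- strsplit(al$a_gapped, "")[[1]]; gb <- strsplit(al$b_gapped, "")[[1]]
      i <- al$a_start; j <- al$b_start
      for (k in seq_along(ga)) {
        if (ga[k] != "-" && gb[k] != "-") {
          pairs <- c(pairs, paste(i, j))
          i <- i + 1; j <- j + 1
        } else if (ga[k] != "-") i <- i + 1 else j <- j + 1
      }
    }
    expect_equal(anyDuplicated(pairs), 0L)
    sc <- vapply(alns, `[[`, numeric(1), "score")
    expect_true(all(diff(sc) <= 0))
  }
})

test_that("identity statistics follow the stated column conventions", {
  expect_equal(unname(alignment_identity(list(a_gapped = "ACGT", b_gapped = "ACGT"))),
               c(4, 4, 1.0))
  # gap column counts in the denominator only
  expect_equal(unname(alignment_identity(list(a_gapped = "AC-GT", b_gapped = "ACCGT"))),
               c(4, 5, 0.8))
  # N columns are never identical
  expect_equal(unname(alignment_identity(list(a_gapped = "ANGT", b_gapped = "AAGT"))),
               c(3, 4, 0.75))
  expect_error(alignment_identity(list(a_gapped = "ACG", b_gapped = "AC")),
               "unequal")
})

test_that("alignment scores agree with Biostrings pairwiseAlignment", {
  # independent library cross-check; Biostrings charges open+ext for the
  # first gap column, so its (open, ext) = (ours - ext, ext)
  sch <- scoring_scheme(5, -4, 16, 4)
  sub <- matrix(-4, 4, 4, dimnames = list(DNA_BASES <- c("A", "C", "G", "T"),
                                          DNA_BASES))
  diag(sub) <- 5
  set.seed(99)
  for (i in 1:10) {
    a <- rand_dna(60); b <- rand_dna(60)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                         substitutionMatrix = sub,
                                         gapOpening = 12, gapExtension = 4,
                                         scoreOnly = TRUE)
    expect_equal(smith_waterman(a, b, sch)$score, as.integer(ref))
  }
})
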