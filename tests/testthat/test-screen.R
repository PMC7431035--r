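make_pair <- function(seed, ...) generate_locus_pair(synthetic_spec(seed = seed, ...))

test_that("homolog windows follow gene spans, flanks and one-to-many rows", {
  pair <- make_pair(5L)
  loci_a <- list(chrA = pair$locus_a); loci_b <- list(chrB = pair$locus_b)
  gene_a <- pair$annotations_a[pair$annotations_a$kind == "gene", ]

  w0 <- homolog_windows(loci_a, loci_b, pair$annotations_a,
                        pair$annotations_b, pair$homology, flank = 0L)
  expect_length(w0, 1L)
  expect_equal(w0[[1]]$a$start, gene_a$start)
  expect_equal(w0[[1]]$a$end, gene_a$end)

  wbig <- homolog_windows(loci_a, loci_b, pair$annotations_a,
                          pair$annotations_b, pair$homology, flank = 10^6L)
  expect_equal(wbig[[1]]$a$start, 0L)
  expect_equal(wbig[[1]]$a$end, nchar(pair$locus_a$seq))

  hom2 <- rbind(pair$homology,
                data.frame(gene_a = "geneA", gene_b = "geneB"))
  hom2$gene_b[2] <- "geneB"  # same target twice stands in for two homologs
  expect_length(homolog_windows(loci_a, loci_b, pair$annotations_a,
                                pair$annotations_b, hom2, 0L), 2L)

  bad <- pair$homology; bad$gene_a <- "nope"
  expect_error(homolog_windows(loci_a, loci_b, pair$annotations_a,
                               pair$annotations_b, bad, 0L), "nope")
})

test_that("candidate search recovers planted elements and respects strand", {
  params <- default_params()
  pair <- make_pair(9L)
  wins <- homolog_windows(list(chrA = pair$locus_a), list(chrB = pair$locus_b),
                          pair$annotations_a, pair$annotations_b,
                          pair$homology, flank = 20000L)
  cands <- candidate_search(wins[[1]], params = params)
  expect_gte(length(cands), 1L)
  ta <- pair$truth$a
  ov <- vapply(cands, function(cc)
    interval_overlap(cc$query$start, cc$query$end, ta$start, ta$end),
    numeric(1))
  expect_gte(max(ov), 0.5 * (ta$end - ta$start))

  # unrelated random windows with a stringent floor: no candidates
  w_null <- list(a = list(chrom = "x", start = 0L, end = 500L,
                          seq = with_seed(1, random_dna(500)), gene = "gA"),
                 b = list(chrom = "y", start = 0L, end = 500L,
                          seq = with_seed(2, random_dna(500)), gene = "gB"),
                 gene_pair = c("gA", "gB"))
  expect_length(candidate_search(w_null, params = params, min_score = 400L), 0L)

  # minus-strand planting is reported with hit strand "-"
  el <- with_seed(5, random_dna(120))
  el_b <- evolve_sequence(el, 0.9, 0, seed = 6)
  wa <- paste0(with_seed(7, random_dna(300)), el, with_seed(8, random_dna(300)))
  wb <- paste0(with_seed(9, random_dna(250)), revcomp(el_b),
               with_seed(10, random_dna(250)))
  wp <- list(a = list(chrom = "a", start = 0L, end = nchar(wa), seq = wa,
                      gene = "gA"),
             b = list(chrom = "b", start = 0L, end = nchar(wb), seq = wb,
                      gene = "gB"),
             gene_pair = c("gA", "gB"))
  cands <- candidate_search(wp, params = params)
  expect_gte(length(cands), 1L)
  expect_equal(cands[[1]]$hit$strand, "-")
  expect_gte(interval_overlap(cands[[1]]$hit$start, cands[[1]]$hit$end,
                              250L, 250L + nchar(el_b)), 100L)
})

test_that("coding exclusion uses annotation overlap, then the ORF scan", {
  pair <- make_pair(11L)
  ex <- pair$annotations_a[pair$annotations_a$kind == "exon", ][1, ]
  mk_cand <- function(start, end, seq = strrep("A", end - start)) {
    cc <- crescreen:::new_candidate("c", list(chrom = "chrA", start = start,
                                              end = end, strand = "+",
                                              seq = seq),
                                    list(chrom = "chrB", start = 0L, end = 10L,
                                         strand = "+", seq = strrep("A", 10)),
                                    smith_waterman("ACGT", "ACGT"),
                                    c("geneA", "geneB"))
    cc
  }
  inside <- mk_cand(ex$start + 10L, ex$start + 80L)
  expect_false(mask_coding(inside, pair$annotations_a))
  # 1 bp overlap fails at the zero-tolerance default
  edge <- mk_cand(ex$start - 60L, ex$start + 1L)
  expect_false(mask_coding(edge, pair$annotations_a))
  outside <- mk_cand(ex$start - 80L, ex$start - 10L)
  expect_true(mask_coding(outside, pair$annotations_a))

  # no exon annotation: ORF scan takes over
  no_ann <- annotation_set()
  orf_seq <- paste0("ATG", strrep("GCT", 120), "TAA")  # 366 bp ORF
  orf_cand <- mk_cand(0L, nchar(orf_seq), orf_seq)
  expect_false(mask_coding(orf_cand, no_ann))
  plain <- mk_cand(0L, 200L, with_seed(33, random_dna(200)))
  expect_true(mask_coding(plain, no_ann))
})

test_that("repeat detection flags homopolymers and tandems, spares random", {
  r1 <- detect_repeats(strrep("A", 100))
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$start, 0L)
  expect_equal(r1$end, 100L)

  r2 <- detect_repeats(strrep("AT", 50))
  expect_equal(nrow(r2), 1L)
  expect_gte(r2$end - r2$start, 95L)

  fracs <- vapply(1:20, function(seed) {
    s <- with_seed(seed + 400, random_dna(1000))
    iv <- detect_repeats(s)
    sum(iv$end - iv$start) / 1000
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})

test_that("criterion application enforces the stated thresholds exactly", {
  th <- criteria_thresholds()
  # synthetic candidate with controllable alignment stats
  fake_cand <- function(identity, n_columns, ev) {
    n_id <- floor(identity * n_columns + 1e-9)
    ga <- paste(c(rep("A", n_id), rep("C", n_columns - n_id)), collapse = "")
    gb <- paste(c(rep("A", n_id), rep("G", n_columns - n_id)), collapse = "")
    al <- structure(list(a_start = 0L, a_end = n_columns, b_start = 0L,
                         b_end = n_columns, a_gapped = ga, b_gapped = gb,
                         score = 100L,
                         n_identical = n_id, n_columns = n_columns,
                         identity = n_id / n_columns, evalue = ev,
                         scheme = scoring_scheme()),
                    class = c("local_alignment", "cre_alignment"))
    crescreen:::new_candidate("c", list(chrom = "chrA", start = 1000L,
                                        end = 1000L + n_columns, strand = "+",
                                        seq = with_seed(3, random_dna(n_columns))),
                              list(chrom = "chrB", start = 0L,
                                   end = n_columns, strand = "+",
                                   seq = with_seed(4, random_dna(n_columns))),
                              al, c("geneA", "geneB"))
  }
  ok <- apply_criteria(fake_cand(0.70, 60L, 1e-3), th)
  expect_true(all(unlist(ok$criteria)))
  expect_equal(ok$verdict, "pass")

  low_id <- apply_criteria(fake_cand(0.619, 100L, 1e-3), th)
  expect_false(low_id$criteria$identity_length_evalue)
  expect_equal(low_id$verdict, "fail")

  short <- apply_criteria(fake_cand(0.80, 54L, 1e-3), th)
  expect_false(short$criteria$identity_length_evalue)

  # inclusive cutoff: exactly 62% over exactly 55 columns passes
  edge <- apply_criteria(fake_cand(0.62, 100L, 0.1), th)
  expect_true(edge$criteria$identity_length_evalue)

  high_e <- apply_criteria(fake_cand(0.70, 60L, 0.2), th)
  expect_false(high_e$criteria$identity_length_evalue)

  unlinked <- fake_cand(0.70, 60L, 1e-3)
  unlinked$linked_gene_pair <- c("geneA", "none")
  expect_false(apply_criteria(unlinked, th)$criteria$homolog_linked)
})

test_that("reciprocal uniqueness flags off-target copies and vacuous cases", {
  params <- default_params()
  pair <- make_pair(31L)
  res <- screen_pair(list(chrA = pair$locus_a), list(chrB = pair$locus_b),
                     pair$annotations_a, pair$annotations_b, pair$homology,
                     params = params)
  pass <- Filter(function(cc) cc$verdict == "pass", res$candidates)
  expect_gte(length(pass), 1L)
  cc <- pass[[1]]
  expect_true(isTRUE(cc$reciprocal_unique))

  # plant a second copy on an unrelated B locus: uniqueness must flip
  tb <- pair$truth$b
  copy <- evolve_sequence(substr(pair$locus_b$seq, tb$start + 1, tb$end),
                          0.95, 0, seed = 77)
  decoy <- genome_locus(paste0(with_seed(78, random_dna(400)), copy,
                               with_seed(79, random_dna(400))),
                        id = "chrB2", species = "speciesB")
  wins <- homolog_windows(list(chrA = pair$locus_a),
                          list(chrB = pair$locus_b),
                          pair$annotations_a, pair$annotations_b,
                          pair$homology, 20000L)
  expect_false(reciprocal_uniqueness(cc, list(chrB = pair$locus_b,
                                              chrB2 = decoy),
                                     wins[[1]]$b, params = params))

  # degenerate candidate with no passing hits anywhere: vacuity + warning
  junk <- cc
  junk$query$seq <- with_seed(80, random_dna(80))
  expect_warning(
    out <- reciprocal_uniqueness(junk, list(chrB = pair$locus_b),
                                 wins[[1]]$b, params = params),
    "vacuity")
  expect_true(out)
})

test_that("refinement records identity close to the local alignment", {
  params <- default_params()
  s <- with_seed(90, random_dna(150))
  cc <- crescreen:::new_candidate(
    "c", list(chrom = "a", start = 0L, end = 150L, strand = "+", seq = s),
    list(chrom = "b", start = 0L, end = 150L, strand = "+", seq = s),
    smith_waterman(s, s), c("gA", "gB"))
  cc <- refine(cc)
  expect_equal(cc$refined_identity, 1.0)

  for (seed in 1:5) {
    pair <- make_pair(seed + 50L)
    res <- screen_pair(list(chrA = pair$locus_a), list(chrB = pair$locus_b),
                       pair$annotations_a, pair$annotations_b, pair$homology,
                       params = params)
    for (cc in Filter(function(x) x$verdict == "pass", res$candidates)) {
      expect_lte(abs(cc$refined_identity - cc$alignment$identity), 0.05)
      expect_equal(cc$verdict, "pass")  # refinement never changes the verdict
    }
  }
})

test_that("the full screen is deterministic given inputs and seed", {
  pair <- make_pair(61L)
  run <- function() {
    res <- screen_pair(list(chrA = pair$locus_a), list(chrB = pair$locus_b),
                       pair$annotations_a, pair$annotations_b, pair$homology,
                       params = default_params())
    res$report
  }
  expect_identical(run(), run())
})
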