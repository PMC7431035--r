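# Synthetic ortholog locus pairs with planted conserved elements, coding
# exons, repeats and motifs, plus an exact truth set.
#
# The generator is the package's measurable stand-in for a pair of real
# genomic loci around homologous genes: a conserved noncoding element is
# planted in both copies at a controlled identity, embedded in background
# diverged far below the classifier's thresholds.

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                    c("A","C","G","T")), 1L, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

#' Specification for a synthetic ortholog locus pair
#'
#' Defaults emulate a desk-scale pair of homolog-anchored loci: 4 kb loci,
#' one 150 bp conserved element evolved to ~85% identity over background
#' diverged to ~30%, a central 2-exon gene with real open reading frames,
#' and two low-complexity repeats. `target_identity` must exceed
#' `background_identity`, and all planted features must fit in the locus
#' (checked before any sequence is produced).
#'
#' @param locus_length locus size in bp.
#' @param n_conserved_elements number of planted conserved elements.
#' @param element_length element size in bp.
#' @param target_identity expected global-alignment identity of the two
#'   element copies, in (0, 1].
#' @param background_identity background relatedness in \[0, 1). At the
#'   default 0.25 the species-B background is independent i.i.d. uniform
#'   DNA (the known null; 0.25 is the expected identity of unrelated
#'   sequence). Values above 0.25 instead evolve the species-A background,
#'   producing positionally syntenic background for sensitivity analyses.
#' @param indel_rate indel events per substituted site (lengths 1-3,
#'   geometric).
#' @param n_repeats,repeat_kind,repeat_length planted repeat tract count,
#'   kind (`"homopolymer"` or `"tandem"`), and length.
#' @param n_exons,exon_length exon count and size (multiple of 3; each exon
#'   carries a start codon, sense codons, and a stop).
#' @param planted_motifs named list `pwm_id -> list(pfm = counts, count = k)`
#'   of motifs to plant inside the first conserved element.
#' @param seed integer seed; every generator output is a pure function of
#'   (spec, seed).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(locus_length = 4000L, n_conserved_elements = 1L,
                           element_length = 150L, target_identity = 0.85,
                           background_identity = 0.25, indel_rate = 0.02,
                           n_repeats = 2L, repeat_kind = "homopolymer",
                           repeat_length = 60L,
                           n_exons = 2L, exon_length = 300L,
                           planted_motifs = list(), seed = 1L) {
  stopifnot(target_identity > 0, target_identity <= 1,
            background_identity >= 0, background_identity < 1,
            indel_rate >= 0, n_conserved_elements >= 0, n_exons >= 0,
            n_repeats >= 0)
  if (target_identity <= background_identity)
    stop("target_identity must exceed background_identity")
  if (!repeat_kind %in% c("homopolymer", "tandem"))
    stop("repeat_kind must be 'homopolymer' or 'tandem'")
  if (n_exons > 0L && exon_length %% 3L != 0L)
    stop("exon_length must be a multiple of 3 (ORF planting)")
  spec <- structure(list(
    locus_length = as.integer(locus_length),
    n_conserved_elements = as.integer(n_conserved_elements),
    element_length = as.integer(element_length),
    target_identity = target_identity,
    background_identity = background_identity,
    indel_rate = indel_rate, n_repeats = as.integer(n_repeats),
    repeat_kind = repeat_kind, repeat_length = as.integer(repeat_length),
    n_exons = as.integer(n_exons), exon_length = as.integer(exon_length),
    planted_motifs = planted_motifs, seed = as.integer(seed)),
    class = "synthetic_spec")
  layout_features(spec) # errors if features do not fit
  spec
}

# Deterministic non-overlapping feature layout (0-based half-open intervals
# in species A). Gene (with its exons) sits in the locus center; conserved
# elements and repeats are spread evenly over the flanks with a fixed
# spacer.
layout_features <- function(spec) {
  L <- spec$locus_length
  spacer <- 50L
  gene_len <- if (spec$n_exons > 0L)
    spec$n_exons * spec$exon_length + (spec$n_exons + 1L) * 100L else 0L
  flank_feats <- list()
  i <- 0L
  for (k in seq_len(spec$n_conserved_elements))
    flank_feats[[i <- i + 1L]] <- list(kind = "cre_truth",
                                       name = paste0("element", k),
                                       len = spec$element_length)
  for (k in seq_len(spec$n_repeats))
    flank_feats[[i <- i + 1L]] <- list(kind = "repeat",
                                       name = paste0("repeat", k),
                                       len = spec$repeat_length)
  total <- gene_len + sum(vapply(flank_feats, `[[`, integer(1), "len")) +
    spacer * (length(flank_feats) + 2L)
  if (total > L)
    stop(sprintf("planted features (%d bp incl. spacers) do not fit in locus_length %d",
                 total, L))
  gene_start <- (L - gene_len) %/% 2L
  gene_end <- gene_start + gene_len
  # alternate features left/right of the gene
  left <- list(); right <- list()
  for (k in seq_along(flank_feats))
    if (k %% 2L == 1L) left[[length(left) + 1L]] <- flank_feats[[k]]
    else right[[length(right) + 1L]] <- flank_feats[[k]]
  place_side <- function(feats, lo, hi) {
    out <- list()
    if (!length(feats)) return(out)
    used <- sum(vapply(feats, `[[`, integer(1), "len"))
    gap <- (hi - lo - used) %/% (length(feats) + 1L)
    pos <- lo + gap
    for (f in feats) {
      out[[length(out) + 1L]] <- c(f, list(start = pos, end = pos + f$len))
      pos <- pos + f$len + gap
    }
    out
  }
  feats <- c(place_side(left, 0L, gene_start),
             place_side(right, gene_end, L))
  exons <- list()
  if (spec$n_exons > 0L) {
    pos <- gene_start + 100L
    for (k in seq_len(spec$n_exons)) {
      exons[[k]] <- list(kind = "exon", name = paste0("exon", k),
                         start = pos, end = pos + spec$exon_length,
                         len = spec$exon_length)
      pos <- pos + spec$exon_length + 100L
    }
  }
  list(gene = if (gene_len > 0L) list(start = gene_start, end = gene_end),
       exons = exons, flank = feats)
}

#' Diverge a sequence to a target identity
#'
#' Substitutions are drawn as `Binomial(length, 1 - target_identity)` and
#' placed uniformly at distinct sites, each replaced by one of the three
#' other bases (Jukes-Cantor-style, no transition bias), so the expected
#' global-alignment identity equals `target_identity`. Indels of length 1-3
#' (geometric) are then applied at `indel_rate` events per substituted
#' site. Deterministic given `seed`.
#'
#' @param seq DNA string.
#' @param target_identity expected identity in (0, 1].
#' @param indel_rate indel events per substituted site.
#' @param seed integer seed.
#' @return the diverged sequence.
#' @export
evolve_sequence <- function(seq, target_identity, indel_rate = 0, seed = 1L) {
  stopifnot(target_identity > 0, target_identity <= 1)
  if (target_identity == 1) return(seq)
  with_seed(seed, {
    x <- seq_chars(seq)
    L <- length(x)
    nsub <- rbinom(1L, L, 1 - target_identity)
    if (nsub > 0L) {
      pos <- sample.int(L, nsub)
      for (p in pos) x[p] <- sample(setdiff(DNA_BASES, x[p]), 1L)
    }
    n_indel <- if (indel_rate > 0 && nsub > 0L)
      rbinom(1L, nsub, min(1, indel_rate)) else 0L
    if (n_indel > 0L) {
      for (k in seq_len(n_indel)) {
        len <- min(1L + rgeom(1L, 0.5), 3L)
        at <- sample.int(length(x), 1L)
        if (runif(1) < 0.5 && length(x) > len + 1L) {
          x <- x[-(at:min(at + len - 1L, length(x)))]           # deletion
        } else {
          ins <- sample(DNA_BASES, len, replace = TRUE)          # insertion
          x <- append(x, ins, after = at)
        }
      }
    }
    paste(x, collapse = "")
  })
}

#' Plant a PWM-sampled motif instance into a sequence
#'
#' Each motif column is sampled from the column distribution of the count
#' matrix; the instance is reverse-complemented when `strand` is `"-"`.
#'
#' @param seq DNA string.
#' @param pfm_counts 4 x width count matrix (rows A,C,G,T).
#' @param position 0-based offset at which the instance is written.
#' @param strand `"+"` or `"-"`.
#' @param seed integer seed.
#' @return list with the modified `seq` and the planted `instance`.
#' @export
plant_motif <- function(seq, pfm_counts, position, strand = "+", seed = 1L) {
  w <- ncol(pfm_counts)
  if (position < 0L || position + w > nchar(seq))
    stop("motif does not fit at position ", position)
  inst <- with_seed(seed, {
    paste(vapply(seq_len(w), function(j) {
      p <- pfm_counts[, j]
      if (sum(p) <= 0) stop("all-zero PFM column ", j)
      sample(DNA_BASES, 1L, prob = p / sum(p))
    }, character(1)), collapse = "")
  })
  if (strand == "-") inst <- revcomp(inst)
  out <- paste0(substr(seq, 1L, position), inst,
                substr(seq, position + w + 1L, nchar(seq)))
  list(seq = out, instance = inst)
}

random_orf <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 6L)
  ncod <- len %/% 3L - 2L
  paste0("ATG", paste(sample(SENSE_CODONS, ncod, replace = TRUE),
                      collapse = ""), "TAA")
}

repeat_tract <- function(kind, len, unit_seed) {
  if (kind == "homopolymer") {
    base <- sample(DNA_BASES, 1L)
    paste(rep(base, len), collapse = "")
  } else {
    unit <- paste(sample(DNA_BASES, 2L), collapse = "")
    substr(paste(rep(unit, ceiling(len / 2)), collapse = ""), 1L, len)
  }
}

#' Generate an ortholog locus pair with exact truth
#'
#' Builds species-A sequence from i.i.d. uniform background with the
#' spec's features planted (central gene with ORF exons, conserved
#' elements, repeat tracts, motifs inside the first element), then derives
#' species B segment-by-segment: conserved elements are evolved at
#' `target_identity`, all other sequence at `background_identity`; exon and
#' repeat tracts in B are re-planted so both annotation sets carry them.
#' Every planted feature is recorded once in the truth set with exact
#' coordinates, and each element pair's realized identity is measured post
#' hoc by global alignment.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_pair` with `locus_a`, `locus_b`,
#'   `annotations_a`, `annotations_b`, `homology`, `truth` (an
#'   [annotation_set()] per species plus per-element `realized_identity`).
#' @export
generate_locus_pair <- function(spec) {
  lay <- layout_features(spec)
  with_seed(spec$seed, {
    L <- spec$locus_length
    a <- seq_chars(random_dna(L))

    # overwrite feature sequence in A
    for (ex in lay$exons) {
      orf <- seq_chars(random_orf(ex$len))
      a[(ex$start + 1L):ex$end] <- orf
    }
    for (f in lay$flank) if (f$kind == "repeat") {
      a[(f$start + 1L):f$end] <- seq_chars(repeat_tract(spec$repeat_kind, f$len))
    }
    a <- paste(a, collapse = "")

    # motifs go inside the first conserved element
    motif_truth <- list()
    els <- Filter(function(f) f$kind == "cre_truth", lay$flank)
    if (length(spec$planted_motifs)) {
      if (!length(els)) stop("cannot plant motifs without a conserved element")
      el <- els[[1L]]
      off <- el$start + 10L
      for (pid in names(spec$planted_motifs)) {
        pm <- spec$planted_motifs[[pid]]
        for (k in seq_len(pm$count %||% 1L)) {
          w <- ncol(pm$pfm)
          if (off + w > el$end - 5L) stop("planted motifs do not fit in element")
          res <- plant_motif(a, pm$pfm, off, pm$strand %||% "+",
                             seed = derive_seed(spec$seed, paste0("motif", pid, k)))
          a <- res$seq
          motif_truth[[length(motif_truth) + 1L]] <-
            list(pwm_id = pid, start = off, end = off + w,
                 strand = pm$strand %||% "+", instance = res$instance)
          off <- off + w + 5L
        }
      }
    }

    # species-A annotations
    ann <- list()
    add <- function(lst, start, end, kind, name)
      c(lst, list(data.frame(chrom = "chrA", start = start, end = end,
                             strand = "+", kind = kind, name = name)))
    if (!is.null(lay$gene))
      ann <- add(ann, lay$gene$start, lay$gene$end, "gene", "geneA")
    for (ex in lay$exons) ann <- add(ann, ex$start, ex$end, "exon", ex$name)
    for (f in lay$flank) ann <- add(ann, f$start, f$end, f$kind, f$name)
    ann_a <- do.call(rbind, ann) %||%
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), kind = character(), name = character())
    ann_a <- annotation_set(ann_a$chrom, ann_a$start, ann_a$end,
                            ann_a$strand, ann_a$kind, ann_a$name)

    # --- build species B segment by segment ------------------------------
    # segment map of A in genomic order
    segs <- list(); pos <- 0L
    feats <- lay$flank
    if (!is.null(lay$gene))
      feats <- c(feats, list(list(kind = "gene", name = "geneB",
                                  start = lay$gene$start, end = lay$gene$end)))
    feats <- feats[order(vapply(feats, `[[`, integer(1), "start"))]
    for (f in feats) {
      if (f$start > pos)
        segs <- c(segs, list(list(kind = "background", start = pos, end = f$start)))
      segs <- c(segs, list(f))
      pos <- f$end
    }
    if (pos < L) segs <- c(segs, list(list(kind = "background", start = pos, end = L)))

    b_parts <- character(); b_pos <- 0L
    ann_b_rows <- list(); truth_rows_a <- list(); truth_rows_b <- list()
    realized <- numeric(); pair_ids <- character()
    el_i <- 0L
    for (s in segs) {
      seg_seq <- subseq0(a, s$start, s$end)
      sseed <- derive_seed(spec$seed, paste0("seg", s$start))
      if (s$kind == "cre_truth") {
        el_i <- el_i + 1L
        bseq <- evolve_sequence(seg_seq, spec$target_identity,
                                spec$indel_rate, sseed)
        aln <- needleman_wunsch(seg_seq, bseq)
        realized <- c(realized, aln$identity)
        pair_ids <- c(pair_ids, s$name)
        truth_rows_a[[el_i]] <- data.frame(chrom = "chrA", start = s$start,
                                           end = s$end, strand = "+",
                                           kind = "cre_truth", name = s$name)
        truth_rows_b[[el_i]] <- data.frame(chrom = "chrB", start = b_pos,
                                           end = b_pos + nchar(bseq),
                                           strand = "+", kind = "cre_truth",
                                           name = s$name)
      } else if (s$kind == "gene") {
        # fresh gene body: background-diverged introns, fresh ORF exons
        bseq <- evolve_sequence(seg_seq, max(spec$background_identity, 0.01),
                                spec$indel_rate, sseed)
        bchars <- seq_chars(bseq)
        gstart_b <- b_pos
        for (ex in lay$exons) {
          rel <- ex$start - s$start
          if (rel + ex$len <= length(bchars)) {
            bchars[(rel + 1L):(rel + ex$len)] <- seq_chars(random_orf(ex$len))
            ann_b_rows <- c(ann_b_rows, list(data.frame(
              chrom = "chrB", start = gstart_b + rel, end = gstart_b + rel + ex$len,
              strand = "+", kind = "exon", name = ex$name)))
          }
        }
        bseq <- paste(bchars, collapse = "")
        ann_b_rows <- c(ann_b_rows, list(data.frame(
          chrom = "chrB", start = gstart_b, end = gstart_b + nchar(bseq),
          strand = "+", kind = "gene", name = "geneB")))
      } else if (s$kind == "repeat") {
        bseq <- repeat_tract(spec$repeat_kind, s$end - s$start)
        ann_b_rows <- c(ann_b_rows, list(data.frame(
          chrom = "chrB", start = b_pos, end = b_pos + nchar(bseq),
          strand = "+", kind = "repeat", name = s$name)))
      } else {
        bseq <- if (spec$background_identity <= 0.25) random_dna(s$end - s$start)
        else evolve_sequence(seg_seq, spec$background_identity,
                             spec$indel_rate, sseed)
      }
      b_parts <- c(b_parts, bseq)
      b_pos <- b_pos + nchar(bseq)
    }
    b <- paste(b_parts, collapse = "")

    ann_b <- do.call(rbind, ann_b_rows) %||%
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), kind = character(), name = character())
    ann_b <- annotation_set(ann_b$chrom, ann_b$start, ann_b$end,
                            ann_b$strand, ann_b$kind, ann_b$name)

    truth_a <- do.call(rbind, truth_rows_a)
    truth_b <- do.call(rbind, truth_rows_b)
    mk_truth <- function(x) if (is.null(x)) annotation_set() else
      annotation_set(x$chrom, x$start, x$end, x$strand, x$kind, x$name)

    homology <- if (!is.null(lay$gene))
      data.frame(gene_a = "geneA", gene_b = "geneB", stringsAsFactors = FALSE)
    else data.frame(gene_a = character(), gene_b = character())
    class(homology) <- c("homology_table", "data.frame")

    structure(list(
      locus_a = genome_locus(a, id = "chrA", species = "speciesA"),
      locus_b = genome_locus(b, id = "chrB", species = "speciesB"),
      annotations_a = ann_a, annotations_b = ann_b,
      homology = homology,
      truth = list(a = mk_truth(truth_a), b = mk_truth(truth_b),
                   realized_identity = setNames(realized, pair_ids),
                   motifs = motif_truth),
      spec = spec), class = "synthetic_pair")
  })
}

#' Write a synthetic pair to disk
#'
#' Emits FASTA, BED (annotations and truth), and the homology TSV using
#' the package's dialects; filenames carry the generator seed.
#'
#' @param pair a `synthetic_pair`.
#' @param dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
write_synthetic_pair <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- pair$spec$seed
  paths <- c(
    fa_a = file.path(dir, sprintf("speciesA_seed%d.fasta", s)),
    fa_b = file.path(dir, sprintf("speciesB_seed%d.fasta", s)),
    bed_a = file.path(dir, sprintf("speciesA_seed%d.bed", s)),
    bed_b = file.path(dir, sprintf("speciesB_seed%d.bed", s)),
    truth_a = file.path(dir, sprintf("truthA_seed%d.bed", s)),
    truth_b = file.path(dir, sprintf("truthB_seed%d.bed", s)),
    hom = file.path(dir, sprintf("homology_seed%d.tsv", s)))
  write_fasta(list(pair$locus_a), paths[["fa_a"]])
  write_fasta(list(pair$locus_b), paths[["fa_b"]])
  write_bed(pair$annotations_a, paths[["bed_a"]])
  write_bed(pair$annotations_b, paths[["bed_b"]])
  write_bed(pair$truth$a, paths[["truth_a"]])
  write_bed(pair$truth$b, paths[["truth_b"]])
  write_homology(pair$homology, paths[["hom"]])
  invisible(paths)
}
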