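# The conservation screen: homolog-anchored candidate search, the
# four-criterion classifier, reciprocal uniqueness, and global refinement.

#' Conservation criteria thresholds
#'
#' Defaults implement the screen's selection rule: candidate matches must
#' reach at least 62% identity over at least 55 alignment columns with
#' E-value at most 0.1, inside windows of +/- 20 kb around homologous
#' genes. The identity cutoff is inclusive (>= 62%).
#'
#' @param min_identity minimum identity fraction (inclusive).
#' @param min_length minimum alignment length in columns (gapped span).
#' @param max_evalue maximum Karlin-Altschul E-value.
#' @param flank window half-width around homolog genes, bp.
#' @param max_exon_overlap maximum tolerated overlap (bp) with an annotated
#'   exon before a candidate is called coding.
#' @param max_repeat_fraction fraction of the candidate span that may be
#'   repeat-flagged before criterion 4 fails.
#' @return object of class `criteria_thresholds`.
#' @export
criteria_thresholds <- function(min_identity = 0.62, min_length = 55L,
                                max_evalue = 0.1, flank = 20000L,
                                max_exon_overlap = 0L,
                                max_repeat_fraction = 0.5) {
  stopifnot(min_identity > 0, min_identity < 1, min_length > 0,
            max_evalue > 0, flank >= 0)
  structure(list(min_identity = min_identity,
                 min_length = as.integer(min_length),
                 max_evalue = max_evalue, flank = as.integer(flank),
                 max_exon_overlap = as.integer(max_exon_overlap),
                 max_repeat_fraction = max_repeat_fraction),
            class = "criteria_thresholds")
}

#' Paired search windows around homologous genes
#'
#' One window pair per (gene_a, gene_b) homology combination; a gene
#' mapped to several partner homologs yields several pairs. Each window is
#' the gene span extended by `flank` on both sides, clipped to the locus.
#'
#' @param loci_a,loci_b named lists of `genome_locus` (names = chrom).
#' @param annotations_a,annotations_b [annotation_set()]s containing the
#'   gene intervals.
#' @param homology a `homology_table`.
#' @param flank half-width in bp.
#' @return list of window pairs; each has `a` and `b` window descriptors
#'   (chrom, start, end, seq) and the `gene_pair`.
#' @export
homolog_windows <- function(loci_a, loci_b, annotations_a, annotations_b,
                            homology, flank = 20000L) {
  gene_window <- function(ann, loci, gene_id) {
    g <- ann[ann$kind == "gene" & ann$name == gene_id, , drop = FALSE]
    if (nrow(g) == 0L) stop("unresolvable gene id: ", gene_id)
    g <- g[1L, ]
    locus <- loci[[g$chrom]]
    if (is.null(locus)) stop("gene ", gene_id, " on unknown chrom ", g$chrom)
    s <- max(0L, g$start - flank)
    e <- min(nchar(locus$seq), g$end + flank)
    list(chrom = g$chrom, start = s, end = e,
         seq = subseq0(locus$seq, s, e), gene = gene_id)
  }
  out <- list()
  for (i in seq_len(nrow(homology))) {
    wa <- gene_window(annotations_a, loci_a, homology$gene_a[i])
    wb <- gene_window(annotations_b, loci_b, homology$gene_b[i])
    out[[length(out) + 1L]] <- list(a = wa, b = wb,
                                    gene_pair = c(homology$gene_a[i],
                                                  homology$gene_b[i]))
  }
  out
}

#' Hard-mask repeats in a sequence
#'
#' Replaces bases covered by [detect_repeats()] intervals (and by annotated
#' `repeat` intervals, when supplied) with `N`. The screen masks window
#' sequences before alignment, as genome-search tools do, so repeat tracts
#' shared between species cannot anchor or bridge candidate alignments;
#' the repeat criterion remains as a backstop for diverged repeats.
#'
#' @param seq DNA string.
#' @param annotations optional [annotation_set()] with `repeat` intervals.
#' @param offset 0-based locus position of `seq[1]`, used to map annotation
#'   coordinates into the sequence.
#' @return the masked sequence.
#' @export
mask_repeats <- function(seq, annotations = NULL, offset = 0L) {
  L <- nchar(seq)
  iv <- detect_repeats(seq)
  if (!is.null(annotations)) {
    rep_ann <- annotations[annotations$kind == "repeat", , drop = FALSE]
    if (nrow(rep_ann)) {
      s <- pmax(rep_ann$start - offset, 0L)
      e <- pmin(rep_ann$end - offset, L)
      keep <- e > s
      iv <- rbind(iv, data.frame(start = s[keep], end = e[keep]))
    }
  }
  if (!nrow(iv)) return(seq)
  x <- seq_chars(seq)
  for (i in seq_len(nrow(iv)))
    x[(iv$start[i] + 1L):iv$end[i]] <- "N"
  paste(x, collapse = "")
}

new_candidate <- function(id, query, hit, alignment, gene_pair) {
  structure(list(
    id = id, query = query, hit = hit, alignment = alignment,
    linked_gene_pair = gene_pair,
    criteria = list(homolog_linked = NA, identity_length_evalue = NA,
                    noncoding = NA, nonrepetitive = NA),
    reciprocal_unique = "untested", refined_identity = NULL,
    refined_alignment = NULL, tfbs_hits = NULL, verdict = "unclassified"),
    class = "candidate_cre")
}

#' @export
print.candidate_cre <- function(x, ...) {
  cat(sprintf("candidate %s: %s:[%d,%d) ~ %s:[%d,%d)%s  score %d, id %.1f%%, E %.3g\n",
              x$id, x$query$chrom, x$query$start, x$query$end,
              x$hit$chrom, x$hit$start, x$hit$end, x$hit$strand,
              x$alignment$score, 100 * x$alignment$identity,
              x$alignment$evalue))
  crit <- unlist(x$criteria)
  cat("  criteria:", paste(names(crit), crit, sep = "=", collapse = " "),
      "\n  reciprocal:", x$reciprocal_unique, " verdict:", x$verdict, "\n")
  invisible(x)
}

#' Declumped candidate search within a window pair
#'
#' Runs Waterman-Eggert declumped local alignment of the two windows on
#' both strands of the B window (the better strand is kept per alignment),
#' attaches E-values, and wraps each alignment as a candidate carrying the
#' window's homolog gene pair. Because both strands are searched, E-values
#' are computed over the doubled search space `m x 2n`. The score floor
#' defaults to the score at which `E = prefilter_evalue` for this search
#' space, so clearly insignificant alignments are never enumerated.
#'
#' @param window_pair one element of [homolog_windows()].
#' @param scheme a [scoring_scheme()].
#' @param params `karlin_params` used for E-values.
#' @param k_max maximum alignments per strand.
#' @param prefilter_evalue E-value floor used to derive `min_score`.
#' @param min_score override for the minimum alignment score.
#' @param repeat_mask hard-mask repeats in both windows before aligning
#'   (see [mask_repeats()]).
#' @param annotations_a,annotations_b optional annotation sets whose
#'   `repeat` intervals are included in the mask.
#' @return list of `candidate_cre` (criteria unfilled).
#' @export
candidate_search <- function(window_pair, scheme = scoring_scheme(),
                             params, k_max = 10L, prefilter_evalue = 1.0,
                             min_score = NULL, repeat_mask = TRUE,
                             annotations_a = NULL, annotations_b = NULL) {
  wa <- window_pair$a; wb <- window_pair$b
  m <- nchar(wa$seq); n <- nchar(wb$seq)
  stopifnot(m > 0L, n > 0L)
  if (is.null(min_score))
    min_score <- max(2L * scheme$match,
                     score_for_evalue(prefilter_evalue, m, 2 * n, params))
  aseq_m <- if (repeat_mask) mask_repeats(wa$seq, annotations_a, wa$start)
            else wa$seq
  bseq_m <- if (repeat_mask) mask_repeats(wb$seq, annotations_b, wb$start)
            else wb$seq
  hits <- list()
  for (strand in c("+", "-")) {
    bseq <- if (strand == "+") bseq_m else revcomp(bseq_m)
    alns <- waterman_eggert(aseq_m, bseq, scheme, k_max, min_score)
    for (al in alns) {
      b_start <- al$b_start; b_end <- al$b_end
      if (strand == "-") { tmp <- b_start; b_start <- n - b_end; b_end <- n - tmp }
      al$evalue <- evalue(al$score, m, 2 * n, params)
      hits[[length(hits) + 1L]] <- list(al = al, strand = strand,
                                        b_start = b_start, b_end = b_end)
    }
  }
  if (!length(hits)) return(list())
  hits <- hits[order(-vapply(hits, function(h) h$al$score, numeric(1)))]
  hits <- head(hits, k_max)
  lapply(seq_along(hits), function(i) {
    h <- hits[[i]]
    query <- list(chrom = wa$chrom, start = wa$start + h$al$a_start,
                  end = wa$start + h$al$a_end, strand = "+",
                  seq = subseq0(wa$seq, h$al$a_start, h$al$a_end))
    hit <- list(chrom = wb$chrom, start = wb$start + h$b_start,
                end = wb$start + h$b_end, strand = h$strand,
                seq = subseq0(wb$seq, h$b_start, h$b_end))
    new_candidate(sprintf("%s_%s_c%02d", wa$gene, wb$gene, i),
                  query, hit, h$al, window_pair$gene_pair)
  })
}

# longest open reading frame (ATG..stop, same frame) on either strand, bp
longest_orf <- function(seq) {
  best <- 0L
  for (s in c(seq, revcomp(seq))) {
    x <- seq_chars(s); L <- length(x)
    if (L < 6L) next
    codon_at <- function(i) paste(x[i:(i + 2L)], collapse = "")
    for (frame in 0:2) {
      starts <- integer(); i <- frame + 1L
      open_at <- NA_integer_
      while (i + 2L <= L) {
        cod <- codon_at(i)
        if (is.na(open_at) && cod == "ATG") open_at <- i
        if (!is.na(open_at) && cod %in% c("TAA", "TAG", "TGA")) {
          best <- max(best, i + 2L - open_at + 1L)
          open_at <- NA_integer_
        }
        i <- i + 3L
      }
    }
  }
  best
}

#' Coding-exclusion test (criterion 3)
#'
#' A candidate is non-coding iff its species-A interval overlaps annotated
#' exons by at most `max_exon_overlap` bp (default 0: any overlap fails).
#' When the annotation set contains no exons at all, an open-reading-frame
#' scan (ORF of at least `min_orf` bp on either strand within the
#' candidate) vetoes instead.
#'
#' @param candidate a `candidate_cre`.
#' @param annotations species-A [annotation_set()].
#' @param thresholds a [criteria_thresholds()].
#' @param min_orf ORF veto length in bp.
#' @return logical: `TRUE` if non-coding.
#' @export
mask_coding <- function(candidate, annotations,
                        thresholds = criteria_thresholds(), min_orf = 300L) {
  ex <- annotations[annotations$kind == "exon", , drop = FALSE]
  q <- candidate$query
  if (nrow(ex)) {
    ov <- vapply(seq_len(nrow(ex)), function(i)
      interval_overlap(q$start, q$end, ex$start[i], ex$end[i]), numeric(1))
    return(all(ov <= thresholds$max_exon_overlap))
  }
  longest_orf(q$seq) < min_orf
}

#' Low-complexity and tandem repeat detection
#'
#' Flags (a) windows whose base-composition Shannon entropy falls below
#' `entropy_threshold` bits and (b) tandem arrays of at least `min_copies`
#' consecutive copies of a unit of period at most `max_period` spanning at
#' least `min_span` bp. Overlapping or adjacent intervals are merged.
#'
#' @param seq DNA string (>= `window` bp for the entropy component).
#' @param window sliding window width in bp.
#' @param entropy_threshold entropy cutoff in bits (max 2 for DNA).
#' @param max_period largest tandem unit length considered.
#' @param min_copies minimum consecutive copies.
#' @param min_span minimum tandem span in bp.
#' @return data.frame of 0-based half-open `start`, `end` intervals.
#' @export
detect_repeats <- function(seq, window = 16L, entropy_threshold = 1.0,
                           max_period = 6L, min_copies = 4L, min_span = 8L) {
  x <- seq_chars(seq); L <- length(x)
  flagged <- data.frame(start = integer(), end = integer())
  # (a) sliding-window entropy
  if (L >= window) {
    ind <- vapply(DNA_BASES, function(b) cumsum(x == b), numeric(L))
    ind <- rbind(0, ind)
    n_win <- L - window + 1L
    counts <- ind[(window + 1L):(L + 1L), , drop = FALSE] -
      ind[1:n_win, , drop = FALSE]
    p <- counts / window
    ent <- -rowSums(ifelse(p > 0, p * log2(p), 0))
    low <- which(ent < entropy_threshold)
    if (length(low))
      flagged <- rbind(flagged, data.frame(start = low - 1L,
                                           end = low - 1L + window))
  }
  # (b) tandem arrays
  for (p in seq_len(min(max_period, L %/% 2L))) {
    same <- x[(p + 1L):L] == x[1:(L - p)]
    r <- rle(same)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      span <- r$lengths[i] + p           # total bp covered by the array
      if (span >= min_copies * p && span >= min_span)
        flagged <- rbind(flagged,
                         data.frame(start = starts[i] - 1L,
                                    end = starts[i] - 1L + span))
    }
  }
  merge_intervals(flagged)
}

repeat_flagged_fraction <- function(candidate, annotations) {
  q <- candidate$query
  span <- q$end - q$start
  det <- detect_repeats(q$seq)
  iv <- data.frame(start = q$start + det$start, end = q$start + det$end)
  rep_ann <- annotations[annotations$kind == "repeat", , drop = FALSE]
  if (nrow(rep_ann))
    iv <- rbind(iv, data.frame(start = pmax(rep_ann$start, q$start),
                               end = pmin(rep_ann$end, q$end)))
  iv <- iv[iv$end > iv$start, , drop = FALSE]
  if (!nrow(iv)) return(0)
  m <- merge_intervals(iv)
  m$start <- pmax(m$start, q$start); m$end <- pmin(m$end, q$end)
  sum(pmax(0L, m$end - m$start)) / span
}

#' Apply the four conservation criteria
#'
#' Fills the candidate's per-criterion booleans: (1) linkage to a homolog
#' gene pair; (2) identity >= `min_identity` AND alignment columns >=
#' `min_length` AND E-value <= `max_evalue`; (3) non-coding per
#' [mask_coding()]; (4) non-repetitive (at most `max_repeat_fraction` of
#' the span repeat-flagged). The verdict is the conjunction, with
#' reciprocal uniqueness still `"untested"`.
#'
#' @param candidate a `candidate_cre` with alignment and E-value.
#' @param thresholds a [criteria_thresholds()].
#' @param annotations_a species-A [annotation_set()].
#' @return the classified `candidate_cre`.
#' @export
apply_criteria <- function(candidate, thresholds = criteria_thresholds(),
                           annotations_a = annotation_set()) {
  al <- candidate$alignment
  if (is.na(al$evalue)) stop("candidate has no E-value; run candidate_search")
  crit <- list(
    homolog_linked = all(candidate$linked_gene_pair != "none"),
    identity_length_evalue = !is.na(al$identity) &&
      al$identity >= thresholds$min_identity &&
      al$n_columns >= thresholds$min_length &&
      al$evalue <= thresholds$max_evalue,
    noncoding = mask_coding(candidate, annotations_a, thresholds),
    nonrepetitive = repeat_flagged_fraction(candidate, annotations_a) <=
      thresholds$max_repeat_fraction)
  candidate$criteria <- crit
  candidate$verdict <- if (all(unlist(crit))) "pass" else "fail"
  if (candidate$verdict == "fail")
    attr(candidate, "failed") <- names(crit)[!unlist(crit)]
  candidate
}

#' Reciprocal uniqueness against the full partner locus set
#'
#' Searches the candidate's species-A sequence against every species-B
#' locus in overlapping tiles with the same declumped aligner. The
#' candidate is reciprocally unique iff every hit that itself passes the
#' criterion-2 thresholds (identity, length, E-value computed over the
#' whole searched space, both strands) lies inside the homologous gene's
#' window. A
#' candidate with no criterion-passing hit anywhere is unique by vacuity
#' (with a warning).
#'
#' @param candidate a `candidate_cre` that passed the four criteria.
#' @param loci_b named list of species-B `genome_locus`.
#' @param homolog_window_b the B window descriptor of the candidate's
#'   window pair.
#' @param scheme a [scoring_scheme()].
#' @param params `karlin_params`.
#' @param thresholds a [criteria_thresholds()].
#' @param tile tile width in bp (tiles overlap by the query length).
#' @return logical.
#' @export
reciprocal_uniqueness <- function(candidate, loci_b, homolog_window_b,
                                  scheme = scoring_scheme(), params,
                                  thresholds = criteria_thresholds(),
                                  tile = 2000L) {
  qseq <- mask_repeats(candidate$query$seq)
  qlen <- nchar(qseq)
  n_total <- 2 * sum(vapply(loci_b, function(l) nchar(l$seq), numeric(1)))
  min_score <- score_for_evalue(thresholds$max_evalue, qlen, n_total, params)
  any_hit <- FALSE
  for (chrom in names(loci_b)) {
    lseq <- mask_repeats(loci_b[[chrom]]$seq)
    L <- nchar(lseq)
    step <- max(tile - qlen, qlen)
    tstarts <- unique(c(seq(0L, max(0L, L - tile), by = step),
                        max(0L, L - tile)))
    for (ts in tstarts) {
      te <- min(L, ts + tile)
      for (strand in c("+", "-")) {
        sub <- subseq0(lseq, ts, te)
        if (strand == "-") sub <- revcomp(sub)
        alns <- waterman_eggert(qseq, sub, scheme, k_max = 5L,
                                min_score = min_score)
        for (al in alns) {
          st <- alignment_identity(al)
          ev <- evalue(al$score, qlen, n_total, params)
          passes <- !is.na(st[["identity"]]) &&
            st[["identity"]] >= thresholds$min_identity &&
            st[["n_columns"]] >= thresholds$min_length &&
            ev <= thresholds$max_evalue
          if (!passes) next
          any_hit <- TRUE
          hs <- al$b_start; he <- al$b_end
          if (strand == "-") { tmp <- hs; hs <- (te - ts) - he; he <- (te - ts) - tmp }
          abs_s <- ts + hs; abs_e <- ts + he
          inside <- chrom == homolog_window_b$chrom &&
            abs_s >= homolog_window_b$start && abs_e <= homolog_window_b$end
          if (!inside) return(FALSE)
        }
      }
    }
  }
  if (!any_hit)
    warning("candidate ", candidate$id,
            ": no criterion-passing hit anywhere in species B; ",
            "reciprocally unique by vacuity")
  TRUE
}

#' Global refinement of a passing candidate
#'
#' Globally aligns the two matched intervals (hit sequence oriented to the
#' candidate strand), records the refined identity and keeps the aligned
#' block structure for binding-site mapping. Refinement never changes the
#' verdict.
#'
#' @param candidate a passing `candidate_cre`.
#' @param scheme a [scoring_scheme()].
#' @return the candidate with `refined_identity` and `refined_alignment`.
#' @export
refine <- function(candidate, scheme = scoring_scheme()) {
  hseq <- candidate$hit$seq
  if (candidate$hit$strand == "-") hseq <- revcomp(hseq)
  ga <- needleman_wunsch(candidate$query$seq, hseq, scheme)
  candidate$refined_alignment <- ga
  candidate$refined_identity <- ga$identity
  candidate
}

#' Run the full conservation screen on a locus pair
#'
#' Orchestrates the stages in order: homolog windows, declumped candidate
#' search, four-criterion classification, reciprocal uniqueness (for
#' candidates passing all four), and global refinement of passing
#' candidates.
#'
#' @param loci_a,loci_b named lists of `genome_locus`.
#' @param annotations_a,annotations_b [annotation_set()]s.
#' @param homology a `homology_table`.
#' @param thresholds a [criteria_thresholds()].
#' @param scheme a [scoring_scheme()].
#' @param params optional `karlin_params`; when `NULL`, calibrated
#'   empirically (and cached) at a simulated length matched to the window
#'   scale (capped at 2 kb).
#' @param k_max maximum candidates per window pair.
#' @param calib_seed seed for the E-value calibration.
#' @param verbose log one line per candidate per stage.
#' @return list with `candidates` (classified `candidate_cre` objects) and
#'   `report` (data.frame).
#' @export
screen_pair <- function(loci_a, loci_b, annotations_a, annotations_b,
                        homology, thresholds = criteria_thresholds(),
                        scheme = scoring_scheme(), params = NULL,
                        k_max = 10L, calib_seed = 1L, verbose = FALSE) {
  wins <- homolog_windows(loci_a, loci_b, annotations_a, annotations_b,
                          homology, thresholds$flank)
  if (is.null(params)) {
    wlen <- if (length(wins))
      max(vapply(wins, function(w) max(w$a$end - w$a$start,
                                       w$b$end - w$b$start), numeric(1)))
    else 500
    calib_len <- max(250L, min(2000L, as.integer(wlen)))
    params <- gapped_params(scheme, background_model(), seq_len = calib_len,
                            n_sims = 500L, seed = calib_seed)
  }
  candidates <- list()
  for (wp in wins) {
    cands <- candidate_search(wp, scheme, params, k_max,
                              annotations_a = annotations_a,
                              annotations_b = annotations_b)
    for (cc in cands) {
      cc <- apply_criteria(cc, thresholds, annotations_a)
      if (verbose)
        message(sprintf("[criteria] %s verdict=%s", cc$id, cc$verdict))
      if (cc$verdict == "pass") {
        cc$reciprocal_unique <- reciprocal_uniqueness(
          cc, loci_b, wp$b, scheme, params, thresholds)
        if (!isTRUE(cc$reciprocal_unique)) cc$verdict <- "fail"
        if (verbose)
          message(sprintf("[reciprocal] %s unique=%s", cc$id,
                          cc$reciprocal_unique))
      }
      if (cc$verdict == "pass") cc <- refine(cc, scheme)
      candidates[[length(candidates) + 1L]] <- cc
    }
  }
  list(candidates = candidates, report = candidates_report(candidates))
}
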