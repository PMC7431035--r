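# Local and global affine-gap alignment with identity statistics.
#
# The dynamic programming core lives in src/alignment.cpp; this file defines
# the user-facing scoring scheme, the alignment S3 class and its statistics.

#' Alignment scoring scheme
#'
#' Integer match/mismatch scores and affine gap penalties. The default
#' (`+5/-4`, gap open 16, gap extend 4) mirrors the DNA defaults of the
#' EDNAFULL matrix with Matcher-like gap costs. A gap of length L costs
#' `gap_open + (L - 1) * gap_extend`.
#'
#' @param match positive integer score for a match.
#' @param mismatch non-positive integer score for a mismatch (`N` against
#'   anything scores as a mismatch).
#' @param gap_open non-negative penalty for the first column of a gap.
#' @param gap_extend non-negative penalty for each further gap column.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 5L, mismatch = -4L,
                           gap_open = 16L, gap_extend = 4L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (match <= 0L) stop("match score must be positive")
  if (mismatch > 0L) stop("mismatch score must be <= 0")
  if (gap_open < 0L || gap_extend < 0L) stop("gap penalties must be >= 0")
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring scheme: match %+d, mismatch %+d, gap open %d, gap extend %d\n",
              x$match, x$mismatch, x$gap_open, x$gap_extend))
  invisible(x)
}

as_seq <- function(x) {
  if (inherits(x, "genome_locus")) x$seq
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a single sequence string or a genome_locus")
}

new_alignment <- function(raw, scheme, kind) {
  stats <- alignment_identity(list(a_gapped = raw$a_gapped,
                                   b_gapped = raw$b_gapped))
  structure(list(
    a_start = raw$a_start, a_end = raw$a_end,
    b_start = raw$b_start, b_end = raw$b_end,
    a_gapped = raw$a_gapped, b_gapped = raw$b_gapped,
    score = raw$score,
    n_identical = stats[["n_identical"]],
    n_columns = stats[["n_columns"]],
    identity = stats[["identity"]],
    evalue = NA_real_,
    scheme = scheme),
    class = c(kind, "cre_alignment"))
}

empty_alignment <- function(scheme) {
  structure(list(a_start = 0L, a_end = 0L, b_start = 0L, b_end = 0L,
                 a_gapped = "", b_gapped = "", score = 0L,
                 n_identical = 0L, n_columns = 0L, identity = NA_real_,
                 evalue = NA_real_, scheme = scheme),
            class = c("local_alignment", "cre_alignment"))
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Exact affine-gap Smith-Waterman. Traceback ties are broken
#' deterministically: diagonal, then gap in `b`, then gap in `a`. When every
#' cell is non-positive the empty alignment (score 0) is returned.
#'
#' @param a,b sequence strings (or `genome_locus` objects).
#' @param scheme a [scoring_scheme()].
#' @return a `local_alignment` with 0-based half-open intervals into `a` and
#'   `b`, gapped strings, score and identity statistics.
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme()) {
  a <- as_seq(a); b <- as_seq(b)
  res <- cpp_local_align(a, b, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend, 1L, 1L)
  if (length(res) == 0L) return(empty_alignment(scheme))
  new_alignment(res[[1L]], scheme, "local_alignment")
}

#' Declumped suboptimal local alignments (Waterman-Eggert)
#'
#' Returns up to `k_max` local alignments in non-increasing score order.
#' After each alignment is reported its aligned residue pairs are forbidden
#' (declumped) and the matrix is recomputed, so no two reported alignments
#' share an aligned pair. Alignments scoring below `min_score` are dropped.
#'
#' @inheritParams smith_waterman
#' @param k_max maximum number of alignments (>= 1).
#' @param min_score minimum score to report.
#' @return list of `local_alignment` objects (possibly empty).
#' @export
waterman_eggert <- function(a, b, scheme = scoring_scheme(),
                            k_max = 10L, min_score = 1L) {
  stopifnot(k_max >= 1L)
  a <- as_seq(a); b <- as_seq(b)
  res <- cpp_local_align(a, b, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend,
                         as.integer(k_max), as.integer(max(1, min_score)))
  lapply(res, new_alignment, scheme = scheme, kind = "local_alignment")
}

#' Optimal global alignment (Needleman-Wunsch, affine gaps)
#'
#' End gaps are penalized. Tie-breaking as in [smith_waterman()].
#'
#' @inheritParams smith_waterman
#' @return a `global_alignment` object with the same statistics fields as a
#'   local alignment.
#' @export
needleman_wunsch <- function(a, b, scheme = scoring_scheme()) {
  a <- as_seq(a); b <- as_seq(b)
  raw <- cpp_global_align(a, b, scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend)
  new_alignment(raw, scheme, "global_alignment")
}

#' Identity statistics of a gapped alignment
#'
#' Identity is counted as identical non-`N` columns over all alignment
#' columns: gap columns and `N`-containing columns enter the denominator
#' only (BLAST-style "identities / alignment length").
#'
#' @param aln an alignment object, or any list with equal-length
#'   `a_gapped` / `b_gapped` strings.
#' @return named vector with `n_identical`, `n_columns`, `identity`.
#' @export
alignment_identity <- function(aln) {
  ga <- seq_chars(aln$a_gapped); gb <- seq_chars(aln$b_gapped)
  if (length(ga) != length(gb)) stop("gapped strings have unequal lengths")
  if (length(ga) == 0L)
    return(c(n_identical = 0, n_columns = 0, identity = NA_real_))
  ident <- ga == gb & ga != "-" & ga != "N" & gb != "N"
  n_id <- sum(ident); n_col <- length(ga)
  c(n_identical = n_id, n_columns = n_col, identity = n_id / n_col)
}

#' Recompute an alignment score from its gapped strings
#'
#' Used to assert the invariant that the reported DP score is exactly
#' reproducible from the alignment itself.
#'
#' @param aln an alignment object.
#' @param scheme a [scoring_scheme()]; defaults to the one stored in `aln`.
#' @return integer score.
#' @export
alignment_score <- function(aln, scheme = aln$scheme) {
  ga <- seq_chars(aln$a_gapped); gb <- seq_chars(aln$b_gapped)
  if (length(ga) == 0L) return(0L)
  gap <- ga == "-" | gb == "-"
  if (any(ga == "-" & gb == "-")) stop("column with gaps in both rows")
  isN <- ga == "N" | gb == "N"
  score <- sum(ifelse(ga[!gap] == gb[!gap] & !isN[!gap],
                      scheme$match, scheme$mismatch))
  # gap runs: first column open, rest extend
  r <- rle(gap)
  gl <- r$lengths[r$values]
  score - sum(ifelse(gl >= 1L, scheme$gap_open + (gl - 1L) * scheme$gap_extend, 0L))
}

#' @export
print.cre_alignment <- function(x, width = 60L, ...) {
  kind <- if (inherits(x, "global_alignment")) "global" else "local"
  cat(sprintf("%s alignment: score %d, identity %s over %d columns%s\n",
              kind, x$score,
              ifelse(is.na(x$identity), "NA", sprintf("%.1f%%", 100 * x$identity)),
              x$n_columns,
              ifelse(is.na(x$evalue), "", sprintf(", E = %.3g", x$evalue))))
  cat(sprintf("  a: [%d, %d)   b: [%d, %d)\n", x$a_start, x$a_end,
              x$b_start, x$b_end))
  ga <- seq_chars(x$a_gapped); gb <- seq_chars(x$b_gapped)
  if (length(ga)) {
    mid <- ifelse(ga == gb & ga != "-" & ga != "N", "|", " ")
    for (off in seq(1L, length(ga), by = width)) {
      idx <- off:min(off + width - 1L, length(ga))
      cat("  ", paste(ga[idx], collapse = ""), "\n", sep = "")
      cat("  ", paste(mid[idx], collapse = ""), "\n", sep = "")
      cat("  ", paste(gb[idx], collapse = ""), "\n", sep = "")
    }
  }
  invisible(x)
}
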