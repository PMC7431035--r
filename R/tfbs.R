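# PWM construction, exact score-distribution p-values, scanning, and
# mapping of hits onto conserved aligned stretches.
#
# Scores are natural-log odds internally; p-values come from the exact
# discrete score distribution computed by column-wise convolution on a
# fixed grid (granularity 1e-3, round-half-even), so no relative-score
# heuristic is needed.

PWM_GRID <- 1e-3

#' Build a position weight matrix from counts
#'
#' Column probabilities are `(count + pseudocount * p_bg) / (total +
#' pseudocount)`; the PWM entries are `log(p_col / p_bg)` in nats,
#' represented on the package's 1e-3 score grid (round-half-even) so that
#' window scores coincide exactly with the convolution score distribution.
#'
#' @param counts 4 x width non-negative count matrix (rows A,C,G,T).
#' @param background a [background_model()].
#' @param pseudocount total pseudocount mass per column (>= 0).
#' @param id label.
#' @return object of class `pwm` with elements `log_odds`, `background`,
#'   `pseudocount`, `id`, `width`.
#' @export
pfm_to_pwm <- function(counts, background = background_model(),
                       pseudocount = 1, id = attr(counts, "id") %||% "pwm") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L || ncol(counts) < 1L)
    stop("counts must be a 4 x width matrix")
  if (any(counts < 0)) stop("negative count in PFM")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  totals <- colSums(counts)
  if (pseudocount == 0 && any(totals == 0))
    stop("all-zero PFM column with pseudocount 0")
  p <- sweep(counts, 2L, totals + pseudocount, "/") +
    outer(unname(background$p), rep(pseudocount, ncol(counts))) /
      rep(totals + pseudocount, each = 4L)
  if (pseudocount == 0 && any(p == 0))
    p[p == 0] <- .Machine$double.xmin  # -Inf log-odds avoided; effectively vetoes
  lo <- round(log(p / background$p) / PWM_GRID) * PWM_GRID
  rownames(lo) <- DNA_BASES
  structure(list(log_odds = lo, background = background,
                 pseudocount = pseudocount, id = id, width = ncol(lo)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: width %d, pseudocount %g (log-odds in nats)\n",
              x$id, x$width, x$pseudocount))
  print(round(x$log_odds, 3))
  invisible(x)
}

grid_round <- function(x) round(x / PWM_GRID)  # round() is round-half-even

#' Exact score distribution of a PWM under the background
#'
#' Column-wise convolution of the per-column score atoms on a fixed grid
#' (1e-3 granularity). Probabilities sum to 1 within 1e-9. The returned
#' object supports exact p-values `P(score >= s)`.
#'
#' @param pwm a [pfm_to_pwm()] object of width <= 25.
#' @param background optional override of the PWM's background.
#' @return object of class `pwm_score_distribution` with `score`, `prob`
#'   and `tail_p` (P(score >= score\[i\])).
#' @export
exact_score_distribution <- function(pwm, background = pwm$background) {
  w <- pwm$width
  if (w > 25L) stop("PWM width ", w, " > 25: score grid would blow up")
  g <- apply(pwm$log_odds, 2L, grid_round)       # 4 x w integer grid scores
  p_bg <- unname(background$p)
  lo_off <- sum(apply(g, 2L, min)); hi_off <- sum(apply(g, 2L, max))
  probs <- numeric(hi_off - lo_off + 1L)
  # init with first column
  off0 <- min(g[, 1L])
  cur <- numeric(max(g[, 1L]) - off0 + 1L)
  for (b in 1:4) cur[g[b, 1L] - off0 + 1L] <- cur[g[b, 1L] - off0 + 1L] + p_bg[b]
  cur_off <- off0
  if (w > 1L) for (j in 2:w) {
    nxt_off <- cur_off + min(g[, j])
    nxt <- numeric(length(cur) + max(g[, j]) - min(g[, j]))
    for (b in 1:4) {
      sh <- g[b, j] - min(g[, j])
      idx <- seq_along(cur) + sh
      nxt[idx] <- nxt[idx] + cur * p_bg[b]
    }
    cur <- nxt; cur_off <- nxt_off
  }
  keep <- cur > 0
  score_grid <- (cur_off + seq_along(cur) - 1L)
  score <- score_grid[keep] * PWM_GRID
  prob <- cur[keep]
  stopifnot(abs(sum(prob) - 1) < 1e-9)
  structure(list(score = score, prob = prob,
                 tail_p = rev(cumsum(rev(prob))),
                 grid = score_grid[keep]),
            class = "pwm_score_distribution")
}

#' Exact p-value of a PWM score
#'
#' `P(score >= s)` under the background, on the distribution's grid.
#'
#' @param dist a [exact_score_distribution()].
#' @param s score(s) in nats.
#' @return p-value(s) in (0, 1].
#' @export
score_pvalue <- function(dist, s) {
  g <- grid_round(s)
  idx <- findInterval(g - 0.5, dist$grid) + 1L   # first grid point >= g
  out <- ifelse(idx > length(dist$grid), 0, dist$tail_p[pmin(idx, length(dist$grid))])
  pmin(1, pmax(out, 0))
}

reverse_complement_pwm <- function(pwm) {
  lo <- pwm$log_odds[4:1, rev(seq_len(pwm$width)), drop = FALSE]
  rownames(lo) <- DNA_BASES
  out <- pwm; out$log_odds <- lo
  out
}

#' Scan a sequence with a PWM
#'
#' Both strands are scanned; a hit is emitted where the exact p-value is at
#' most `pvalue_threshold`. Windows containing `N` are disqualified.
#' Positions are 0-based offsets of the window start on the + strand.
#'
#' @param seq DNA string (length >= PWM width).
#' @param pwm a [pfm_to_pwm()] object.
#' @param pvalue_threshold maximum p-value (default 1e-4).
#' @param dist optional precomputed [exact_score_distribution()].
#' @return data.frame of class `tfbs_hits`: `pwm_id`, `position`, `strand`,
#'   `score`, `pvalue`, `inside_conserved` (NA until mapped).
#' @export
scan_pwm <- function(seq, pwm, pvalue_threshold = 1e-4, dist = NULL) {
  w <- pwm$width
  L <- nchar(seq)
  if (L < w) stop("sequence shorter than PWM width")
  if (is.null(dist)) dist <- exact_score_distribution(pwm)
  code <- match(seq_chars(seq), DNA_BASES)        # NA for N
  n_win <- L - w + 1L
  score_strand <- function(lo) {
    sc <- numeric(n_win); ok <- rep(TRUE, n_win)
    for (k in seq_len(w)) {
      ck <- code[k:(k + n_win - 1L)]
      bad <- is.na(ck)
      ok <- ok & !bad
      ck[bad] <- 1L
      sc <- sc + lo[cbind(ck, k)]
    }
    list(score = sc, ok = ok)
  }
  fwd <- score_strand(pwm$log_odds)
  rev_ <- score_strand(reverse_complement_pwm(pwm)$log_odds)
  collect <- function(res, strand) {
    pv <- score_pvalue(dist, res$score)
    keep <- res$ok & pv <= pvalue_threshold
    if (!any(keep)) return(NULL)
    data.frame(pwm_id = pwm$id, position = which(keep) - 1L, strand = strand,
               score = res$score[keep], pvalue = pv[keep],
               inside_conserved = NA, stringsAsFactors = FALSE)
  }
  out <- rbind(collect(fwd, "+"), collect(rev_, "-"))
  if (is.null(out))
    out <- data.frame(pwm_id = character(), position = integer(),
                      strand = character(), score = numeric(),
                      pvalue = numeric(), inside_conserved = logical(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tfbs_hits", "data.frame")
  out
}

#' Map binding-site hits onto conserved aligned stretches
#'
#' A hit is `inside_conserved` iff its window lies wholly within alignment
#' columns whose smoothed local identity (centered running mean over
#' `smooth` columns, truncated at the ends) is at least `min_identity`.
#' Hit positions are offsets into the refined alignment's species-A
#' (query) sequence.
#'
#' @param hits a `tfbs_hits` data.frame from [scan_pwm()].
#' @param refined_alignment a `global_alignment` from [refine()] /
#'   [needleman_wunsch()].
#' @param width PWM width used for the scan.
#' @param min_identity conservation cutoff (the screen's identity
#'   threshold).
#' @param smooth smoothing window in columns (odd).
#' @return `hits` with `inside_conserved` filled.
#' @export
map_to_conserved <- function(hits, refined_alignment, width,
                             min_identity = 0.62, smooth = 21L) {
  ga <- seq_chars(refined_alignment$a_gapped)
  gb <- seq_chars(refined_alignment$b_gapped)
  ident <- as.numeric(ga == gb & ga != "-" & ga != "N" & gb != "N")
  n <- length(ident)
  half <- smooth %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(ident[lo:hi])
  }, numeric(1))
  conserved_col <- sm >= min_identity
  # query offset -> alignment column
  a_cols <- which(ga != "-")
  q_off_of_col <- cumsum(ga != "-")  # 1-based query offset at each column
  hits$inside_conserved <- vapply(seq_len(nrow(hits)), function(i) {
    q0 <- hits$position[i] + 1L           # 1-based first query base
    q1 <- q0 + width - 1L
    if (q1 > length(a_cols)) return(FALSE)
    cols <- a_cols[q0]:a_cols[q1]
    all(conserved_col[cols])
  }, logical(1))
  hits
}

#' Count conserved binding-site hits for a refined candidate
#'
#' Convenience wrapper: scans the candidate's query sequence with each PWM
#' and counts hits inside conserved stretches of the refined alignment.
#'
#' @param candidate a refined `candidate_cre`.
#' @param pwms list of [pfm_to_pwm()] objects.
#' @param pvalue_threshold scan threshold.
#' @param min_identity conservation cutoff.
#' @return the candidate with `tfbs_hits` (count) and attribute
#'   `tfbs_table`.
#' @export
annotate_tfbs <- function(candidate, pwms, pvalue_threshold = 1e-4,
                          min_identity = 0.62) {
  if (is.null(candidate$refined_alignment))
    stop("candidate must be refined before TFBS annotation")
  tabs <- list()
  for (pwm in pwms) {
    if (nchar(candidate$query$seq) < pwm$width) next
    h <- scan_pwm(candidate$query$seq, pwm, pvalue_threshold)
    if (nrow(h))
      tabs[[length(tabs) + 1L]] <-
        map_to_conserved(h, candidate$refined_alignment, pwm$width,
                         min_identity)
  }
  tab <- do.call(rbind, tabs)
  candidate$tfbs_hits <- if (is.null(tab)) 0L else sum(tab$inside_conserved)
  attr(candidate, "tfbs_table") <- tab
  candidate
}
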