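# Shared helpers: sequence utilities, interval arithmetic, seeded RNG scopes.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Wrapper around [Biostrings::reverseComplement()] that preserves the plain
#' character representation used throughout the package. `N` maps to `N`.
#'
#' @param seq a single character string over `A,C,G,T,N`.
#' @return the reverse-complemented string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards. All stochastic operations in the package funnel
#' through this, which is what makes generator outputs pure functions of
#' (spec, seed).
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a master seed
#'
#' Gives each pipeline stage an independent, reproducible stream. The
#' result stays below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stage stage label.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1103L + h) %% 2147483587)
}

#' i.i.d. uniform random DNA
#'
#' Draws from the current RNG stream; wrap in [with_seed()] for
#' reproducibility.
#'
#' @param n length in bp.
#' @return a DNA string.
#' @export
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# substring by 0-based half-open interval
subseq0 <- function(seq, start, end) substr(seq, start + 1L, end)

#' Overlap of two 0-based half-open intervals
#'
#' @param s1,e1,s2,e2 interval bounds.
#' @return overlap in bp (0 when disjoint).
#' @export
interval_overlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2))
}

# merge overlapping/adjacent 0-based half-open intervals given as a
# data.frame with columns start, end
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(data.frame(start = integer(), end = integer()))
  df <- df[order(df$start, df$end), , drop = FALSE]
  out_s <- df$start[1L]; out_e <- df$end[1L]
  res_s <- integer(); res_e <- integer()
  for (i in seq_len(nrow(df))[-1L]) {
    if (df$start[i] <= out_e) out_e <- max(out_e, df$end[i])
    else { res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
           out_s <- df$start[i]; out_e <- df$end[i] }
  }
  data.frame(start = c(res_s, out_s), end = c(res_e, out_e))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
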