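# Karlin-Altschul E-value statistics for local alignment scores.
#
# Two routes to the (lambda, K) pair:
#   * analytic_ungapped -- lambda solves sum_ij p_i p_j exp(lambda s_ij) = 1
#     by bisection; K from the classical lattice-case series;
#   * empirical_gapped  -- maximum-likelihood Gumbel fit to simulated best
#     local scores of random sequence pairs (the default for the gapped
#     screen, where no closed form exists).

#' Background base composition
#'
#' @param p numeric vector of 4 base frequencies in A,C,G,T order.
#' @return object of class `background_model`.
#' @export
background_model <- function(p = rep(0.25, 4)) {
  stopifnot(length(p) == 4L, all(p >= 0), abs(sum(p) - 1) < 1e-9)
  structure(list(p = setNames(as.numeric(p), DNA_BASES)),
            class = "background_model")
}

new_karlin_params <- function(lambda, K, source, extra = list()) {
  stopifnot(lambda > 0, K > 0)
  structure(c(list(lambda = lambda, K = K, source = source), extra),
            class = "karlin_params")
}

#' @export
print.karlin_params <- function(x, ...) {
  cat(sprintf("Karlin-Altschul parameters (%s): lambda = %.6f, K = %.4g\n",
              x$source, x$lambda, x$K))
  invisible(x)
}

# single aligned-pair score distribution under the background:
# P(match) = sum p_i^2 at score `match`, else mismatch.
step_distribution <- function(scheme, bg) {
  pm <- sum(bg$p^2)
  list(scores = c(scheme$match, scheme$mismatch), probs = c(pm, 1 - pm))
}

#' Solve for the ungapped Karlin-Altschul lambda
#'
#' Bisection on `sum_ij p_i p_j exp(lambda * s_ij) = 1` to a residual below
#' `1e-9`. Requires negative expected pair score and a positive maximum
#' score; K is estimated from the classical lattice-case series truncated
#' at `1e-6`.
#'
#' @param scheme a [scoring_scheme()].
#' @param bg a [background_model()].
#' @return `karlin_params` with `source = "analytic_ungapped"`.
#' @export
solve_lambda <- function(scheme, bg = background_model()) {
  sd_ <- step_distribution(scheme, bg)
  mu <- sum(sd_$scores * sd_$probs)
  if (mu >= 0)
    stop("expected pair score under background is non-negative (", signif(mu, 4),
         "); Karlin-Altschul statistics require negative drift")
  if (max(sd_$scores) <= 0) stop("maximum pair score must be positive")
  f <- function(l) sum(sd_$probs * exp(l * sd_$scores)) - 1
  lo <- 1e-12; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < 1e-12 && (hi - lo) < 1e-12) break
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  lambda <- (lo + hi) / 2
  stopifnot(abs(f(lambda)) < 1e-9)
  K <- karlin_K(sd_, lambda)
  new_karlin_params(lambda, K, "analytic_ungapped")
}

# Classical lattice-case K (Karlin & Altschul 1990):
#   K = delta * lambda * exp(-2*sigma) / (E[S exp(lambda S)] * (1 - exp(-lambda*delta)))
# with sigma = sum_k (1/k) [ P(S_k >= 0) + E(exp(lambda S_k); S_k < 0) ],
# where S_k is the k-step random walk of pair scores. Both summand parts
# decay geometrically; the series is truncated once a term drops below 1e-6.
karlin_K <- function(sd_, lambda) {
  delta <- as.integer(do.call(gcd_int, as.list(abs(sd_$scores))))
  Eprime <- sum(sd_$probs * sd_$scores * exp(lambda * sd_$scores))
  # distribution of S_k: with a two-atom step this is binomial
  pm <- sd_$probs[1L]; sm <- sd_$scores[1L]; sx <- sd_$scores[2L]
  sigma <- 0
  for (k in 1:5000) {
    j <- 0:k
    pk <- dbinom(j, k, pm)
    sk <- j * sm + (k - j) * sx
    neg <- sk < 0
    term <- (sum(pk[!neg]) + sum(pk[neg] * exp(lambda * sk[neg]))) / k
    sigma <- sigma + term
    if (k > 10 && term < 1e-6) break
  }
  delta * lambda * exp(-2 * sigma) / (Eprime * (1 - exp(-lambda * delta)))
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
gcd_int <- function(...) Reduce(gcd2, list(...))

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * score)`: the expected number of chance
#' local alignments scoring at least `score` between random sequences of
#' lengths `m` and `n`.
#'
#' @param score alignment score (vectorized).
#' @param m,n search space lengths in bp (both > 0).
#' @param params a `karlin_params` object.
#' @return numeric E-value(s).
#' @export
evalue <- function(score, m, n, params) {
  stopifnot(m > 0, n > 0, inherits(params, "karlin_params"))
  params$K * m * n * exp(-params$lambda * score)
}

# smallest integer score with E <= e under params
score_for_evalue <- function(e, m, n, params) {
  ceiling(log(params$K * m * n / e) / params$lambda)
}

#' Empirical Gumbel calibration for gapped alignment scores
#'
#' Simulates the best local alignment scores of `n_sims` random i.i.d.
#' sequence pairs of length `seq_len` under the background composition and
#' fits a Gumbel law by maximum likelihood. The fitted location/scale
#' (mu, beta) map to `lambda = 1/beta` and
#' `K = exp(mu/beta) / (seq_len^2)`.
#'
#' @inheritParams solve_lambda
#' @param seq_len simulated sequence length (bp).
#' @param n_sims number of simulated pairs (>= 100).
#' @param seed integer seed; the calibration is deterministic given it.
#' @return `karlin_params` with `source = "empirical_gapped"`.
#' @export
calibrate_gapped <- function(scheme, bg = background_model(), seq_len = 500L,
                             n_sims = 1000L, seed = 1L) {
  if (n_sims < 100L) stop("n_sims must be >= 100 for a stable Gumbel fit")
  scores <- with_seed(seed, cpp_null_best_scores(
    as.integer(n_sims), as.integer(seq_len),
    scheme$match, scheme$mismatch, scheme$gap_open, scheme$gap_extend,
    unname(bg$p)))
  if (sd(scores) < 1e-12) stop("degenerate fit: simulated scores have zero variance")
  beta0 <- sd(scores) * sqrt(6) / pi
  mu0 <- mean(scores) - 0.5772156649 * beta0
  nll <- function(par) {
    mu <- par[1L]; beta <- exp(par[2L])
    z <- (scores - mu) / beta
    sum(log(beta) + z + exp(-z))
  }
  fit <- optim(c(mu0, log(beta0)), nll, method = "BFGS")
  mu <- fit$par[1L]; beta <- exp(fit$par[2L])
  lambda <- 1 / beta
  K <- exp(mu / beta) / (as.numeric(seq_len)^2)
  new_karlin_params(lambda, K, "empirical_gapped",
                    list(seq_len = as.integer(seq_len),
                         n_sims = as.integer(n_sims), seed = as.integer(seed)))
}

# --- calibration cache ------------------------------------------------------

.calib_cache <- new.env(parent = emptyenv())

calib_key <- function(scheme, bg, seq_len, n_sims, seed) {
  paste(scheme$match, scheme$mismatch, scheme$gap_open, scheme$gap_extend,
        paste(signif(bg$p, 6), collapse = ","), seq_len, n_sims, seed,
        sep = "|")
}

#' Cached gapped calibration
#'
#' As [calibrate_gapped()], but memoized per (scheme, background, length,
#' n_sims, seed) within the session and optionally persisted as a TSV cache
#' file.
#'
#' @inheritParams calibrate_gapped
#' @param cache_file optional TSV path read before and written after
#'   calibration.
#' @return `karlin_params`.
#' @export
gapped_params <- function(scheme, bg = background_model(), seq_len = 500L,
                          n_sims = 1000L, seed = 1L, cache_file = NULL) {
  key <- calib_key(scheme, bg, seq_len, n_sims, seed)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  if (!is.null(cache_file) && file.exists(cache_file)) {
    tab <- read.table(cache_file, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    hit <- tab[tab$key == key, , drop = FALSE]
    if (nrow(hit) == 1L) {
      p <- new_karlin_params(hit$lambda, hit$K, "empirical_gapped",
                             list(seq_len = as.integer(seq_len),
                                  n_sims = as.integer(n_sims),
                                  seed = as.integer(seed)))
      .calib_cache[[key]] <- p
      return(p)
    }
  }
  p <- calibrate_gapped(scheme, bg, seq_len, n_sims, seed)
  .calib_cache[[key]] <- p
  if (!is.null(cache_file)) {
    row <- data.frame(key = key, lambda = p$lambda, K = p$K,
                      seq_len = seq_len, n_sims = n_sims, seed = seed)
    if (file.exists(cache_file)) {
      tab <- read.table(cache_file, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
      row <- rbind(tab, row)
    }
    write.table(row, cache_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  p
}
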