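# Independent oracles used across the suite.
#
# naive_*_score: straightforward full-matrix affine-gap DP written directly
# from the recurrences, kept free of the package's C++ code path. Gap model
# matches the package contract: first gap column costs `go`, later ones `ge`.

naive_pair_score <- function(ca, cb, match, mismatch) {
  if (ca == "N" || cb == "N") return(mismatch)
  if (ca == cb) match else mismatch
}

naive_dp <- function(a, b, match, mismatch, go, ge, local) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1); X <- M; Y <- M
  M[1, 1] <- 0
  if (!local) {
    for (i in seq_len(m)) X[i + 1, 1] <- -(go + (i - 1) * ge)
    for (j in seq_len(n)) Y[1, j + 1] <- -(go + (j - 1) * ge)
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  best <- if (local) 0 else NEG
  for (i in seq_len(m)) for (j in seq_len(n)) {
    X[i + 1, j + 1] <- max(M[i, j + 1] - go, X[i, j + 1] - ge)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - go, Y[i + 1, j] - ge)
    d <- max(M[i, j], X[i, j], Y[i, j], if (local) 0 else NEG)
    M[i + 1, j + 1] <- d + naive_pair_score(A[i], B[j], match, mismatch)
    if (local) best <- max(best, M[i + 1, j + 1])
  }
  if (local) best else max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
}

naive_local_score <- function(a, b, scheme)
  naive_dp(a, b, scheme$match, scheme$mismatch, scheme$gap_open,
           scheme$gap_extend, local = TRUE)

naive_global_score <- function(a, b, scheme)
  naive_dp(a, b, scheme$match, scheme$mismatch, scheme$gap_open,
           scheme$gap_extend, local = FALSE)

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# exhaustive PWM p-value over all 4^w words under the background
brute_pwm_pvalue <- function(pwm, s, grid = 1e-3) {
  w <- pwm$width
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- apply(words, 1, function(ix) sum(pwm$log_odds[cbind(ix, seq_len(w))]))
  pr <- apply(words, 1, function(ix) prod(pwm$background$p[ix]))
  sum(pr[round(sc / grid) >= round(s / grid)])
}

random_pfm <- function(width, total = 20L) {
  m <- matrix(0, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(width)) m[, j] <- as.vector(stats::rmultinom(1, total, runif(4)))
  m
}

sharp_pfm <- function(width, total = 200L) {
  m <- matrix(0, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  picks <- sample(1:4, width, TRUE)
  for (j in seq_len(width)) { m[picks[j], j] <- total - 3; m[-picks[j], j] <- 1 }
  m
}

# shared gapped calibrations (memoized inside the package per session):
# a cheap one for small-window module tests, and one at the screen's
# window-matched calibration length for the end-to-end checks
default_params <- function(seed = 101L)
  gapped_params(scoring_scheme(), background_model(), seq_len = 500L,
                n_sims = 500L, seed = seed)

screen_params <- function(seed = 101L)
  gapped_params(scoring_scheme(), background_model(), seq_len = 2000L,
                n_sims = 500L, seed = seed)
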