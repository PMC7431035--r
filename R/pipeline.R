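# End-to-end orchestration: flat-file config, the screen runner, and the
# synthetic benchmark grid.

#' Read a flat key=value config file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#' Values that parse as numbers are returned numeric.
#'
#' @param path config file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("unparseable config line: ", l)
    key <- trimws(kv[1L]); val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

config_thresholds <- function(cfg) {
  criteria_thresholds(
    min_identity = cfg$min_identity %||% 0.62,
    min_length = cfg$min_length %||% 55L,
    max_evalue = cfg$max_evalue %||% 0.1,
    flank = cfg$flank %||% 20000L,
    max_exon_overlap = cfg$max_exon_overlap %||% 0L,
    max_repeat_fraction = cfg$max_repeat_fraction %||% 0.5)
}

config_scheme <- function(cfg) {
  scoring_scheme(match = cfg$match %||% 5L, mismatch = cfg$mismatch %||% -4L,
                 gap_open = cfg$gap_open %||% 16L,
                 gap_extend = cfg$gap_extend %||% 4L)
}

#' Run the conservation screen from a config
#'
#' Config keys: `genome_a`, `genome_b` (FASTA), `annotations_a`,
#' `annotations_b` (BED6), `homology` (TSV), `out_dir`, optional `pfms`
#' (JASPAR text, scanned over passing candidates), optional threshold and
#' scoring overrides (`min_identity`, `min_length`, `max_evalue`, `flank`,
#' `match`, `mismatch`, `gap_open`, `gap_extend`, `tfbs_pvalue`), and
#' `seed`. All referenced paths are checked before any computation starts;
#' on error the output directory contains only the log.
#'
#' @param config path to a key=value config file, or an equivalent list.
#' @param seed overrides the config seed when non-NULL.
#' @return invisibly, the screen result (list with `candidates`, `report`,
#'   and output `paths`).
#' @export
run_screen <- function(config, seed = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  for (key in c("genome_a", "genome_b", "annotations_a", "annotations_b",
                "homology"))
    if (is.null(cfg[[key]]) || !file.exists(cfg[[key]]))
      stop("config path missing or nonexistent: ", key)
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)

  loci_a <- read_fasta(cfg$genome_a, species = "speciesA")
  loci_b <- read_fasta(cfg$genome_b, species = "speciesB")
  ann_a <- read_bed(cfg$annotations_a)
  ann_b <- read_bed(cfg$annotations_b)
  homology <- read_homology(cfg$homology)

  scheme <- config_scheme(cfg)
  thresholds <- config_thresholds(cfg)
  res <- screen_pair(loci_a, loci_b, ann_a, ann_b, homology, thresholds,
                     scheme, calib_seed = derive_seed(seed, "calibration"),
                     verbose = isTRUE(cfg$verbose > 0))

  if (!is.null(cfg$pfms)) {
    pwms <- lapply(read_jaspar_pfm(cfg$pfms), pfm_to_pwm)
    res$candidates <- lapply(res$candidates, function(cc) {
      if (cc$verdict == "pass")
        cc <- annotate_tfbs(cc, pwms, cfg$tfbs_pvalue %||% 1e-4,
                            thresholds$min_identity)
      cc
    })
    res$report <- candidates_report(res$candidates)
  }

  paths <- c(bed = file.path(out_dir, sprintf("candidates_seed%d.bed", seed)),
             tsv = file.path(out_dir, sprintf("candidates_seed%d.tsv", seed)))
  write_candidates(res$candidates, paths[["bed"]], paths[["tsv"]])
  res$paths <- paths
  invisible(res)
}

#' Synthetic recovery/specificity benchmark
#'
#' For each target identity in `identity_grid` and each of `n_seeds`
#' seeds, generates a synthetic ortholog pair, runs the screen, and
#' scores recovery (fraction of truth elements overlapped >= 50%
#' reciprocally by a passing candidate), false passes per 10 kb of
#' window-pair background, and the mean absolute difference between
#' realized and detected identity.
#'
#' @param identity_grid target identities to sweep.
#' @param n_seeds seeds per grid cell.
#' @param base_seed first seed.
#' @param spec_args further arguments to [synthetic_spec()].
#' @param thresholds,scheme screen configuration.
#' @return data.frame with one row per grid cell.
#' @export
run_benchmark <- function(identity_grid = c(0.55, 0.65, 0.75, 0.85),
                          n_seeds = 5L, base_seed = 1L, spec_args = list(),
                          thresholds = criteria_thresholds(),
                          scheme = scoring_scheme()) {
  params <- gapped_params(scheme, background_model(), seq_len = 500L,
                          n_sims = 500L, seed = base_seed)
  rows <- list()
  for (ti in identity_grid) {
    rec <- c(); fp10 <- c(); did <- c()
    for (s in seq_len(n_seeds) + base_seed - 1L) {
      args <- c(list(target_identity = ti, seed = s), spec_args)
      pair <- generate_locus_pair(do.call(synthetic_spec, args))
      res <- screen_pair(list(chrA = pair$locus_a), list(chrB = pair$locus_b),
                         pair$annotations_a, pair$annotations_b,
                         pair$homology, thresholds, scheme, params)
      sc <- score_against_truth(res$candidates, pair)
      rec <- c(rec, sc$recovery)
      fp10 <- c(fp10, sc$false_per_10kb)
      did <- c(did, sc$identity_abs_err)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      target_identity = ti,
      recovery = if (all(is.na(rec))) NA_real_ else mean(rec, na.rm = TRUE),
      false_per_10kb = mean(fp10, na.rm = TRUE),
      identity_abs_err = if (all(is.na(did))) NA_real_
        else mean(did, na.rm = TRUE),
      n_seeds = n_seeds)
  }
  do.call(rbind, rows)
}

#' Score screen candidates against a synthetic truth set
#'
#' A truth element counts as recovered when some passing candidate
#' overlaps it reciprocally by at least `min_overlap` (fraction of both
#' the candidate span and the truth span). Passing candidates overlapping
#' no truth element are false passes, normalized per 10 kb of window-pair
#' sequence.
#'
#' @param candidates list of classified candidates.
#' @param pair a `synthetic_pair`.
#' @param min_overlap reciprocal overlap fraction.
#' @return list with `recovery` (NA when nothing was planted),
#'   `false_per_10kb`, `identity_abs_err`, `n_pass`.
#' @export
score_against_truth <- function(candidates, pair, min_overlap = 0.5) {
  truth <- pair$truth$a
  pass <- Filter(function(cc) cc$verdict == "pass", candidates)
  overlaps <- function(cc, t) {
    ov <- interval_overlap(cc$query$start, cc$query$end, t$start, t$end)
    ov >= min_overlap * (cc$query$end - cc$query$start) &&
      ov >= min_overlap * (t$end - t$start)
  }
  recovered <- logical(nrow(truth)); idn_err <- numeric(0)
  false_pass <- 0L
  for (cc in pass) {
    hit <- FALSE
    for (i in seq_len(nrow(truth))) {
      if (overlaps(cc, truth[i, ])) {
        recovered[i] <- TRUE; hit <- TRUE
        idn_err <- c(idn_err,
                     abs(cc$alignment$identity -
                           pair$truth$realized_identity[[truth$name[i]]]))
      }
    }
    if (!hit) false_pass <- false_pass + 1L
  }
  window_bp <- nchar(pair$locus_a$seq) + nchar(pair$locus_b$seq)
  list(recovery = if (nrow(truth)) mean(recovered) else NA_real_,
       false_per_10kb = false_pass / (window_bp / 2) * 1e4,
       identity_abs_err = if (length(idn_err)) mean(idn_err) else NA_real_,
       n_pass = length(pass))
}
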