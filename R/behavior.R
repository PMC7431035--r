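# Startle-induced negative geotaxis (SING) scoring and the statistical
# decision tree with the dual-control significance rule.
#
# Protocol emulated: groups of 10 flies per tube climb after a startle;
# the number above the 2 cm mark at 10 s is counted; 15 trials per tube
# are averaged; 10 tubes per sex per genotype are the experimental units.

#' A SING trial block (one tube)
#'
#' @param counts per-trial numbers of flies above the mark.
#' @param genotype,sex labels.
#' @param group_size flies per tube (protocol: 10).
#' @param n_trials expected number of trials (protocol: 15); a deviating
#'   count raises a warning (configurable), not an error.
#' @param warn_trials warn when `length(counts) != n_trials`.
#' @return object of class `sing_block`.
#' @export
sing_block <- function(counts, genotype = "genotype", sex = "NA",
                       group_size = 10L, n_trials = 15L, warn_trials = TRUE) {
  counts <- as.numeric(counts)
  if (any(counts < 0 | counts > group_size))
    stop("trial counts must lie in [0, group_size]")
  if (warn_trials && length(counts) != n_trials)
    warning(sprintf("block has %d trials, expected %d", length(counts),
                    n_trials))
  structure(list(genotype = genotype, sex = sex,
                 group_size = as.integer(group_size),
                 n_trials = length(counts), counts = counts),
            class = "sing_block")
}

#' SING performance score of a tube
#'
#' Arithmetic mean of the per-trial counts above the mark.
#'
#' @param block a [sing_block()].
#' @return numeric score.
#' @export
sing_score <- function(block) mean(block$counts)

#' Normality gate (Anderson-Darling)
#'
#' Each group is tested with the Anderson-Darling test; the overall gate
#' passes iff every group does. Groups of fewer than 5 observations are an
#' error (the test is undefined at the stated precision).
#'
#' @param groups list of numeric vectors.
#' @param alpha significance level.
#' @return list with `per_group` (named logical) and `overall`.
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  if (any(lengths(groups) < 5L))
    stop("normality gate needs n >= 5 per group")
  per <- vapply(groups, function(g) {
    if (sd(g) == 0) return(FALSE)  # degenerate: not plausibly normal
    nortest::ad.test(g)$p.value > alpha
  }, logical(1))
  list(per_group = per, overall = all(per))
}

#' Critical value of Hartley's Fmax
#'
#' Exact numeric computation: with k independent sample variances on df
#' degrees of freedom each, `P(Fmax <= c) = k * Int f(x) (F(cx) - F(x))^(k-1) dx`
#' over the scaled chi-square density; the 1-alpha quantile is found by
#' root search.
#'
#' @param k number of groups.
#' @param df degrees of freedom per group (n - 1).
#' @param alpha upper tail probability.
#' @return critical Fmax value.
#' @export
hartley_fmax_critical <- function(k, df, alpha = 0.05) {
  stopifnot(k >= 2L, df >= 2L)
  key <- sprintf("fmax|%d|%d|%g", k, df, alpha)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  cdf <- function(cv) {
    integrand <- function(x)
      k * dchisq(x, df) * pmax(0, pchisq(cv * x, df) - pchisq(x, df))^(k - 1L)
    integrate(integrand, 0, Inf, rel.tol = 1e-8)$value
  }
  crit <- uniroot(function(cv) cdf(cv) - (1 - alpha), c(1 + 1e-6, 1e6),
                  tol = 1e-6)$root
  .calib_cache[[key]] <- crit
  crit
}

#' Variance homogeneity gate (Hartley's Fmax)
#'
#' `fmax = max(s^2) / min(s^2)`; the gate passes iff fmax is at most the
#' critical value for (k, df). A zero-variance group fails the gate with a
#' warning (the ratio is undefined). Group sizes must be equal or nearly
#' so; the smallest df is used (conservative).
#'
#' @param groups list of numeric vectors.
#' @param fmax_critical optional critical value; computed from
#'   [hartley_fmax_critical()] when `NULL`.
#' @param alpha level for the computed critical value.
#' @return list with `fmax`, `critical`, `pass`.
#' @export
variance_gate <- function(groups, fmax_critical = NULL, alpha = 0.05) {
  v <- vapply(groups, var, numeric(1))
  if (any(v == 0)) {
    warning("zero-variance group: Fmax undefined; variance gate fails")
    return(list(fmax = Inf, critical = NA_real_, pass = FALSE))
  }
  fmax <- max(v) / min(v)
  if (is.null(fmax_critical))
    fmax_critical <- hartley_fmax_critical(length(groups),
                                           min(lengths(groups)) - 1L, alpha)
  list(fmax = fmax, critical = fmax_critical, pass = fmax <= fmax_critical)
}

#' Dunn-Sidak adjusted significance level
#'
#' `alpha' = 1 - (1 - alpha)^(1/k)` for k pairwise comparisons.
#'
#' @param alpha family-wise level.
#' @param k number of comparisons.
#' @return adjusted per-comparison alpha.
#' @export
dunn_sidak_alpha <- function(alpha = 0.05, k = 3L) 1 - (1 - alpha)^(1 / k)

#' Statistical decision tree for a three-group comparison
#'
#' If every group passes the Anderson-Darling normality gate and the
#' variances pass Hartley's Fmax gate, a one-way ANOVA is run; when the
#' omnibus p < alpha, pairwise comparisons use the Tukey-Kramer test.
#' Otherwise a Kruskal-Wallis test is run; when its omnibus p < alpha,
#' pairwise Mann-Whitney U tests are compared against the Dunn-Sidak
#' adjusted level `1 - (1 - alpha)^(1/3)`. A non-significant omnibus marks
#' all pairs non-significant.
#'
#' @param experimental,control_uas,control_gal4 numeric vectors of per-tube
#'   scores.
#' @param alpha significance level.
#' @return object of class `group_comparison`: `branch_taken`
#'   (`"anova_tukey"` or `"kw_mwu"`), `omnibus_p`, `pairwise_p` (named:
#'   `exp_vs_uas`, `exp_vs_gal4`, `uas_vs_gal4`), `pairwise_significant`,
#'   `significant` (the dual-control verdict).
#' @export
decision_tree <- function(experimental, control_uas, control_gal4,
                          alpha = 0.05) {
  groups <- list(experimental = experimental, control_uas = control_uas,
                 control_gal4 = control_gal4)
  if (length(groups) != 3L) stop("exactly three groups are required")
  norm_ok <- normality_gate(groups, alpha)$overall
  var_ok <- if (norm_ok) {
    suppressWarnings(variance_gate(groups)$pass)
  } else FALSE
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  pairs <- rbind(c("experimental", "control_uas"),
                 c("experimental", "control_gal4"),
                 c("control_uas", "control_gal4"))
  pair_names <- c("exp_vs_uas", "exp_vs_gal4", "uas_vs_gal4")
  if (norm_ok && var_ok) {
    branch <- "anova_tukey"
    fit <- aov(vals ~ fac)
    omnibus_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    if (omnibus_p < alpha) {
      tk <- TukeyHSD(fit, conf.level = 1 - alpha)$fac
      # rownames are "g2-g1"
      pw <- vapply(seq_len(nrow(pairs)), function(i) {
        r1 <- paste0(pairs[i, 1L], "-", pairs[i, 2L])
        r2 <- paste0(pairs[i, 2L], "-", pairs[i, 1L])
        tk[rownames(tk) %in% c(r1, r2), "p adj"][1L]
      }, numeric(1))
      sig <- pw < alpha
    } else { pw <- rep(NA_real_, 3L); sig <- rep(FALSE, 3L) }
  } else {
    branch <- "kw_mwu"
    omnibus_p <- kruskal.test(vals, fac)$p.value
    if (omnibus_p < alpha) {
      adj <- dunn_sidak_alpha(alpha, 3L)
      pw <- vapply(seq_len(nrow(pairs)), function(i)
        suppressWarnings(wilcox.test(groups[[pairs[i, 1L]]],
                                     groups[[pairs[i, 2L]]],
                                     exact = FALSE)$p.value), numeric(1))
      sig <- pw < adj
    } else { pw <- rep(NA_real_, 3L); sig <- rep(FALSE, 3L) }
  }
  names(pw) <- names(sig) <- pair_names
  cmp <- structure(list(branch_taken = branch, omnibus_p = omnibus_p,
                        pairwise_p = pw, pairwise_significant = sig,
                        alpha = alpha, significant = NA),
                   class = "group_comparison")
  cmp$significant <- dual_control_rule(cmp)
  cmp
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("branch %s, omnibus p = %.4g\n", x$branch_taken, x$omnibus_p))
  for (nm in names(x$pairwise_p))
    cat(sprintf("  %-12s p = %-10.4g %s\n", nm, x$pairwise_p[nm],
                ifelse(x$pairwise_significant[nm], "*", "")))
  cat("dual-control significant:", x$significant, "\n")
  invisible(x)
}

#' Dual-control significance rule
#'
#' A result is significant iff the experimental group differs from both
#' controls and the two controls do not differ from one another.
#'
#' @param comparison a `group_comparison`, or a logical vector of three
#'   pairwise outcomes (`exp_vs_uas`, `exp_vs_gal4`, `uas_vs_gal4`).
#' @return logical.
#' @export
dual_control_rule <- function(comparison) {
  s <- if (inherits(comparison, "group_comparison"))
    comparison$pairwise_significant else comparison
  stopifnot(length(s) == 3L)
  isTRUE(s[[1L]]) && isTRUE(s[[2L]]) && !isTRUE(s[[3L]])
}

#' Read SING trial data
#'
#' TSV with columns `genotype`, `sex`, `tube_id`, `trial_index`,
#' `count_above_mark`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_sing_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("genotype", "sex", "tube_id", "trial_index", "count_above_mark")
  if (!all(need %in% names(tab)))
    stop("SING TSV must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Per-tube SING scores from trial data
#'
#' @param trials data.frame from [read_sing_tsv()].
#' @param warn_trials warn on tubes with a trial count other than 15.
#' @return data.frame with `genotype`, `sex`, `tube_id`, `score`.
#' @export
sing_scores <- function(trials, warn_trials = TRUE) {
  sp <- split(trials, interaction(trials$genotype, trials$sex,
                                  trials$tube_id, drop = TRUE))
  do.call(rbind, lapply(sp, function(d) {
    b <- sing_block(d$count_above_mark[order(d$trial_index)],
                    genotype = d$genotype[1L], sex = d$sex[1L],
                    warn_trials = warn_trials)
    data.frame(genotype = d$genotype[1L], sex = d$sex[1L],
               tube_id = d$tube_id[1L], score = sing_score(b),
               stringsAsFactors = FALSE)
  }))
}

#' SING analysis of an experimental genotype against its two controls
#'
#' Applies the decision tree separately per sex and to the pooled data
#' (sexes are analysed both ways and both reported).
#'
#' @param trials data.frame from [read_sing_tsv()].
#' @param experimental,control_uas,control_gal4 genotype labels.
#' @param alpha significance level.
#' @return data.frame with one row per analysis (`sex` in
#'   `"female"`, `"male"`, `"pooled"` as present): branch, omnibus and
#'   pairwise p-values, dual-control verdict.
#' @export
run_behavior <- function(trials, experimental, control_uas, control_gal4,
                         alpha = 0.05) {
  scores <- sing_scores(trials)
  one <- function(sc, label) {
    g <- function(gt) sc$score[sc$genotype == gt]
    cmp <- decision_tree(g(experimental), g(control_uas), g(control_gal4),
                         alpha)
    data.frame(sex = label, branch = cmp$branch_taken,
               omnibus_p = cmp$omnibus_p,
               p_exp_vs_uas = cmp$pairwise_p[["exp_vs_uas"]],
               p_exp_vs_gal4 = cmp$pairwise_p[["exp_vs_gal4"]],
               p_uas_vs_gal4 = cmp$pairwise_p[["uas_vs_gal4"]],
               significant = cmp$significant, stringsAsFactors = FALSE)
  }
  out <- list()
  for (sx in unique(scores$sex))
    out[[length(out) + 1L]] <- one(scores[scores$sex == sx, ], sx)
  if (length(unique(scores$sex)) > 1L)
    out[[length(out) + 1L]] <- one(scores, "pooled")
  do.call(rbind, out)
}
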