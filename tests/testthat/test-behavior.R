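test_that("SING scores are per-tube trial means with protocol checks", {
  expect_equal(sing_score(sing_block(rep(10, 15))), 10.0)
  expect_equal(sing_score(sing_block(rep(0, 15))), 0.0)
  counts <- c(rep(4, 8), rep(6, 7))
  expect_equal(sing_score(sing_block(counts)), mean(counts))
  expect_equal(sing_score(sing_block(counts)), 74 / 15)
  expect_warning(sing_block(rep(5, 12)), "12 trials")
  expect_error(sing_block(c(rep(5, 14), 11)), "group_size")
})

test_that("normality gate is a conjunction over Anderson-Darling tests", {
  set.seed(21)
  g_norm <- replicate(3, rnorm(30, 5, 1), simplify = FALSE)
  g_exp <- c(g_norm[1:2], list(rexp(30)))
  res <- normality_gate(g_exp)
  expect_length(res$per_group, 3L)
  expect_error(normality_gate(list(rnorm(4), rnorm(30), rnorm(30))), "n >= 5")

  # type-I rate near 1 - (1-alpha)^3 under normal groups; strong power
  # against an exponential group (spec of the gate, n = 30)
  overall_null <- vapply(1:300, function(i) {
    set.seed(i)
    normality_gate(replicate(3, rnorm(30, 5, 1), simplify = FALSE))$overall
  }, logical(1))
  expect_gt(mean(overall_null), 0.80)
  overall_exp <- vapply(1:100, function(i) {
    set.seed(i + 5000)
    normality_gate(c(replicate(2, rnorm(30, 5, 1), simplify = FALSE),
                     list(rexp(30))))$overall
  }, logical(1))
  expect_lte(mean(overall_exp), 0.10)
})

test_that("variance gate computes Fmax against the exact critical value", {
  g <- replicate(3, c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), simplify = FALSE)
  res <- variance_gate(g)
  expect_equal(res$fmax, 1.0)
  expect_true(res$pass)

  g2 <- list(c(1, 3, 5, 7, 9), c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(variance_gate(g2)$fmax, 4.0)
  # permutation invariance
  expect_equal(variance_gate(g2[c(3, 1, 2)])$fmax, 4.0)

  expect_warning(res0 <- variance_gate(list(rep(5, 6), rnorm(6), rnorm(6))),
                 "zero-variance")
  expect_false(res0$pass)

  # computed critical value reproduces the published table point (k=3, df=9)
  expect_equal(hartley_fmax_critical(3, 9), 5.34, tolerance = 0.01)
})

test_that("decision tree takes the documented branches", {
  set.seed(2)
  null_cmp <- decision_tree(rnorm(10, 5), rnorm(10, 5), rnorm(10, 5))
  expect_equal(null_cmp$branch_taken, "anova_tukey")
  expect_false(null_cmp$significant)

  # strong effect: experimental shifted by +3 SD is called significant in
  # nearly all datasets; on the parametric branch the Tukey pairwise
  # pattern (exp vs both controls, controls alike) drives the call
  res <- lapply(1:100, function(i) {
    set.seed(i)
    decision_tree(rnorm(10, 8), rnorm(10, 5), rnorm(10, 5))
  })
  expect_gte(mean(vapply(res, `[[`, logical(1), "significant")), 0.9)
  anova_runs <- Filter(function(cmp) cmp$branch_taken == "anova_tukey", res)
  expect_gt(length(anova_runs), 50L)  # gates pass at ~0.95^3 * 0.95
  sig_on_anova <- vapply(anova_runs, `[[`, logical(1), "significant")
  expect_gte(mean(sig_on_anova), 0.9)

  # non-normal data forces the nonparametric branch regardless of variances
  kw <- vapply(1:50, function(i) {
    set.seed(i + 300)
    decision_tree(rexp(30), rnorm(30, 5), rnorm(30, 5))$branch_taken
  }, character(1))
  expect_gte(mean(kw == "kw_mwu"), 0.9)
})

test_that("Dunn-Sidak adjustment and the dual-control rule are exact", {
  expect_equal(dunn_sidak_alpha(0.05, 3), 1 - 0.95^(1 / 3))
  expect_equal(dunn_sidak_alpha(0.05, 3), 0.0169524, tolerance = 1e-5)

  expect_true(dual_control_rule(c(TRUE, TRUE, FALSE)))
  expect_false(dual_control_rule(c(TRUE, FALSE, FALSE)))
  expect_false(dual_control_rule(c(FALSE, TRUE, FALSE)))
  expect_false(dual_control_rule(c(TRUE, TRUE, TRUE)))
  expect_false(dual_control_rule(c(FALSE, FALSE, FALSE)))
  expect_false(dual_control_rule(c(FALSE, FALSE, TRUE)))
})

test_that("dual-control false positives stay below 1.5 alpha under the null", {
  fp <- vapply(1:2000, function(i) {
    set.seed(i)
    decision_tree(rnorm(10, 5), rnorm(10, 5), rnorm(10, 5))$significant
  }, logical(1))
  expect_lte(mean(fp), 0.05 * 1.5)
})

test_that("trial tables flow through scoring into the decision tree", {
  set.seed(8)
  # protocol replication: 10 tubes per sex per genotype
  mk <- function(genotype, mu) do.call(rbind, lapply(1:20, function(tube) {
    data.frame(genotype = genotype, sex = ifelse(tube > 10, "m", "f"),
               tube_id = paste0(genotype, tube), trial_index = 1:15,
               count_above_mark = pmin(10, pmax(0, round(rnorm(15, mu, 1)))))
  }))
  trials <- rbind(mk("exp", 3), mk("uas", 7), mk("gal4", 7))
  tf <- tempfile(fileext = ".tsv")
  write.table(trials, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_sing_tsv(tf)
  out <- run_behavior(tab, "exp", "uas", "gal4")
  expect_true(all(c("branch", "significant") %in% names(out)))
  pooled <- out[out$sex == "pooled", ]
  expect_true(pooled$significant)
  writeLines("a\tb", tf)
  expect_error(read_sing_tsv(tf), "columns")
})
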