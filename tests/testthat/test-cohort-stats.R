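two_visit_cohort <- function(visits) {
  # visits: list(group -> c(v1, v2)) for one task; two identical subjects
  # per group so group summaries are exact
  rows <- lapply(names(visits), function(g) {
    data.frame(subject_id = paste0(g, 1:2), diagnosis = g,
               ppt_both_v1 = visits[[g]][1], ppt_both_v2 = visits[[g]][2],
               updrs_v1 = 10, updrs_v2 = 12, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("one-year change is visit2 minus visit1, by subject", {
  ch <- two_visit_cohort(list(MSA = c(9.870, 6.957), PSP = c(8.718, 5.923),
                              HC = c(20.70, 20.70)))
  cs <- one_year_change(ch, tasks = "both")
  sm <- change_summary(cs)
  expect_equal(sm$mean_change[sm$diagnosis == "MSA"], -2.913)
  expect_equal(sm$mean_change[sm$diagnosis == "PSP"], -2.795)
  expect_equal(sm$mean_change[sm$diagnosis == "HC"], 0)
})

test_that("subjects missing a visit are excluded with a message", {
  ch <- two_visit_cohort(list(PD = c(10, 9), HC = c(12, 12)))
  ch$ppt_both_v2[1] <- NA
  expect_message(cs <- one_year_change(ch, tasks = "both"), "excluded")
  expect_equal(nrow(cs), 3L)
})

test_that("one-way ANOVA reproduces the textbook 3x3 example", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  fit <- oneway_anova(vals, grp)
  expect_equal(fit$f, 3.0)
  expect_equal(fit$df, c(2, 6))
  expect_equal(fit$p, pf(3, 2, 6, lower.tail = FALSE))
})

test_that("two-group ANOVA F equals the squared pooled t", {
  set.seed(43)
  a <- rnorm(20); b <- rnorm(25, 0.5)
  fit <- oneway_anova(c(a, b), rep(c("a", "b"), c(20, 25)))
  t_pooled <- t.test(a, b, var.equal = TRUE)$statistic
  expect_equal(fit$f, unname(t_pooled^2), tolerance = 1e-9)
})

test_that("a group with one record is rejected", {
  expect_error(oneway_anova(1:5, c("a", "a", "a", "a", "b")), "at least 2")
})

test_that("independent covariates barely move the ANOVA F", {
  set.seed(47)
  n <- 400
  grp <- rep(c("a", "b"), each = n / 2)
  y <- rnorm(n) + (grp == "b") * 0.4
  covs <- data.frame(age = rnorm(n), sex = factor(rep(c("M", "F"), n / 2)))
  f0 <- oneway_anova(y, grp)$f
  f1 <- oneway_anova(y, grp, covs)$f
  expect_lt(abs(f1 - f0) / f0, 0.05)
})

test_that("mixed ANCOVA matches the classical mixed-model aov decomposition", {
  set.seed(53)
  n_per <- 10; k <- 3
  subj <- factor(rep(1:(3 * n_per), each = k))
  grp <- factor(rep(rep(c("a", "b", "c"), each = n_per), each = k))
  wit <- factor(rep(paste0("w", 1:k), times = 3 * n_per))
  y <- rnorm(3 * n_per * k) + (grp == "b") * 0.5 + (wit == "w2") * 0.3
  d <- data.frame(y, subj, grp, wit)
  ours <- mixed_ancova(d, "y", "subj", "wit", "grp")
  ref <- summary(aov(y ~ grp * wit + Error(subj / wit), data = d))
  f_b <- ref[["Error: subj"]][[1]]["grp", "F value"]
  f_w <- ref[["Error: subj:wit"]][[1]][c("wit", "grp:wit"), "F value"]
  tab <- ours$table
  expect_equal(tab$f[tab$effect == "grp"], f_b, tolerance = 1e-9)
  expect_equal(tab$f[tab$effect == "wit"], f_w[1], tolerance = 1e-9)
  expect_equal(tab$f[tab$effect == "wit:grp"], f_w[2], tolerance = 1e-9)
  expect_true(ours$gg_epsilon > 0.5 && ours$gg_epsilon <= 1)
})

test_that("a planted time-by-group interaction is detected reliably", {
  hits <- sapply(1:200, function(rep_i) {
    set.seed(6000 + rep_i)
    n <- 60
    grp <- rep(c("decliner", "flat1", "flat2", "flat3"), each = n)
    v1 <- rnorm(4 * n, 10, 1)
    v2 <- v1 + rnorm(4 * n, 0, 1) - (grp == "decliner") * 1.5
    d <- data.frame(
      subject = rep(seq_len(4 * n), 2),
      visit = rep(c("v1", "v2"), each = 4 * n),
      grp = rep(grp, 2), score = c(v1, v2))
    fit <- mixed_ancova(d, "score", "subject", "visit", "grp")
    fit$table$p[fit$table$effect == "visit:grp"] < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("covariates independent of outcome leave the interaction F alone", {
  set.seed(59)
  n <- 200
  grp <- rep(c("a", "b"), each = n)
  v1 <- rnorm(2 * n, 10, 1)
  v2 <- v1 + rnorm(2 * n, 0, 1) - (grp == "a") * 0.3
  d <- data.frame(subject = rep(seq_len(2 * n), 2),
                  visit = rep(c("v1", "v2"), each = 2 * n),
                  grp = rep(grp, 2), age = rep(rnorm(2 * n), 2),
                  score = c(v1, v2))
  f0 <- mixed_ancova(d, "score", "subject", "visit", "grp")
  f1 <- mixed_ancova(d, "score", "subject", "visit", "grp", "age")
  i0 <- f0$table$f[f0$table$effect == "visit:grp"]
  i1 <- f1$table$f[f1$table$effect == "visit:grp"]
  expect_lt(abs(i1 - i0) / i0, 0.05)
})

test_that("incomplete within-subject cells are dropped with a message", {
  d <- data.frame(subject = c(1, 1, 2, 2, 3, 4, 4, 5, 5, 6, 6),
                  visit = c("v1", "v2", "v1", "v2", "v1",
                            "v1", "v2", "v1", "v2", "v1", "v2"),
                  grp = c("a", "a", "a", "a", "a",
                          "b", "b", "b", "b", "a", "a"),
                  score = rnorm(11))
  expect_message(fit <- mixed_ancova(d, "score", "subject", "visit", "grp"),
                 "dropped")
  expect_equal(fit$n_subjects, 5)
  expect_equal(fit$n_dropped, 1)
})

test_that("Benjamini-Hochberg adjustment follows the step-up arithmetic", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.42), 0.42)
  set.seed(61)
  p <- runif(25)
  expect_equal(fdr_bh(p), naive_bh(p))
  expect_true(all(fdr_bh(p) >= p))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_bh(numeric(0)), "empty")
})

test_that("post hoc family under the null controls false discoveries", {
  fdp <- sapply(1:1000, function(i) {
    set.seed(7000 + i)
    ch <- data.frame(
      subject_id = as.character(1:40),
      diagnosis = rep(c("PD", "PSP", "MSA", "HC"), each = 10),
      ppt_both_v1 = rnorm(40, 10), ppt_both_v2 = rnorm(40, 10),
      updrs_v1 = 10, updrs_v2 = 10)
    cs <- one_year_change(ch, tasks = "both")
    ph <- posthoc_group_changes(cs, "both")
    any(ph$p_adj < 0.05)
  })
  # all nulls: any discovery is false; BH keeps the rate near alpha
  expect_lte(mean(fdp), 0.07)
})

test_that("a planted 1-SD group decline difference survives FDR", {
  hits <- sapply(1:200, function(i) {
    set.seed(8000 + i)
    n <- 100
    ch <- data.frame(
      subject_id = as.character(seq_len(2 * n)),
      diagnosis = rep(c("PD", "HC"), each = n),
      ppt_both_v1 = rnorm(2 * n, 12, 2), updrs_v1 = 10, updrs_v2 = 10)
    ch$ppt_both_v2 <- ch$ppt_both_v1 + rnorm(2 * n, 0, 2) -
      (ch$diagnosis == "PD") * 2
    cs <- one_year_change(ch, tasks = "both")
    ph <- posthoc_group_changes(cs, "both")
    ph$p_adj[ph$comparison == "HC vs PD"] < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("a single post hoc comparison is not adjusted", {
  ch <- data.frame(subject_id = as.character(1:20),
                   diagnosis = rep(c("PD", "HC"), each = 10),
                   ppt_both_v1 = rnorm(20), ppt_both_v2 = rnorm(20),
                   updrs_v1 = 1, updrs_v2 = 1)
  cs <- one_year_change(ch, tasks = "both")
  ph <- posthoc_group_changes(cs, "both", comparisons = list(c("HC", "PD")))
  expect_equal(ph$p_adj, ph$p)
  expect_error(posthoc_group_changes(cs, "both", comparisons = list()),
               "empty")
})

test_that("sensor tests reproduce a hand-worked Welch t", {
  feats <- data.frame(diagnosis = rep(c("A", "B"), each = 3),
                      sensor = "DH", task = "dominant",
                      sd_accel = c(1, 2, 3, 2, 3, 4), apen = 0.1)
  out <- sensor_group_tests(feats, "sd_accel", "dominant")
  oracle <- naive_welch(c(1, 2, 3), c(2, 3, 4))
  expect_equal(out$t, oracle$t, tolerance = 1e-9)
  expect_equal(out$t, -1.2247, tolerance = 1e-4)
  expect_equal(out$df, oracle$df, tolerance = 1e-9)
  expect_equal(out$df, 4, tolerance = 1e-9)
})

test_that("identical groups give small sensor t statistics on average", {
  set.seed(67)
  n <- 200
  feats <- do.call(rbind, lapply(c("NDH", "NDB", "DH", "DB", "HD"),
    function(s) data.frame(diagnosis = rep(c("PD", "HC"), each = n),
                           sensor = s, task = "both",
                           sd_accel = rnorm(2 * n, 0.05, 0.01),
                           apen = 0.1)))
  out <- sensor_group_tests(feats, "sd_accel", "both")
  # null case: signed t statistics centred on zero (single-family FDR
  # error control is exercised in the post hoc null simulation)
  expect_lt(abs(mean(out$t)), 2.5 / sqrt(5))
  expect_true(all(out$p_adj >= out$p))
  expect_true(all(out$p_adj <= 1))
})

test_that("undersized sensor groups are skipped with a message", {
  feats <- data.frame(diagnosis = c("PD", "PD", "HC", "PD", "PD", "HC", "HC"),
                      sensor = c("DH", "DH", "DH", "DB", "DB", "DB", "DB"),
                      task = "dominant",
                      sd_accel = rnorm(7), apen = 0.1)
  expect_message(out <- sensor_group_tests(feats, "sd_accel", "dominant"),
                 "skipped")
  expect_equal(out$sensor, "DB")
})

test_that("correlations reproduce the rank-difference formula", {
  out <- correlate_changes(c(1, 2, 3), c(3, 1, 2))
  expect_equal(out$estimate, -0.5)
  expect_equal(out$estimate, naive_spearman(c(1, 2, 3), c(3, 1, 2)))
  expect_equal(correlate_changes(1:10, (1:10)^3)$estimate, 1)
  expect_equal(correlate_changes(1:10, 2 * (1:10) + 1, "pearson")$estimate, 1)
  expect_error(correlate_changes(rep(1, 5), 1:5), "zero variance")
  expect_error(correlate_changes(1:2, 1:2), "3 complete pairs")
})
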