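test_that("the gated two-group comparison matches the pooled-variance t oracle", {
  res <- compare_two_groups(c(1, 2, 3, 4), c(2, 3, 4, 5), method = "t")
  # hand-computed pooled-variance oracle
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  sp <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  t_oracle <- (mean(a) - mean(b)) / (sp * sqrt(1 / 4 + 1 / 4))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 6), tolerance = 1e-12)
})

test_that("identical and degenerate groups are handled per the test definitions", {
  res <- compare_two_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  tie <- compare_two_groups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(tie$statistic, 0)
  expect_equal(tie$p, 1)
  diffc <- compare_two_groups(c(2, 2, 2), c(3, 3, 3))
  expect_equal(diffc$p, 0)
  expect_error(compare_two_groups(1, c(1, 2)),
               class = "pulmomech_invalid_spec")
})

test_that("the normality gate routes skewed samples to the Mann-Whitney test", {
  skewed_a <- c(rep(0.1, 12), 40, 55, 90)
  skewed_b <- c(rep(0.2, 12), 35, 60, 80)
  res <- compare_two_groups(skewed_a, skewed_b)
  expect_identical(res$test, "mann-whitney")
  expect_false(res$gate$both_normal)
  normal_res <- compare_two_groups(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_identical(normal_res$test, "t")
})

test_that("two-group test type-I error is calibrated at the nominal level", {
  set.seed(314)
  n_rep <- 5000
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    r <- compare_two_groups(rnorm(8), rnorm(8))
    if (r$p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("a constant response yields zero F for every effect", {
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:3)
  d$y <- 5
  res <- two_way_anova(d, "y", "A", "B")
  expect_equal(res$table$F, c(0, 0, 0))
  expect_equal(res$table$p, c(1, 1, 1))
})

test_that("two-way ANOVA F values match the projection-matrix oracle on balanced designs", {
  set.seed(7)
  d <- expand.grid(A = factor(c("a1", "a2")), B = factor(c("b1", "b2")),
                   rep = 1:4)
  d$y <- 2 + (d$A == "a2") * 1.5 + (d$B == "b2") * 0.7
  d$y[5] <- d$y[5] + 1        # single perturbed value
  res <- two_way_anova(d, "y", "A", "B")
  oracle <- oracle_anova_F(d$y, d$A, d$B)
  expect_equal(res$table$F, unname(oracle), tolerance = 1e-10)
  # a second balanced fixture with noise everywhere
  d$y2 <- rnorm(nrow(d))
  res2 <- two_way_anova(d, "y2", "A", "B")
  expect_equal(res2$table$F, unname(oracle_anova_F(d$y2, d$A, d$B)),
               tolerance = 1e-10)
  expect_error(two_way_anova(d[d$A == "a1" | d$B == "b1", ], "y", "A", "B"),
               class = "pulmomech_invalid_spec")
})

test_that("a region effect with no strain effect is detected with correct specificity", {
  set.seed(99)
  regions <- c("pleura", "septum", "adventitia", "media")
  hits_region <- 0L; null_strain <- 0L
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    d <- expand.grid(region = regions, strain = c("WT", "MFS"), rep = 1:3)
    d$E <- 10 + (d$region == "media") * 4 + rnorm(nrow(d), 0, 1.5)
    tab <- two_way_anova(d, "E", "region", "strain")$table
    if (tab$p[tab$effect == "region"] < 0.05) hits_region <- hits_region + 1L
    if (tab$p[tab$effect == "strain"] > 0.05) null_strain <- null_strain + 1L
  }
  expect_gte(hits_region / n_rep, 0.90)
  expect_gte(null_strain / n_rep, 0.90)
})

test_that("repeated-measures ANOVA partitions the within-subject error", {
  set.seed(12)
  d <- expand.grid(freq = factor(c("f1", "f2", "f3", "f4")),
                   subj = factor(1:10))
  d$strain <- factor(ifelse(as.integer(d$subj) <= 5, "WT", "MFS"))
  d$y <- rnorm(nrow(d)) + as.integer(d$freq) * 0.8
  res <- two_way_anova(d, "y", "freq", "strain", repeated = "freq",
                       subject = "subj")
  expect_identical(res$table$effect,
                   c("freq", "strain", "freq:strain"))
  expect_true(all(is.finite(res$table$F)))
  expect_lt(res$table$p[res$table$effect == "freq"], 0.05)
  # the between-subject factor's F uses the subject stratum: compare with aov
  ref <- summary(aov(y ~ freq * strain + Error(subj / freq), data = d))
  Fs <- unlist(lapply(ref, function(s) as.data.frame(s[[1]])[["F value"]]))
  expect_true(all(res$table$F %in% Fs[is.finite(Fs)]))
})

test_that("Holm-Sidak adjustment follows the hand-stepped formula with monotonicity", {
  hs <- holm_sidak(c(0.01, 0.04, 0.03))
  expect_equal(hs$p_adjusted,
               c(1 - 0.99^3, max(1 - 0.97^2, 1 - 0.96), 1 - 0.97^2),
               tolerance = 1e-12)
  one <- holm_sidak(0.04)
  expect_equal(one$p_adjusted, 0.04)
  expect_true(one$reject)
  all1 <- holm_sidak(rep(1, 5))
  expect_equal(all1$p_adjusted, rep(1, 5))
  expect_false(any(all1$reject))
  empty <- holm_sidak(numeric(0))
  expect_length(empty$p_adjusted, 0)
  expect_error(holm_sidak(c(0.2, 1.4)), class = "pulmomech_invalid_spec")
})

test_that("adjusted p values are sorted-monotone and never below the raw values", {
  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(1:12, 1))
    hs <- holm_sidak(p)
    expect_true(all(hs$p_adjusted >= p - 1e-15))
    ord <- order(p)
    expect_true(all(diff(hs$p_adjusted[ord]) >= -1e-15))
    expect_true(all(hs$p_adjusted <= 1))
  }
})
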