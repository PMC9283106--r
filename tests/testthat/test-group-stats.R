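make_meta <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("s%03d", 1:n),
             age = runif(n, 6, 83),
             IQ = pmin(pmax(rnorm(n, 100, 15), 55), 145),
             stringsAsFactors = FALSE)
}

test_that("bootstrap ensembles are reproducible and honor the ordering", {
  atlas <- generate_atlas("DKA")
  coh <- make_test_cohort(n_subjects = 10, atlas = atlas)
  msns <- lapply(seq_along(coh$subjects), function(s)
    build_msn(coh$features[[s]], "9f", subject = coh$subjects[s]))
  names(msns) <- coh$subjects
  meta <- data.frame(subject_id = coh$subjects, age = coh$age, IQ = coh$iq,
                     stringsAsFactors = FALSE)

  e1 <- bootstrap_ensemble(msns, meta, n_boot = 4, ordering = "age",
                           seed = 5, n_samples = 3)
  e2 <- bootstrap_ensemble(msns, meta, n_boot = 4, ordering = "age",
                           seed = 5, n_samples = 3)
  expect_identical(e1$F, e2$F)
  expect_identical(e1$f_matrix, e2$f_matrix)
  expect_length(e1$profiles, 4)

  # ages non-decreasing within every bootstrap
  for (idx in e1$resamples)
    expect_true(all(diff(coh$age[idx]) >= 0))

  # resamples are with replacement at cohort size
  expect_true(all(vapply(e1$resamples, length, 0L) == 10))
  expect_true(any(vapply(e1$resamples, anyDuplicated, 0L) > 0))

  bad_meta <- meta; bad_meta$IQ[3] <- NA
  expect_error(bootstrap_ensemble(msns, bad_meta, n_boot = 2,
                                  ordering = "IQ", seed = 1, n_samples = 1),
               coh$subjects[3])
})

test_that("IQ grouping splits strictly beyond one standard deviation", {
  m <- data.frame(subject_id = c("a", "b", "c"), IQ = c(70, 100, 130))
  g <- make_iq_groups(m)       # mean 100, sd 30: boundaries land in group 2
  expect_equal(g$group, c(2L, 2L, 2L))
  expect_equal(as.integer(table(factor(g$group, levels = 1:3))),
               c(0L, 3L, 0L))

  expect_error(make_iq_groups(data.frame(subject_id = 1:3,
                                         IQ = c(100, 100, 100))),
               "zero")

  # normal cohort: each tail holds roughly 16% of subjects
  meta <- make_meta(500, seed = 4)
  g2 <- make_iq_groups(meta)
  tails <- c(mean(g2$group == 1), mean(g2$group == 3))
  expect_true(all(tails > 0.16 - 4 * sqrt(0.16 * 0.84 / 500)))
  expect_true(all(tails < 0.16 + 4 * sqrt(0.16 * 0.84 / 500)))

  # balancing subsamples the middle group to the larger tail
  gb <- make_iq_groups(meta, balance = TRUE, seed = 2)
  expect_equal(sum(gb$group == 2),
               max(sum(gb$group == 1), sum(gb$group == 3)))
  gb2 <- make_iq_groups(meta, balance = TRUE, seed = 2)
  expect_identical(gb, gb2)
})

test_that("age bins follow the 12-bin scheme", {
  m <- data.frame(subject_id = c("a", "b", "c", "d", "e"),
                  age = c(7, 70, 63, 6, 85))
  b <- make_age_bins(m)
  expect_equal(b$bin, c(1L, 12L, 11L, 1L, 12L))

  # every subject in exactly one bin, bins 1..12 only
  meta <- make_meta(300, seed = 6)
  bb <- make_age_bins(meta)
  expect_false(any(is.na(bb$bin)))
  expect_true(all(bb$bin %in% 1:12))

  expect_error(make_age_bins(data.frame(subject_id = "x", age = 90)), "x")
  expect_error(make_age_bins(data.frame(subject_id = "y", age = 3)), "y")
})

test_that("KS normality check behaves under null and alternative", {
  ps <- vapply(1:100, function(s) {
    set.seed(s)
    ks_normality(rnorm(300))$p_value
  }, 0)
  expect_gte(mean(ps > 0.05), 0.9)

  # power against a flat distribution (studentized; large n needed)
  pu <- vapply(1:25, function(s) {
    set.seed(100 + s)
    ks_normality(runif(2000))$p_value
  }, 0)
  expect_true(all(pu < 0.01))

  r <- ks_normality(rnorm(50))
  expect_gte(r$statistic, 0)
  expect_lte(r$statistic, 1)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(rnorm(3)), "5")
})

test_that("Kruskal-Wallis reproduces hand-computed values", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, 7.2)
  expect_equal(r$df, 2)

  same <- kruskal_wallis(list(1:10, 1:10))
  expect_equal(same$statistic, 0)
  expect_gte(same$p_value, 0)
  expect_lte(same$p_value, 1)

  expect_error(kruskal_wallis(list(1:5)), "2 groups")
  expect_error(kruskal_wallis(list(1:5, 3)), "2 values")

  # pairwise follow-up appears only when the omnibus test is significant
  set.seed(2)
  sig <- kruskal_wallis(list(rnorm(20), rnorm(20) + 5, rnorm(20) + 10))
  expect_true(is.matrix(sig$pairwise))
  expect_true(all(sig$pairwise <= 1, na.rm = TRUE))
})

test_that("KW type-I error is calibrated near the nominal level", {
  rej <- vapply(1:500, function(s) {
    set.seed(9000 + s)
    kruskal_wallis(list(rnorm(35), rnorm(35), rnorm(35)),
                   posthoc = FALSE)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("edge-weight correlations recover linear and null relations", {
  # perfectly linear in age
  d <- data.frame(mean_positive = 1:10 / 10, mean_negative = -(1:10) / 20,
                  age = 20 + 2 * (1:10))
  r <- correlate_edge_weights(d, "age")
  expect_equal(r$r[r$sign == "positive"], 1)
  expect_equal(r$r[r$sign == "negative"], -1)

  # 3-point hand example against the closed form
  d3 <- data.frame(mean_positive = c(0.2, 0.5, 0.3),
                   mean_negative = c(-0.1, -0.4, -0.2),
                   age = c(10, 20, 40))
  r3 <- correlate_edge_weights(d3, "age")
  closed <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(r3$r[1], closed(c(0.2, 0.5, 0.3), c(10, 20, 40)))

  # independent covariate: small correlations in most seeds
  n <- 100
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    d0 <- data.frame(mean_positive = rnorm(n), mean_negative = rnorm(n),
                     age = rnorm(n))
    abs(correlate_edge_weights(d0, "age")$r[1]) < 3 / sqrt(n)
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  expect_error(correlate_edge_weights(
    data.frame(mean_positive = 1:5, mean_negative = 1:5, age = rep(1, 5)),
    "age"), "zero-variance")
  expect_error(correlate_edge_weights(d3[1:2, ], "age"), "3 subjects")
})
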