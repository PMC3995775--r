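test_that("paired Wilcoxon matches exact enumeration at small n", {
  # n = 8 all-positive differences: two one-sided extremes out of 2^8
  a <- c(5, 6, 7, 8, 9, 10, 11, 12)
  b <- a - c(1, 2.2, 0.5, 3, 1.7, 2.9, 0.4, 1.1)
  wt <- paired_wilcoxon(a, b)
  expect_equal(wt$p_value, 2 / 256)
  expect_true(wt$exact)
  expect_equal(wt$statistic, sum(1:8))

  # independent oracle at n = 12: full enumeration of sign patterns
  set.seed(71)
  d <- round(rnorm(12, 0.4, 1), 3)
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  v_obs <- sum(ranks[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% ranks
  p_exact <- mean(abs(v_all - n * (n + 1) / 4) >= abs(v_obs - n * (n + 1) / 4))
  wt <- paired_wilcoxon(d + 10, rep(10, n))
  expect_equal(wt$p_value, p_exact, tolerance = 1e-12)

  # normal approximation (continuity-corrected) agrees with enumeration
  # to within 0.02
  z <- (abs(v_obs - n * (n + 1) / 4) - 0.5) /
    sqrt(n * (n + 1) * (2 * n + 1) / 24)
  p_normal <- 2 * stats::pnorm(-z)
  expect_lt(abs(p_normal - p_exact), 0.02)
})

test_that("paired Wilcoxon drops zero differences and rejects degenerate input", {
  a <- c(1, 2, 3, 4, 5, 6)
  expect_error(paired_wilcoxon(a, a), class = "gv_degenerate_test")
  b <- a
  b[1:2] <- b[1:2] + c(0.5, -0.3) # four zero differences remain
  wt <- paired_wilcoxon(b, a)
  expect_equal(wt$n_nonzero, 2)
  expect_equal(wt$n_pairs, 6)
})

test_that("paired Wilcoxon is invariant to adding a constant to both members", {
  set.seed(72)
  a <- rnorm(30, 5)
  b <- rnorm(30, 4.5)
  expect_equal(
    paired_wilcoxon(a, b)$p_value,
    paired_wilcoxon(a + 17.3, b + 17.3)$p_value
  )
})

test_that("variance F test is two-sided, symmetric, and matches var.test", {
  set.seed(73)
  a <- rnorm(40, sd = 3.2)
  b <- rnorm(35, sd = 2.7)
  ft <- variance_f_test(a, b)
  expect_gte(ft$statistic, 1)
  # symmetry in the arguments
  ft_swapped <- variance_f_test(b, a)
  expect_equal(ft$p_value, ft_swapped$p_value)
  expect_equal(ft$statistic, ft_swapped$statistic)
  # oracle: var.test's two-sided p is identical
  expect_equal(ft$p_value, stats::var.test(a, b)$p.value, tolerance = 1e-12)

  ident <- rnorm(10)
  ft1 <- variance_f_test(ident, ident)
  expect_equal(ft1$statistic, 1)
  expect_equal(ft1$p_value, 1)

  expect_error(variance_f_test(rep(1, 5), rnorm(5)), class = "gv_degenerate_test")
})

test_that("unequal variances like the normal-cohort spreads are detected at n = 150", {
  # closed-form tail: SDs 3.2 vs 2.7 at n = 150 per group
  f <- (3.2 / 2.7)^2
  p <- 2 * stats::pf(f, 149, 149, lower.tail = FALSE)
  expect_lt(p, 0.05)
  # and the test statistic reproduces that p on samples scaled to those SDs
  set.seed(74)
  a <- rnorm(150)
  b <- rnorm(150)
  a <- (a - mean(a)) / sd(a) * 3.2
  b <- (b - mean(b)) / sd(b) * 2.7
  expect_equal(variance_f_test(a, b)$p_value, p, tolerance = 1e-9)
})

test_that("cohort_summary matches a brute-force recomputation", {
  set.seed(75)
  res <- tibble::tibble(
    shoulder_id = rep(sprintf("s%d", 1:20), 2),
    method = rep(c("conventional", "vault"), each = 20),
    version_deg = rnorm(40, 5, 4)
  )
  s <- cohort_summary(res, method)
  for (m in c("conventional", "vault")) {
    v <- res$version_deg[res$method == m]
    row <- s[s$method == m, ]
    expect_equal(row$n, length(v))
    expect_equal(row$mean_deg, sum(v) / length(v))
    expect_equal(row$sd_deg, sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
    expect_equal(row$min_deg, min(v))
    expect_equal(row$max_deg, max(v))
  }
})

test_that("compare_methods reproduces hand-computed statistics on a toy table", {
  res <- tibble::tibble(
    shoulder_id = rep(c("a", "b", "c", "d", "e"), each = 2),
    method = rep(c("conventional", "vault"), 5),
    version_deg = c(1, 9, -2, 4, 3, 10, 0, 6.5, 2, 7)
  )
  comp <- compare_methods(res)
  expect_equal(comp$n_shoulders, 5)
  conv <- c(1, -2, 3, 0, 2)
  vault <- c(9, 4, 10, 6.5, 7)
  expect_equal(comp$mean_difference_deg, mean(vault - conv))
  expect_equal(
    comp$summary$mean_deg[comp$summary$method == "vault"], mean(vault)
  )
  expect_equal(
    comp$summary$sd_deg[comp$summary$method == "conventional"], sd(conv)
  )
  # all five differences positive: exact two-sided p = 2/2^5
  expect_equal(comp$wilcoxon$p_value, 2 / 32)
  g <- glance(comp)
  expect_equal(g$mean_difference_deg, comp$mean_difference_deg)
})

test_that("compare_methods with identical methods is degenerate", {
  res <- tibble::tibble(
    shoulder_id = rep(sprintf("s%d", 1:6), each = 2),
    method = rep(c("conventional", "vault"), 6),
    version_deg = rep(rnorm(6), each = 2)
  )
  expect_error(compare_methods(res), class = "gv_degenerate_test")
})

test_that("compare_sides detects a dominance shift and flips with relabelled sides", {
  set.seed(76)
  spec <- cohort_spec(preset = "paired_dominance", n_shoulders = 150)
  cohort <- generate_cohort(spec, seed = 77)
  res <- measure_version(cohort$landmarks)
  comp <- compare_sides(res)
  expect_equal(comp$n_pairs, 75)
  tests <- comp$tests
  expect_true(all(tests$mean_shift_deg > 0))
  expect_true(all(tests$p_value < 0.05))

  # relabelling the sides flips the sign of the shift, p unchanged
  flipped <- res
  flipped$dominance <- ifelse(
    flipped$dominance == "dominant", "nondominant", "dominant"
  )
  comp_f <- compare_sides(flipped)
  expect_equal(comp_f$tests$mean_shift_deg, -tests$mean_shift_deg)
  expect_equal(comp_f$tests$p_value, tests$p_value)
})

test_that("zero dominance shift rejects at roughly the nominal rate", {
  set.seed(78)
  spec <- cohort_spec(
    preset = "paired_dominance",
    n_shoulders = 40, dominance_shift_deg = 0
  )
  pvals <- vapply(1:40, function(i) {
    cohort <- generate_cohort(spec, seed = 1000 + i)
    res <- measure_version(cohort$landmarks, method = "vault")
    compare_sides(res)$tests$p_value
  }, numeric(1))
  # 40 null replicates: rejections should be rare (binomial 40, 0.05)
  expect_lte(sum(pvals < 0.05), 7)
})

test_that("compare_sides rejects subjects lacking one side", {
  res <- tibble::tibble(
    subject_id = c("p1", "p1", "p2"),
    dominance = c("dominant", "nondominant", "dominant"),
    method = "vault",
    version_deg = c(9, 8, 10)
  )
  expect_error(compare_sides(res), regexp = "p2", class = "gv_validation_error")
})

test_that("aggregate_ratings averages over raters and sessions", {
  ratings <- tidyr::expand_grid(
    shoulder_id = c("a", "b"),
    method = c("conventional", "vault"),
    rater = c("r1", "r2", "r3"),
    session = 1:2
  )
  set.seed(79)
  ratings$version_deg <- rnorm(nrow(ratings), 10, 2)
  agg <- aggregate_ratings(ratings)
  expect_equal(nrow(agg), 4)
  manual <- mean(ratings$version_deg[
    ratings$shoulder_id == "a" & ratings$method == "vault"
  ])
  expect_equal(
    agg$version_deg[agg$shoulder_id == "a" & agg$method == "vault"],
    manual
  )
})
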