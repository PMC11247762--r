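test_that("clr transform has the closed form and scale invariance", {
  expect_equal(clr_transform(c(1, 1, 1, 1)), c(0, 0, 0, 0))
  expect_equal(clr_transform(c(1, exp(2))), c(-1, 1))
  set.seed(5)
  for (i in 1:20) {
    x <- rexp(sample(3:12, 1)) + 0.01
    expect_equal(sum(clr_transform(x)), 0, tolerance = 1e-9)
    expect_equal(clr_transform(5 * x), clr_transform(x), tolerance = 1e-12)
  }
  expect_error(clr_transform(c(1, 0)), "positive")
  # matrix form transforms columns independently
  m <- cbind(c(1, exp(2)), c(2, 2))
  expect_equal(clr_transform(m), cbind(c(-1, 1), c(0, 0)))
})

test_that("Dirichlet Monte-Carlo instances live on the simplex and are
           reproducible", {
  inst <- dirichlet_mc_instances(c(5L, 0L, 3L), n_mc = 50, seed = 9)
  expect_true(all(inst > 0))
  expect_equal(colSums(inst), rep(1, 50), tolerance = 1e-12)
  inst2 <- dirichlet_mc_instances(c(5L, 0L, 3L), n_mc = 50, seed = 9)
  expect_identical(unclass(inst), unclass(inst2))
  expect_false(identical(
    unclass(dirichlet_mc_instances(c(5L, 0L, 3L), n_mc = 50, seed = 10)),
    unclass(inst)))
  expect_error(dirichlet_mc_instances(c(1L), seed = 1), "length")
  expect_error(dirichlet_mc_instances(c(1L, 2L), prior_mass = 0, seed = 1),
               "prior_mass")
})

test_that("posterior mean under the half prior matches the analytic
           Dirichlet mean", {
  # counts (0, 0), prior 0.5: marginals are Beta(0.5, 0.5), mean 0.5,
  # sd 0.3536; the MC mean over 10000 draws must sit within 3 SE
  inst <- dirichlet_mc_instances(c(0L, 0L), n_mc = 10000, seed = 42)
  se <- sqrt(0.125) / sqrt(10000)
  expect_lt(abs(mean(inst[1, ]) - 0.5), 3 * se)
  expect_lt(abs(mean(inst[2, ]) - 0.5), 3 * se)
})

test_that("studentized range tail is a valid survival function", {
  expect_equal(studentized_range_sf(0, 2, 5), 1)
  expect_equal(studentized_range_sf(0, 7, 123.4), 1)
  q <- seq(0, 10, length.out = 60)
  p <- studentized_range_sf(q, 4, 12.3)
  expect_true(all(diff(p) <= 1e-12))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(studentized_range_sf(1, 1, 5), "k")
  expect_error(studentized_range_sf(1, 3, 0), "df")
  expect_error(studentized_range_sf(-1, 3, 5), "q")
})

test_that("range tail agrees with base R's distribution function", {
  # independent oracle: stats::ptukey, in the regime where it is accurate
  # agreement to ptukey's own accuracy (~1e-6 in places)
  q <- seq(0.05, 10, length.out = 40)
  for (k in c(2, 3, 4, 6)) for (df in c(5, 9.7, 24, 200)) {
    expect_lt(max(abs(studentized_range_sf(q, k, df) -
                        ptukey(q, k, df, lower.tail = FALSE))), 1e-6)
  }
})

test_that("k = 2 reduces to the two-sided t tail", {
  q <- seq(0.05, 12, length.out = 50)
  for (df in c(2, 6.5, 30)) {
    expect_lt(max(abs(studentized_range_sf(q, 2, df) -
                        2 * pt(q / sqrt(2), df, lower.tail = FALSE))),
              1e-8)
  }
})

test_that("Games-Howell matches its closed-form contract", {
  gh <- games_howell(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(gh$estimated_difference, 0)
  expect_equal(gh$t_statistic, 0)
  expect_equal(gh$p_value, 1)
  expect_true(gh$ci_low <= 0 && gh$ci_high >= 0)

  # k = 2: p equals the two-sided Welch t-test p (independent oracle)
  gh2 <- games_howell(list(x = c(0, 0, 1, 1, 2), y = c(5, 6, 7, 8, 9)))
  wt <- t.test(c(0, 0, 1, 1, 2), c(5, 6, 7, 8, 9))
  expect_equal(gh2$p_value, wt$p.value, tolerance = 1e-9)
  expect_equal(gh2$welch_df, unname(wt$parameter), tolerance = 1e-9)

  # label reversal negates d and t, leaves p and CI width unchanged
  gh3 <- games_howell(list(y = c(5, 6, 7, 8, 9), x = c(0, 0, 1, 1, 2)))
  expect_equal(gh3$estimated_difference, -gh2$estimated_difference)
  expect_equal(gh3$t_statistic, -gh2$t_statistic)
  expect_equal(gh3$p_value, gh2$p_value)
  expect_equal(gh3$ci_high - gh3$ci_low, gh2$ci_high - gh2$ci_low,
               tolerance = 1e-12)

  expect_error(games_howell(list(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero-variance")
  expect_error(games_howell(list(a = 1, b = c(1, 2, 3))), "n < 2")
})

test_that("Games-Howell p decreases as the group separation grows", {
  set.seed(31)
  base <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8))
  shifts <- seq(0, 4, by = 0.5)
  res <- vapply(shifts, function(s) {
    g <- base; g$c <- g$c + s
    gh <- games_howell(g)
    hit <- gh$group_a == "a" & gh$group_b == "c"
    c(gh$p_value[hit], abs(gh$estimated_difference[hit]))
  }, numeric(2))
  # p is monotone nonincreasing in |d| for fixed spreads
  ord <- order(res[2, ])
  expect_true(all(diff(res[1, ord]) <= 1e-10))
  expect_true(all(res[1, ] >= 0 & res[1, ] <= 1))
})

test_that("Games-Howell controls the pairwise null error rate", {
  # 4 groups of 10 from one normal distribution; per-pair rejection at
  # alpha = 0.05 stays below 0.07 over 2000 replicates
  set.seed(77)
  rej <- 0L; total <- 0L
  for (r in 1:2000) {
    g <- split(rnorm(40), rep(letters[1:4], each = 10))
    p <- games_howell(g)$p_value
    rej <- rej + sum(p < 0.05)
    total <- total + length(p)
  }
  expect_lte(rej / total, 0.07)
})

test_that("exact signed-rank test matches enumeration and symmetry", {
  expect_equal(wilcoxon_signed_rank_paired(1:5, 1:5)$p_value, 1)

  d <- c(0.3, 1.1, 2.7, 0.6, 1.9, 3.3)
  res <- wilcoxon_signed_rank_paired(d, rep(0, 6))
  bf <- brute_signed_rank(d, rep(0, 6))
  expect_equal(res$statistic, bf$statistic)
  expect_equal(res$p_value, bf$p_value)

  # negating every difference maps W to m(m+1)/2 - W, same p
  res_neg <- wilcoxon_signed_rank_paired(rep(0, 6), d)
  expect_equal(res_neg$statistic, 6 * 7 / 2 - res$statistic)
  expect_equal(res_neg$p_value, res$p_value)

  # agreement with stats::wilcox.test where that is exact (no ties)
  set.seed(19)
  for (i in 1:20) {
    x <- rnorm(9); y <- rnorm(9)
    expect_equal(wilcoxon_signed_rank_paired(x, y)$p_value,
                 wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
  }
  expect_error(wilcoxon_signed_rank_paired(1:3, 1:4), "length")
})

test_that("exact mode handles mid-ranked ties like the enumeration", {
  set.seed(29)
  for (i in 1:40) {
    m <- sample(3:10, 1)
    x <- sample(c(-3:3), m, replace = TRUE) + 0.5 * sample(0:1, m, TRUE)
    y <- rep(0, m)
    res <- wilcoxon_signed_rank_paired(x, y)
    bf <- brute_signed_rank(x, y)
    expect_equal(res$statistic, bf$statistic)
    expect_equal(res$p_value, bf$p_value)
  }
})

test_that("the Pratt zero policy ranks zeros but drops their
           contribution", {
  x <- c(0, 0, 1.5, -0.5, 2, 3)
  y <- rep(0, 6)
  pratt <- wilcoxon_signed_rank_paired(x, y, zero_policy = "pratt")
  # zeros occupy ranks 1.5, 1.5; nonzero ranks are 3..6
  r <- rank(abs(x))[x != 0]
  w_exp <- sum(r[x[x != 0] > 0])
  expect_equal(pratt$statistic, w_exp)
  # exact tail by direct enumeration over the nonzero sign assignments
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 4)))
  w_all <- as.vector(signs %*% r)
  p_exp <- min(1, 2 * min(mean(w_all <= w_exp), mean(w_all >= w_exp)))
  expect_equal(pratt$p_value, p_exp)
  # with no zero differences the two policies coincide
  z <- c(1, -2, 3, -4.5)
  expect_identical(wilcoxon_signed_rank_paired(z, rep(0, 4)),
                   wilcoxon_signed_rank_paired(z, rep(0, 4),
                                               zero_policy = "pratt"))
})

test_that("large-sample approximation tracks the exact tail", {
  set.seed(41)
  x <- rnorm(40, 0.3); y <- rnorm(40)
  appr <- wilcoxon_signed_rank_paired(x, y)
  expect_false(appr$exact)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE,
                     correct = TRUE)$p.value
  expect_equal(appr$p_value, ref, tolerance = 1e-10)
})
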