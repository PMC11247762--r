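test_that("profiles are per-sample means of proportions", {
  cnt <- make_counts(list(
    AMPLICON = matrix(c(50, 50), 2, 1, dimnames = list(c("X", "Y"), NULL))))
  prof <- build_profile(cnt, "order")
  expect_equal(sort(prof$mean_proportion), c(0.5, 0.5))

  # unweighted mean across samples, absent lineage contributes 0
  cnt2 <- make_counts(list(
    SAG = matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("X", "Y"), NULL))))
  prof2 <- build_profile(cnt2, "order")
  expect_equal(prof2$mean_proportion[prof2$lineage == "X"], 0.5)
  expect_equal(prof2$mean_proportion[prof2$lineage == "Y"], 0.5)

  # excluded lineages removed before normalization
  cnt3 <- make_counts(list(
    SAG = matrix(c(10, 90), 2, 1,
                 dimnames = list(c("X", "chloroplast"), NULL))))
  prof3 <- build_profile(cnt3, "order")
  expect_identical(prof3$lineage, "X")
  expect_equal(prof3$mean_proportion, 1.0)

  # a sample left empty by the exclusions is an error naming the sample
  cnt4 <- make_counts(list(
    SAG = matrix(c(0, 5), 2, 1,
                 dimnames = list(c("X", "eukaryote"), NULL))))
  expect_error(build_profile(cnt4, "order"), "zero total.*SAG_s01")
})

test_that("profiles sum to one per method and ignore sample order", {
  set.seed(3)
  mats <- list(SAG = matrix(rpois(30, 20), 5, 6,
                            dimnames = list(paste0("L", 1:5), NULL)),
               MAG = matrix(rpois(30, 20), 5, 6,
                            dimnames = list(paste0("L", 1:5), NULL)))
  cnt <- make_counts(mats)
  prof <- build_profile(cnt, "order")
  sums <- tapply(prof$mean_proportion, prof$method, sum)
  expect_equal(as.numeric(sums), rep(1, 2), tolerance = 1e-9)
  shuffled <- cnt[sample(nrow(cnt)), ]
  expect_equal(build_profile(shuffled, "order"), prof)
})

test_that("rare-lineage lumping follows the either-reference rule", {
  prof <- build_profile(make_counts(list(
    AMPLICON = matrix(c(1, 5, 94), 3, 1,
                      dimnames = list(c("rareA", "midB", "bigC"), NULL)),
    SHOTGUN = matrix(c(1, 1, 98), 3, 1,
                     dimnames = list(c("rareA", "midB", "bigC"), NULL)),
    SAG = matrix(c(30, 30, 40), 3, 1,
                 dimnames = list(c("rareA", "midB", "bigC"), NULL)))),
    "order")
  lumped <- lump_rare(prof, c("AMPLICON", "SHOTGUN"), min_fraction = 0.02)
  # rareA < 2% in both references -> lumped even where SAG has 30%
  expect_false("rareA" %in% lumped$lineage)
  expect_true("Others" %in% lumped$lineage)
  # midB reaches 5% in one reference -> kept
  expect_true("midB" %in% lumped$lineage)
  sums <- tapply(lumped$mean_proportion, lumped$method, sum)
  expect_equal(as.numeric(sums), rep(1, 3), tolerance = 1e-12)
})

test_that("prevalence filter applies a strict per-method threshold", {
  full <- matrix(5, 2, 10, dimnames = list(c("A", "B"), NULL))
  nine <- full; nine["B", 1] <- 0     # B in exactly 9/10 SAG samples
  cnt <- make_counts(list(SAG = nine, MAG = full, AMPLICON = full,
                          SHOTGUN = full))
  expect_identical(prevalence_filter(cnt, "order", 0.9), "A")
  # absent everywhere -> dropped
  zero <- full; zero["B", ] <- 0
  cnt2 <- make_counts(list(SAG = zero, MAG = zero, AMPLICON = zero,
                           SHOTGUN = zero))
  expect_identical(prevalence_filter(cnt2, "order", 0.9), "A")
})

test_that("vectorized differential abundance equals per-cell
           Games-Howell on the same Monte-Carlo draws", {
  set.seed(8)
  mats <- lapply(setNames(nm = c("SAG", "MAG", "AMPLICON", "SHOTGUN")),
                 function(m) matrix(rpois(12, 40), 4, 3,
                                    dimnames = list(paste0("L", 1:4), NULL)))
  cnt <- make_counts(mats)
  n_mc <- 4
  da <- differential_abundance(cnt, "order", n_mc = n_mc, seed = 3,
                               lineages = paste0("L", 1:4))

  # replica: same draws through the exported primitives, looped tests
  cm <- sagmag:::.count_matrix(sagmag:::validate_table(cnt, "counts"),
                               "order",
                               lineages = paste0("L", 1:4))
  a <- array(NA_real_, c(4, n_mc, ncol(cm$counts)))
  for (s in seq_len(ncol(cm$counts)))
    a[, , s] <- clr_transform(unclass(
      dirichlet_mc_instances(cm$counts[, s], n_mc = n_mc,
                             seed = sagmag:::derive_seed(3, s)))) / log(2)
  for (row in sample(nrow(da), 6)) {
    lin <- match(da$lineage[row], paste0("L", 1:4))
    ds <- ps <- numeric(n_mc)
    for (i in seq_len(n_mc)) {
      groups <- split(a[lin, i, ], cm$method)
      gh <- games_howell(groups)
      hit <- gh$group_a == da$method_a[row] & gh$group_b == da$method_b[row]
      ds[i] <- gh$estimated_difference[hit]
      ps[i] <- gh$p_value[hit]
    }
    expect_equal(da$expected_difference[row], mean(ds), tolerance = 1e-10)
    expect_equal(da$expected_p[row], mean(ps), tolerance = 1e-10)
  }
})

test_that("identical count tables for two methods yield no calls", {
  mat <- matrix(c(40, 30, 20, 10), 4, 3,
                dimnames = list(paste0("L", 1:4), NULL))
  cnt <- make_counts(list(SAG = mat, MAG = mat))
  da <- differential_abundance(cnt, "order", n_mc = 1, seed = 5,
                               lineages = paste0("L", 1:4))
  expect_false(any(da$significant))
  expect_true(all(da$expected_p >= 0 & da$expected_p <= 1))
})

test_that("differential abundance is compositionally invariant", {
  set.seed(12)
  mat <- matrix(rpois(40, 50), 4, 10,
                dimnames = list(paste0("L", 1:4), NULL))
  mag <- mat + matrix(rpois(40, 5), 4, 10)
  cnt1 <- make_counts(list(SAG = mat, MAG = mag))
  da1 <- differential_abundance(cnt1, "order", n_mc = 300, seed = 7,
                                lineages = paste0("L", 1:4))
  # doubling all counts: same composition, only the Dirichlet gets
  # sharper; expected differences agree within MC noise
  cnt2 <- make_counts(list(SAG = mat * 2L, MAG = mag * 2L))
  da2 <- differential_abundance(cnt2, "order", n_mc = 300, seed = 7,
                                lineages = paste0("L", 1:4))
  expect_lt(max(abs(da1$expected_difference - da2$expected_difference)),
            0.25)
})

test_that("a planted abundance shift is recovered with its sign", {
  spec0 <- community_spec(n_lineages = 12, n_samples = 10)
  bias <- rep(1, 12); bias[3] <- 8
  spec1 <- community_spec(n_lineages = 12, n_samples = 10,
                          method_bias = list(MAG = bias))
  sim <- simulate_community_counts(spec1, seed = 21)
  lin <- prevalence_filter(sim$counts, "order")
  da <- differential_abundance(sim$counts, "order", n_mc = 200, seed = 22,
                               lineages = lin)
  planted <- sim$truth$planted$lineage
  hits <- da[da$lineage == planted & da$significant, ]
  expect_gt(nrow(hits), 0)
  # MAG is always the side with the planted excess
  mag_side <- ifelse(hits$method_a == "MAG", 1, -1)
  expect_true(all(mag_side * hits$expected_difference > 0))
  # and no pair not involving MAG flags the planted lineage
  non_mag <- da$lineage == planted & da$method_a != "MAG" &
    da$method_b != "MAG"
  expect_false(any(da$significant[non_mag]))
})
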