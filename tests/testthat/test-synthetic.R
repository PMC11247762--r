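test_that("community counts are reproducible and concentrate on the
           truth", {
  spec <- community_spec(n_lineages = 15, n_samples = 20,
                         mean_depth = 1e6, depth_sdlog = 0)
  sim1 <- simulate_community_counts(spec, seed = 5)
  sim2 <- simulate_community_counts(spec, seed = 5)
  expect_identical(sim1, sim2)
  expect_false(identical(
    sim1$counts, simulate_community_counts(spec, seed = 6)$counts))

  # per-lineage mean sample proportion within 3 SE of the truth
  cnt <- sim1$counts[sim1$counts$method == "SHOTGUN", ]
  mat <- do.call(cbind, lapply(split(cnt$count, cnt$sample_id), as.numeric))
  rownames(mat) <- sort(unique(cnt$lineage))
  props <- sweep(mat, 2, colSums(mat), "/")
  truth <- sim1$truth$true_proportions[rownames(mat)]
  se <- sqrt(truth * (1 - truth) / 1e6 / 20)
  expect_true(all(abs(rowMeans(props) - truth) <= 3 * se + 1e-6))
})

test_that("collection sampling reproduces the documented biases", {
  spec <- community_spec(n_lineages = 24, n_samples = 4)
  truth <- simulate_community_counts(spec, seed = 3)$truth
  g <- simulate_genome_collections(truth, n_sag = 150, n_mag = 150,
                                   n_isolate = 10, seed = 8)
  expect_identical(sum(g$collection == "SAG"), 150L)
  expect_identical(sum(g$collection == "MAG"), 150L)
  expect_identical(sum(g$collection == "ISOLATE"), 10L)
  expect_identical(anyDuplicated(g$genome_id), 0L)

  # tau = 1: SAG and MAG lineage frequencies indistinguishable
  ok <- 0L
  for (r in 1:10) {
    gg <- simulate_genome_collections(truth, 200, 200, tau = 1,
                                      seed = 100 + r)
    tab <- table(taxonomy_labels(gg, "order"), gg$collection)
    keep <- rowSums(tab) > 0
    p <- suppressWarnings(chisq.test(tab[keep, ])$p.value)
    ok <- ok + (p > 0.01)
  }
  expect_gte(ok, 8L)

  # tau = 0.3: the rare half of the community is over-represented in MAGs
  rare <- names(sort(truth$true_proportions))[1:12]
  rare_tax <- sprintf("Lineage%02d",
                      match(rare, names(truth$true_proportions)))
  ok2 <- 0L
  for (r in 1:10) {
    gg <- simulate_genome_collections(truth, 200, 200, tau = 0.3,
                                      seed = 200 + r)
    lab <- sub("o__", "", taxonomy_labels(gg, "order"))
    share <- tapply(lab %in% rare_tax, gg$collection, mean)
    ok2 <- ok2 + (share[["MAG"]] > share[["SAG"]])
  }
  expect_gte(ok2, 9L)
})

test_that("a noiseless gene catalog is recovered exactly by clustering", {
  g <- make_genomes(6, collection = c("SAG", "SAG", "SAG", "MAG", "MAG",
                                      "MAG"))
  cat0 <- simulate_gene_catalog(g, n_core = 4, n_flexible = 5,
                                base_dropout = 0, sag_flexible_dropout = 0,
                                mag_flexible_dropout = 0,
                                mutation_rate = 0, gene_length = 60,
                                seed = 31)
  # every genome carries every family
  expect_identical(nrow(cat0$annotations), 6L * 9L)
  cl <- greedy_cluster(cat0$sequences, cluster_params(0.95, 0.9))
  expect_identical(length(unique(cl$cluster_id)), 9L)
})

test_that("within-family mutation stays inside the species threshold", {
  g <- make_genomes(8)
  cat0 <- simulate_gene_catalog(g, n_core = 6, n_flexible = 0,
                                base_dropout = 0, mutation_rate = 0.02,
                                gene_length = 300, seed = 77)
  fams <- sub("^.*:", "", cat0$sequences$seq_id)
  ids <- c()
  for (f in unique(fams)) {
    members <- cat0$sequences[fams == f, ]
    pick <- utils::combn(seq_len(nrow(members)), 2)[, 1:4]
    ids <- c(ids, apply(pick, 2, function(ij)
      pairwise_identity(members[ij[1], ], members[ij[2], ])$identity))
  }
  expect_gt(mean(ids >= 0.95), 0.9)
})

test_that("flexible-gene depletion separates the accumulation curves", {
  g <- rbind(make_genomes(16, collection = "SAG"),
             within(make_genomes(16, collection = "MAG"),
                    genome_id <- sprintf("h%03d", 1:16)))
  cat0 <- simulate_gene_catalog(g, n_core = 10, n_flexible = 30,
                                base_dropout = 0.05,
                                sag_flexible_dropout = 0.1,
                                mag_flexible_dropout = 0.6,
                                mutation_rate = 0, gene_length = 40,
                                seed = 41, emit_sequences = FALSE)
  # use the family annotations directly as perfect clusters
  cl <- data.frame(member_id = cat0$annotations$gene_id,
                   cluster_id = sub("^.*:", "", cat0$annotations$gene_id),
                   stringsAsFactors = FALSE)
  cl$is_representative <- !duplicated(cl$cluster_id)
  genome_of <- setNames(cat0$annotations$genome_id,
                        cat0$annotations$gene_id)
  inc <- incidence_matrix(cl, setNames(g$collection, g$genome_id),
                          genome_of = genome_of)
  sag <- accumulation_curve_exact(inc, "SAG")
  mag <- accumulation_curve_exact(inc, "MAG")
  d <- min(nrow(sag), nrow(mag))
  expect_true(all(sag$expected_richness[2:d] >=
                    mag$expected_richness[2:d]))
  # clearly separated before either curve saturates
  expect_gt(sag$expected_richness[3], mag$expected_richness[3] + 2)
})

test_that("quality reports plant exactly the promised chimeras and
           conflicts", {
  g <- make_genomes(120)
  none <- simulate_quality_reports(g, chimera_fraction = 0,
                                   conflict_fraction = 0, seed = 9)
  calls <- consensus_chimera_call(none$gunc, none$mdm)
  expect_false(any(calls$consensus_call))
  cf <- conflict_16s(g, none$rrna)
  expect_true(all(cf$mismatch_counts == 0))

  planted <- simulate_quality_reports(g, chimera_fraction = 0.05,
                                      conflict_fraction = 0.1, seed = 10)
  calls2 <- consensus_chimera_call(planted$gunc, planted$mdm)
  expect_setequal(calls2$genome_id[calls2$consensus_call],
                  planted$truth$chimera_ids)
  cf2 <- conflict_16s(g, planted$rrna)
  # every planted conflict shows up as a mismatch at its planted rank
  for (i in seq_len(nrow(planted$truth$conflicts))) {
    expect_true(any(
      cf2$mismatches$genome_id == planted$truth$conflicts$genome_id[i] &
        cf2$mismatches$rank == planted$truth$conflicts$rank[i]))
  }
})

test_that("recruitment simulation honors coverage and noise settings", {
  spec <- community_spec(n_lineages = 10, n_samples = 4)
  truth <- simulate_community_counts(spec, seed = 2)$truth
  full <- simulate_recruitment(truth,
                               reference_coverage = c(SAG = 1, MAG = 1),
                               n_samples = 4, n_reads = 500,
                               identity_noise = 0, aln_sd = 0, seed = 3)
  fr <- recruitment_fraction(full, 1.0)
  expect_equal(fr$fraction, rep(1, 8))

  gap <- simulate_recruitment(truth,
                              reference_coverage = c(SAG = 0.9, MAG = 0.6),
                              n_samples = 8, n_reads = 2000, seed = 4)
  res <- compare_recruitment(gap, thresholds = 0.9)
  fr2 <- recruitment_fraction(gap, 0.9)
  expect_lt(res$p_value, 0.05)
  expect_gt(mean(fr2$fraction[fr2$reference_set == "SAG"]),
            mean(fr2$fraction[fr2$reference_set == "MAG"]))
})
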