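test_that("module completeness and presence use the inclusive 75% rule", {
  mod <- c("K1", "K2", "K3", "K4")
  expect_equal(module_completeness(c("K1", "K2", "K3"), mod), 0.75)
  expect_equal(module_completeness(character(0), mod), 0)
  expect_equal(module_completeness(c(mod, "K9"), mod), 1)
  expect_true(call_presence(0.75))
  expect_false(call_presence(0.749))
  expect_true(call_presence(1.0))
  expect_error(module_completeness("K1", character(0)), "empty")
})

test_that("module retention follows the reference-or-prevalence rule", {
  genomes <- sprintf("g%02d", 1:40)
  coll <- setNames(rep(c("SAG", "MAG"), 20), genomes)
  pres <- matrix(FALSE, 40, 3,
                 dimnames = list(genomes, c("M1", "M2", "M3")))
  pres[1, "M2"] <- TRUE              # 1/40 = 2.5% < 5%
  pres[1:2, "M3"] <- TRUE            # 2/40 = 5% exactly (inclusive)
  refs <- c(M1 = TRUE, M2 = FALSE, M3 = FALSE)
  expect_setequal(retain_modules(pres, refs, coll), c("M1", "M3"))
  # per-collection variant requires the threshold in both collections
  pres2 <- pres
  pres2[c(1, 3), "M2"] <- TRUE       # two SAGs, zero MAGs
  expect_false("M2" %in% retain_modules(pres2, refs, coll, pooled = FALSE))
})

test_that("overlap merging respects the boundary and the closure", {
  defs <- list(A = c("k1", "k2", "k3"), B = c("k1", "k2", "k4"))
  # overlap 2/3 = 0.667 >= 0.65 -> one category
  merged <- merge_overlapping(defs, 0.65)
  expect_identical(length(merged$categories), 1L)
  expect_setequal(merged$categories[[1]]$ko_union,
                  c("k1", "k2", "k3", "k4"))
  # representative: largest KO set, lexicographic tie-break
  expect_identical(names(merged$categories), "A")

  disjoint <- merge_overlapping(list(A = c("k1"), B = c("k2")), 0.65)
  expect_identical(length(disjoint$categories), 2L)

  # chain A-B, B-C with A-C below the cutoff still forms one category
  chain <- list(A = c("k1", "k2", "k3"),
                B = c("k2", "k3", "k4"),
                C = c("k3", "k4", "k5"))
  got <- merge_overlapping(chain, 0.65)
  expect_identical(length(got$categories), 1L)
})

test_that("merging agrees with an independent transitive closure", {
  set.seed(123)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    defs <- lapply(seq_len(n), function(i)
      sort(sample(sprintf("k%02d", 1:12), sample(2:6, 1))))
    names(defs) <- sprintf("M%02d", seq_len(n))
    thr <- runif(1, 0.3, 0.9)
    got <- merge_overlapping(defs, thr)
    pairs <- combn(names(defs), 2, simplify = FALSE)
    edges <- Filter(function(e) {
      a <- defs[[e[1]]]; b <- defs[[e[2]]]
      length(intersect(a, b)) / min(length(a), length(b)) >= thr
    }, pairs)
    want <- closure_components(names(defs), edges)
    got_parts <- lapply(got$categories, `[[`, "member_modules")
    norm <- function(parts)
      unname(sort(vapply(parts, paste, "", collapse = "|")))
    expect_identical(norm(got_parts), norm(lapply(want, sort)))
  }
})

test_that("merging is idempotent and monotone in the threshold", {
  set.seed(321)
  defs <- lapply(1:8, function(i) sample(sprintf("k%02d", 1:15),
                                         sample(3:7, 1)))
  names(defs) <- sprintf("M%02d", 1:8)
  m1 <- merge_overlapping(defs, 0.6)
  again <- merge_overlapping(lapply(m1$categories, `[[`, "ko_union"), 0.6)
  expect_identical(length(again$categories), length(m1$categories))
  n_prev <- 0L
  for (thr in c(0.3, 0.5, 0.7, 0.9)) {
    n_now <- length(merge_overlapping(defs, thr)$categories)
    expect_gte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("standardized counts divide by the isolate median once per
           gene", {
  cats <- merge_overlapping(list(M1 = c("k1", "k2"), M2 = c("k2", "k3")),
                            overlap_threshold = 0.5)
  expect_identical(length(cats$categories), 1L)   # nested overlap merges
  ann <- data.frame(
    genome_id = c("s1", "s1", "s1", "s2"),
    gene_id = c("s1:a", "s1:b", "s1:b", "s2:a"),
    ko_id = c("k1", "k2", "k3", "k1"), stringsAsFactors = FALSE)
  # gene s1:b carries KOs claimed by both member modules: counted once
  iso <- data.frame(genome_id = c("i1", "i2"),
                    gene_id = c("i1:a", "i2:a"),
                    ko_id = c("k1", "k2"), stringsAsFactors = FALSE)
  std <- standardized_counts(ann, cats, iso)
  expect_equal(std$raw_gene_count[std$genome_id == "s1"], 2)
  expect_equal(std$isolate_median[1], 1)
  expect_equal(std$standardized_count[std$genome_id == "s1"], 2)

  # isolates standardized against themselves have median 1
  std_iso <- standardized_counts(iso, cats, iso)
  expect_equal(median(std_iso$standardized_count), 1)
})

test_that("zero isolate medians fall back to the compared genomes", {
  cats <- merge_overlapping(list(M1 = c("k1"), M9 = c("k9")), 0.65)
  ann <- data.frame(genome_id = c("s1", "s2", "s3"),
                    gene_id = c("s1:a", "s2:a", "s3:a"),
                    ko_id = c("k1", "k1", "k1"), stringsAsFactors = FALSE)
  iso <- data.frame(genome_id = "i1", gene_id = "i1:z", ko_id = "kZZ",
                    stringsAsFactors = FALSE)
  expect_message(std <- standardized_counts(ann, cats, iso), "zero median")
  # M1: isolate median 0 -> fallback median over s1..s3 = 1
  expect_true(all(std$isolate_median[std$category_id == "M1"] == 1))
  # M9: nobody has it anywhere -> dropped
  expect_false("M9" %in% std$category_id)
})

test_that("category comparison flags a planted depletion with the
           right sign", {
  set.seed(55)
  n <- 200
  coll <- setNames(rep(c("SAG", "MAG"), each = n),
                   c(sprintf("s%03d", 1:n), sprintf("m%03d", 1:n)))
  counts <- data.frame(
    genome_id = names(coll),
    category_id = "Mx",
    raw_gene_count = 0L,
    standardized_count = c(rnorm(n, 2.0, 0.5), rnorm(n, 0.5, 0.5)),
    isolate_median = 1, stringsAsFactors = FALSE)
  res <- compare_categories(counts, coll)
  expect_true(res$significant)
  expect_identical(res$enriched_in, "SAG")
  expect_gt(res$estimated_difference, 0)

  # null: identical distributions are not flagged
  set.seed(56)
  counts$standardized_count <- c(rnorm(n, 1, .3), rnorm(n, 1, .3))
  expect_false(compare_categories(counts, coll)$significant)

  # k = 2 Games-Howell p equals the Welch t-test p
  welch <- t.test(counts$standardized_count[1:n],
                  counts$standardized_count[(n + 1):(2 * n)])
  expect_equal(compare_categories(counts, coll)$p_value, welch$p.value,
               tolerance = 1e-9)
})

test_that("zero-variance categories are excluded and reported", {
  coll <- c(a = "SAG", b = "SAG", c = "MAG", d = "MAG")
  counts <- data.frame(genome_id = rep(names(coll), 2),
                       category_id = rep(c("M1", "M2"), each = 4),
                       raw_gene_count = 1L,
                       standardized_count = c(1, 1, 1, 1, 1, 2, 3, 4),
                       isolate_median = 1, stringsAsFactors = FALSE)
  res <- compare_categories(counts, coll)
  expect_identical(res$category_id, "M2")
  expect_identical(attr(res, "excluded"), "M1")
})

test_that("a planted MAG depletion survives the whole module pipeline", {
  genomes <- rbind(
    make_genomes(30, collection = "SAG"),
    within(make_genomes(30, collection = "MAG"),
           genome_id <- sprintf("h%03d", 1:30)),
    within(make_genomes(10, collection = "ISOLATE"),
           genome_id <- sprintf("i%03d", 1:10)))
  cat0 <- simulate_gene_catalog(genomes, n_core = 18, n_flexible = 18,
                                base_dropout = 0.05,
                                sag_flexible_dropout = 0.1,
                                mag_flexible_dropout = 0.6,
                                mutation_rate = 0, gene_length = 60,
                                module_size = 6, seed = 99,
                                emit_sequences = FALSE)
  coll <- setNames(genomes$collection, genomes$genome_id)
  iso <- genomes$genome_id[coll == "ISOLATE"]
  ann <- cat0$annotations
  sm_ann <- ann[!ann$genome_id %in% iso, ]
  iso_ann <- ann[ann$genome_id %in% iso, ]
  pres <- presence_matrix(sm_ann, cat0$modules)
  ref <- apply(presence_matrix(iso_ann, cat0$modules, genomes = iso), 2,
               any)
  kept <- retain_modules(pres, ref, coll)
  cats <- merge_overlapping(module_definitions(cat0$modules)[kept])
  std <- standardized_counts(sm_ann, cats, iso_ann, isolate_genomes = iso)
  res <- compare_categories(std, coll)
  flexible_mods <- unique(cat0$truth$module_id[cat0$truth$flexible])
  hit <- res[res$category_id %in% flexible_mods, ]
  expect_true(any(hit$significant))
  expect_true(all(hit$enriched_in[hit$significant] == "SAG"))
})
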