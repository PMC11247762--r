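# Per-method taxonomic composition profiles and the compositional
# differential-abundance procedure: prevalence filter -> Dirichlet Monte
# Carlo -> CLR -> Games-Howell across methods -> dual cutoff.

DEFAULT_EXCLUDED_LINEAGES <- c("chloroplast", "mitochondria", "eukaryote",
                               "unclassified")

# counts table restricted to one rank, as lineage x sample matrix plus the
# method of each sample column. Samples are all distinct (method, sample_id)
# pairs at that rank; lineages missing from a sample count 0.
.count_matrix <- function(table, rank, lineages = NULL) {
  tab <- table[table$rank == rank, , drop = FALSE]
  if (!nrow(tab)) stop("no rows at rank '", rank, "'", call. = FALSE)
  if (is.null(lineages)) lineages <- sort(unique(tab$lineage))
  tab <- tab[tab$lineage %in% lineages, , drop = FALSE]
  samp_key <- unique(data.frame(method = tab$method, sample_id = tab$sample_id,
                                stringsAsFactors = FALSE))
  samp_key <- samp_key[order(samp_key$method, samp_key$sample_id), ]
  sid <- paste(samp_key$method, samp_key$sample_id, sep = "\r")
  mat <- matrix(0L, nrow = length(lineages), ncol = nrow(samp_key),
                dimnames = list(lineages, paste(samp_key$method,
                                                samp_key$sample_id)))
  ix <- cbind(match(tab$lineage, lineages),
              match(paste(tab$method, tab$sample_id, sep = "\r"), sid))
  mat[ix] <- tab$count
  list(counts = mat, method = samp_key$method, sample_id = samp_key$sample_id)
}

#' Per-method taxonomic composition profile
#'
#' For each observation method, the profile is the unweighted mean across
#' that method's samples of the per-sample lineage proportions. Lineages in
#' `exclude_lineages` (organelle, eukaryotic and unclassified signal by
#' default) are removed before proportions are computed.
#'
#' @param table a `counts` table (see [read_table()]).
#' @param rank taxonomic rank to profile.
#' @param exclude_lineages lineage labels dropped before normalization.
#' @return a data.frame of class `"composition_profile"` with columns
#'   `method`, `rank`, `lineage`, `mean_proportion`, `n_samples`; within
#'   each method the proportions sum to 1.
#' @export
build_profile <- function(table, rank,
                          exclude_lineages = DEFAULT_EXCLUDED_LINEAGES) {
  table <- validate_table(table, "counts")
  tab <- table[table$rank == rank & !table$lineage %in% exclude_lineages, ,
               drop = FALSE]
  if (!nrow(tab)) stop("no rows at rank '", rank, "'", call. = FALSE)
  cm <- .count_matrix(tab, rank)
  totals <- colSums(cm$counts)
  if (any(totals == 0))
    stop("zero total count after exclusions in sample(s): ",
         paste(colnames(cm$counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  props <- sweep(cm$counts, 2L, totals, "/")
  out <- do.call(rbind, lapply(unique(cm$method), function(m) {
    cols <- cm$method == m
    data.frame(method = m, rank = rank, lineage = rownames(props),
               mean_proportion = rowMeans(props[, cols, drop = FALSE]),
               n_samples = sum(cols), stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  class(out) <- c("composition_profile", "data.frame")
  out
}

#' Lump rare lineages into an "Others" bucket
#'
#' A lineage is lumped when its mean proportion is below `min_fraction` in
#' every reference method (i.e. kept when it reaches the cutoff in at
#' least one of them); the community survey methods (amplicon and shotgun)
#' are the natural references. Per-method totals are preserved exactly.
#'
#' @param profile a [build_profile()] result.
#' @param reference_methods methods whose proportions decide lumping.
#' @param min_fraction minimum mean proportion to escape lumping (e.g.
#'   0.02 at genus rank, 0.03 at phylum rank).
#' @return a `composition_profile` with rare lineages merged into
#'   `"Others"`.
#' @export
lump_rare <- function(profile, reference_methods = c("AMPLICON", "SHOTGUN"),
                      min_fraction = 0.02) {
  stopifnot(all(reference_methods %in% profile$method))
  ref <- profile[profile$method %in% reference_methods, , drop = FALSE]
  keep_max <- tapply(ref$mean_proportion, ref$lineage, max)
  kept <- names(keep_max)[keep_max >= min_fraction]
  lump <- !profile$lineage %in% kept
  profile$lineage[lump] <- "Others"
  out <- do.call(rbind, lapply(split(profile, profile[c("method", "lineage")],
                                     drop = TRUE), function(g) {
    g$mean_proportion[1L] <- sum(g$mean_proportion)
    g[1L, , drop = FALSE]
  }))
  out <- out[order(out$method, out$lineage != "Others", -out$mean_proportion), ]
  rownames(out) <- NULL
  class(out) <- c("composition_profile", "data.frame")
  out
}

#' Cross-method prevalence filter
#'
#' Keeps the lineages observed (count > 0) in strictly more than
#' `min_prevalence` of the samples of every observation method separately.
#' This is the noise filter applied before differential-abundance testing,
#' restricting attention to lineages consistently recovered by all four
#' methods.
#'
#' @inheritParams build_profile
#' @param min_prevalence fraction of samples (strict inequality; default
#'   0.9, i.e. "found in > 90% of samples").
#' @return character vector of retained lineage labels.
#' @export
prevalence_filter <- function(table, rank, min_prevalence = 0.9) {
  table <- validate_table(table, "counts")
  cm <- .count_matrix(table, rank)
  methods <- unique(cm$method)
  keep <- rownames(cm$counts)
  for (m in methods) {
    cols <- cm$method == m
    if (!any(cols)) stop("method with zero samples: ", m, call. = FALSE)
    prev <- rowMeans(cm$counts[, cols, drop = FALSE] > 0)
    keep <- keep[prev[keep] > min_prevalence]
  }
  keep
}

# Vectorized Games-Howell across methods for every (lineage, MC instance)
# cell at once. `a` is an L x n_mc x S array of CLR values; returns, per
# unordered method pair, L x n_mc matrices of differences and p-values.
.gh_cellwise <- function(a, method) {
  methods <- sort(unique(method))
  k <- length(methods)
  dims <- dim(a)
  stat <- lapply(methods, function(m) {
    ix <- which(method == m)
    ns <- length(ix)
    sub <- a[, , ix, drop = FALSE]
    mu <- rowSums(sub, dims = 2L) / ns
    ss <- rowSums(sub^2, dims = 2L)
    v <- (ss - ns * mu^2) / (ns - 1L)
    list(mu = mu, vn = pmax(v, 0) / ns, n = ns)
  })
  names(stat) <- methods
  pairs <- combn(methods, 2L)
  out <- vector("list", ncol(pairs))
  for (ix in seq_len(ncol(pairs))) {
    sa <- stat[[pairs[1L, ix]]]; sb <- stat[[pairs[2L, ix]]]
    se2 <- sa$vn + sb$vn
    if (any(se2 == 0)) {
      bad <- which(se2 == 0, arr.ind = TRUE)
      stop("zero-variance cell for lineage '",
           rownames(se2)[bad[1L, 1L]] %||% bad[1L, 1L], "' in pair ",
           pairs[1L, ix], "-", pairs[2L, ix], call. = FALSE)
    }
    d <- sa$mu - sb$mu
    df <- se2^2 / (sa$vn^2 / (sa$n - 1L) + sb$vn^2 / (sb$n - 1L))
    p_flat <- studentized_range_sf(abs(as.vector(d / sqrt(se2))) * sqrt(2),
                                   k, as.vector(df))
    p <- array(p_flat, dim = dim(d), dimnames = dimnames(d))
    out[[ix]] <- list(method_a = pairs[1L, ix], method_b = pairs[2L, ix],
                      d = d, p = p)
  }
  out
}

#' Compositional differential abundance across observation methods
#'
#' For each sample, `n_mc` Dirichlet Monte-Carlo instances are drawn over
#' the (already prevalence-filtered) lineages; each instance is CLR
#' transformed; for each Monte-Carlo index a Games-Howell test is run
#' across methods on the per-sample CLR values of each lineage; and the
#' per-instance estimated differences and p-values are then aggregated
#' over instances (arithmetic mean by default -- the "expected" values).
#' A lineage/pair is flagged significant by the dual cutoff
#' `|expected_difference| > diff_cutoff` and `expected_p < p_cutoff`
#' (defaults 2 and 1e-3). Estimated differences are reported in base-2
#' CLR units -- the convention of the Dirichlet-CLR differential
#' abundance procedure the dual cutoff comes from -- so a difference of
#' 2 is roughly a four-fold shift.
#'
#' @inheritParams build_profile
#' @param n_mc Dirichlet Monte-Carlo instances per sample (default 1000).
#' @param prior_mass Dirichlet prior mass per cell (default 0.5).
#' @param diff_cutoff,p_cutoff dual significance cutoffs (strict
#'   inequalities).
#' @param seed integer seed for the Monte-Carlo draws.
#' @param lineages lineages to test; default
#'   `prevalence_filter(table, rank)`.
#' @param aggregate `"mean"` (default) or `"median"` over MC instances.
#' @param mc_mode `"test_then_average"` (default: per-instance tests,
#'   aggregated after) or `"average_then_test"` (CLR values averaged over
#'   instances first, one test).
#' @return a data.frame of class `"diff_abundance"`: `lineage`,
#'   `method_a`, `method_b`, `expected_difference`, `expected_p`,
#'   `significant`.
#' @export
differential_abundance <- function(table, rank, n_mc = 1000,
                                   prior_mass = 0.5, diff_cutoff = 2,
                                   p_cutoff = 1e-3, seed = 1L,
                                   lineages = NULL,
                                   aggregate = c("mean", "median"),
                                   mc_mode = c("test_then_average",
                                               "average_then_test")) {
  aggregate <- match.arg(aggregate)
  mc_mode <- match.arg(mc_mode)
  table <- validate_table(table, "counts")
  if (is.null(lineages)) lineages <- prevalence_filter(table, rank)
  if (length(lineages) < 2L)
    stop("need >= 2 lineages after filtering", call. = FALSE)
  cm <- .count_matrix(table, rank, lineages = lineages)
  n_per <- table(cm$method)
  if (any(n_per < 2L))
    stop("need >= 2 samples per method", call. = FALSE)
  L <- nrow(cm$counts); S <- ncol(cm$counts)
  a <- array(NA_real_, dim = c(L, as.integer(n_mc), S),
             dimnames = list(rownames(cm$counts), NULL, NULL))
  for (s in seq_len(S)) {
    inst <- dirichlet_mc_instances(cm$counts[, s], n_mc = n_mc,
                                   prior_mass = prior_mass,
                                   seed = derive_seed(seed, s))
    a[, , s] <- clr_transform(unclass(inst)) / log(2)   # base-2 CLR units
  }
  if (mc_mode == "average_then_test") {
    a <- array(rowMeans(a, dims = 2L), dim = c(L, 1L, S),
               dimnames = list(rownames(cm$counts), NULL, NULL))
  }
  cells <- .gh_cellwise(a, cm$method)
  agg <- if (aggregate == "mean") rowMeans else
    function(m) apply(m, 1L, median)
  out <- do.call(rbind, lapply(cells, function(cell) {
    data.frame(lineage = rownames(cm$counts),
               method_a = cell$method_a, method_b = cell$method_b,
               expected_difference = agg(cell$d),
               expected_p = agg(cell$p),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out$significant <- abs(out$expected_difference) > diff_cutoff &
    out$expected_p < p_cutoff
  attr(out, "n_mc") <- as.integer(n_mc)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "cutoffs") <- c(diff = diff_cutoff, p = p_cutoff)
  class(out) <- c("diff_abundance", "data.frame")
  out
}

#' @param x a `diff_abundance` result.
#' @param ... ignored.
#' @rdname differential_abundance
#' @export
print.diff_abundance <- function(x, ...) {
  co <- attr(x, "cutoffs")
  cat("Differential abundance (Dirichlet MC + CLR + Games-Howell), n_mc = ",
      attr(x, "n_mc"), "\n", "significance: |difference| > ", co[["diff"]],
      " and p < ", format(co[["p"]]), "; ", sum(x$significant), " of ",
      nrow(x), " lineage/pair tests flagged\n\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
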