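# Richness and pangenome accumulation: rank-wise unique/shared taxon
# counts, Venn counts of clusters by collection, and rarefaction curves
# with a closed-form (hypergeometric) twin.

#' Unique and shared taxa at a rank
#'
#' Set comparison of the distinct, assigned (non-empty) taxon labels of
#' two genome collections at one taxonomic rank. The three counts
#' disjointly partition the union of labels.
#'
#' @param sag_taxa,mag_taxa taxonomies of the two collections: a `genomes`
#'   table, a character vector of GTDB-style strings, or a parsed
#'   taxonomy matrix.
#' @param rank one of the seven ranks.
#' @return named integer vector `c(shared, sag_only, mag_only)`.
#' @export
richness_by_rank <- function(sag_taxa, mag_taxa, rank) {
  s <- unique(taxonomy_labels(sag_taxa, rank))
  m <- unique(taxonomy_labels(mag_taxa, rank))
  s <- s[nzchar(s)]; m <- m[nzchar(m)]
  c(shared = length(intersect(s, m)),
    sag_only = length(setdiff(s, m)),
    mag_only = length(setdiff(m, s)))
}

# member -> genome -> collection lookup, with validation
.member_collections <- function(assignment, collection_of, genome_of = NULL) {
  g <- if (is.null(genome_of)) assignment$member_id
       else unname(genome_of[assignment$member_id])
  if (anyNA(g) || any(!nzchar(g)))
    stop("member(s) without a genome mapping", call. = FALSE)
  cl <- unname(collection_of[g])
  if (anyNA(cl))
    stop("genome(s) without a collection label: ",
         paste(unique(g[is.na(cl)]), collapse = ", "), call. = FALSE)
  cl
}

#' Shared and exclusive clusters between collections
#'
#' A cluster is "shared" when it contains members from both the SAG and
#' the MAG collection, otherwise it is exclusive to the collection of its
#' members. The three counts partition all clusters; the result is
#' invariant to cluster relabeling.
#'
#' @param assignment a `clusters` table.
#' @param collection_of named character vector, genome id -> collection
#'   (`"SAG"`/`"MAG"`), or a `genomes` table.
#' @param genome_of optional named character vector, member id ->
#'   genome id (defaults to members being genomes themselves).
#' @return named integer vector `c(shared, sag_exclusive, mag_exclusive)`.
#' @export
venn_counts <- function(assignment, collection_of, genome_of = NULL) {
  assignment <- validate_table(assignment, "clusters")
  if (is.data.frame(collection_of))
    collection_of <- setNames(collection_of$collection,
                              collection_of$genome_id)
  cl <- .member_collections(assignment, collection_of, genome_of)
  has_sag <- tapply(cl == "SAG", assignment$cluster_id, any)
  has_mag <- tapply(cl == "MAG", assignment$cluster_id, any)
  c(shared = sum(has_sag & has_mag),
    sag_exclusive = sum(has_sag & !has_mag),
    mag_exclusive = sum(!has_sag & has_mag))
}

#' Cluster-by-genome incidence matrix
#'
#' Presence flags of clusters (rows) across genomes (columns), the input
#' of the rarefaction estimators. A genome's multiple members in one
#' cluster count once: accumulation is over distinct clusters.
#'
#' @inheritParams venn_counts
#' @return logical matrix with a `collection` attribute (named per
#'   genome).
#' @export
incidence_matrix <- function(assignment, collection_of, genome_of = NULL) {
  assignment <- validate_table(assignment, "clusters")
  if (is.data.frame(collection_of))
    collection_of <- setNames(collection_of$collection,
                              collection_of$genome_id)
  g <- if (is.null(genome_of)) assignment$member_id
       else unname(genome_of[assignment$member_id])
  genomes <- sort(unique(g))
  clusters <- sort(unique(assignment$cluster_id))
  inc <- matrix(FALSE, length(clusters), length(genomes),
                dimnames = list(clusters, genomes))
  inc[cbind(match(assignment$cluster_id, clusters), match(g, genomes))] <- TRUE
  attr(inc, "collection") <- collection_of[genomes]
  inc
}

.subset_incidence <- function(inc, subset) {
  if (!identical(subset, "all")) {
    coll <- attr(inc, "collection")
    keep <- which(coll == subset)
    if (!length(keep)) stop("empty subset '", subset, "'", call. = FALSE)
    inc <- inc[, keep, drop = FALSE]
  }
  inc[rowSums(inc) > 0L, , drop = FALSE]
}

#' Rarefaction (accumulation) curves of cluster richness
#'
#' `accumulation_curve_perm()` estimates the expected number of distinct
#' clusters recovered by the first g genomes of a random genome ordering,
#' by averaging over `n_perm` random permutations (the classical
#' permutation rarefaction). `accumulation_curve_exact()` computes the
#' same expectation in closed form: a cluster present in `n_c` of the `N`
#' genomes is missed by a random subset of g genomes with probability
#' `choose(N - n_c, g) / choose(N, g)`, so
#' `E[richness(g)] = sum_c (1 - choose(N - n_c, g) / choose(N, g))`
#' (evaluated via log-gamma, relative error below 1e-10).
#'
#' @param inc an [incidence_matrix()].
#' @param subset `"all"` or a collection label; restricts the genome pool
#'   (clusters absent from the pool are dropped).
#' @param n_perm number of random permutations (default 1000).
#' @param seed integer seed.
#' @return `accumulation_curve_perm()`: a data.frame of class
#'   `"accumulation_curve"` with `depth`, `mean_richness`, `sd_richness`
#'   (n-1 denominator). `accumulation_curve_exact()`: a data.frame with
#'   `depth` and `expected_richness`.
#' @export
accumulation_curve_perm <- function(inc, subset = "all", n_perm = 1000,
                                    seed = 1L) {
  inc <- .subset_incidence(inc, subset)
  N <- ncol(inc)
  members <- apply(inc, 1L, which, simplify = FALSE)
  rich <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      pos <- sample.int(N)           # pos[g] = permutation position of genome g
      first <- vapply(members, function(ix) min(pos[ix]), 0L)
      cumsum(tabulate(first, nbins = N))
    }, numeric(N))
  })
  rich <- matrix(rich, nrow = N)     # depth x n_perm
  out <- data.frame(depth = seq_len(N),
                    mean_richness = rowMeans(rich),
                    sd_richness = apply(rich, 1L, sd))
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "subset") <- subset
  class(out) <- c("accumulation_curve", "data.frame")
  out
}

#' @rdname accumulation_curve_perm
#' @export
accumulation_curve_exact <- function(inc, subset = "all") {
  inc <- .subset_incidence(inc, subset)
  N <- ncol(inc)
  n_c <- rowSums(inc)
  expected <- vapply(seq_len(N), function(g) {
    miss <- ifelse(N - n_c >= g,
                   exp(lchoose(N - n_c, g) - lchoose(N, g)), 0)
    sum(1 - miss)
  }, 0)
  data.frame(depth = seq_len(N), expected_richness = expected)
}

#' @param x an `accumulation_curve`.
#' @param ... passed to [graphics::plot.default()].
#' @rdname accumulation_curve_perm
#' @method plot accumulation_curve
#' @export
plot.accumulation_curve <- function(x, ...) {
  graphics::plot(x$depth, x$mean_richness, type = "l",
                 xlab = "genomes sampled",
                 ylab = "distinct clusters (mean over permutations)", ...)
  se <- x$sd_richness
  graphics::lines(x$depth, x$mean_richness + se, lty = 3)
  graphics::lines(x$depth, pmax(x$mean_richness - se, 0), lty = 3)
  invisible(x)
}

#' @rdname accumulation_curve_perm
#' @export
print.accumulation_curve <- function(x, ...) {
  cat("Accumulation curve (", attr(x, "subset"), "), ", nrow(x),
      " depths, ", attr(x, "n_perm"), " permutations\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10L), digits = 4,
                   row.names = FALSE)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more depths)\n", sep = "")
  invisible(x)
}
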