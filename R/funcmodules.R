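# KEGG-module gene-content comparison, in six steps: module completeness
# -> genome-level presence -> retention against references and prevalence
# -> overlap merging of redundant modules -> median standardization
# against isolates -> per-category Games-Howell.

#' Module definitions from a modules table
#'
#' @param modules a `modules` table (`module_id`, `ko_id`, one row per
#'   pair) or a named list of KO identifier vectors.
#' @return named list of unique KO sets, one per module.
#' @export
module_definitions <- function(modules) {
  if (is.data.frame(modules)) {
    modules <- validate_table(modules, "modules")
    defs <- lapply(split(modules$ko_id, modules$module_id), unique)
  } else defs <- lapply(modules, unique)
  if (any(!lengths(defs))) stop("empty ko_set", call. = FALSE)
  defs
}

#' KO-fraction completeness of a module in a genome
#'
#' The fraction of a module's KOs present in the genome's annotation:
#' `|ko_set intersect genome_kos| / |ko_set|`.
#'
#' @param genome_kos character vector of KO identifiers found in the
#'   genome.
#' @param ko_set the module's KO set.
#' @return real in `[0,1]`.
#' @export
module_completeness <- function(genome_kos, ko_set) {
  ko_set <- unique(ko_set)
  if (!length(ko_set)) stop("empty ko_set", call. = FALSE)
  sum(ko_set %in% genome_kos) / length(ko_set)
}

#' Genome-level module presence call
#'
#' A module is called present when its completeness reaches the threshold
#' (inclusive: "at least 75% of the affiliated KOs").
#'
#' @param completeness real in `[0,1]`.
#' @param threshold presence threshold (default 0.75).
#' @return logical.
#' @export
call_presence <- function(completeness, threshold = 0.75) {
  stopifnot(all(completeness >= 0 & completeness <= 1))
  completeness >= threshold
}

#' Genome-by-module presence matrix
#'
#' @param annotations an `annotations` table (`genome_id`, `gene_id`,
#'   `ko_id`).
#' @param modules module definitions ([module_definitions()] input).
#' @param threshold presence threshold passed to [call_presence()].
#' @param genomes optional character vector fixing the genome universe
#'   (genomes without annotations get all-absent rows).
#' @return logical matrix genomes x modules.
#' @export
presence_matrix <- function(annotations, modules, threshold = 0.75,
                            genomes = NULL) {
  annotations <- validate_table(annotations, "annotations")
  defs <- module_definitions(modules)
  kos_by_genome <- lapply(split(annotations$ko_id, annotations$genome_id),
                          unique)
  if (is.null(genomes)) genomes <- sort(names(kos_by_genome))
  pres <- matrix(FALSE, length(genomes), length(defs),
                 dimnames = list(genomes, names(defs)))
  for (g in genomes) {
    kos <- kos_by_genome[[g]] %||% character(0)
    comp <- vapply(defs, function(ks) module_completeness(kos, ks), 0)
    pres[g, ] <- call_presence(comp, threshold)
  }
  pres
}

#' Retain modules supported by references or prevalence
#'
#' A module is retained when it is present in at least one fully
#' annotated reference (KEGG) genome, or called present in at least
#' `min_prevalence` (inclusive) of the compared SAG and MAG genomes --
#' pooled by default, or required of each collection separately with
#' `pooled = FALSE`.
#'
#' @param presence logical genome x module matrix ([presence_matrix()]).
#' @param kegg_reference_presence named logical vector per module
#'   (presence in any reference genome).
#' @param collections named character vector genome -> collection; only
#'   `SAG`/`MAG` genomes enter the prevalence.
#' @param min_prevalence prevalence threshold (default 0.05).
#' @param pooled pool SAGs and MAGs (default) or require the threshold in
#'   each collection.
#' @return character vector of retained module ids.
#' @export
retain_modules <- function(presence, kegg_reference_presence, collections,
                           min_prevalence = 0.05, pooled = TRUE) {
  mods <- colnames(presence)
  stopifnot(all(mods %in% names(kegg_reference_presence)))
  cl <- collections[rownames(presence)]
  pool <- rownames(presence)[cl %in% c("SAG", "MAG")]
  if (!length(pool)) stop("no SAG/MAG genomes in presence matrix",
                          call. = FALSE)
  prev_ok <- if (pooled) {
    colMeans(presence[pool, , drop = FALSE]) >= min_prevalence
  } else {
    sag <- pool[cl[pool] == "SAG"]; mag <- pool[cl[pool] == "MAG"]
    colMeans(presence[sag, , drop = FALSE]) >= min_prevalence &
      colMeans(presence[mag, , drop = FALSE]) >= min_prevalence
  }
  mods[kegg_reference_presence[mods] | prev_ok]
}

#' Merge modules with largely overlapping KO sets
#'
#' Two modules overlap by `|A intersect B| / min(|A|, |B|)` (so a module
#' nested in another counts as full overlap, which is what guards
#' against double-counting genes); modules joined by overlap at or above
#' the threshold -- transitively, via connected components of the overlap
#' graph -- are combined into one representative category. The
#' representative is the member with the largest KO set (ties:
#' lexicographically smallest module id) and the category's KO set is
#' the union over members.
#'
#' @param modules module definitions.
#' @param overlap_threshold minimum overlap (default 0.65).
#' @param overlap_fun `"min"` (default) or `"jaccard"`.
#' @return a list of class `"merged_categories"`: `categories` (named
#'   list with `member_modules` and `ko_union`) and `map` (data.frame
#'   module_id -> category_id).
#' @export
merge_overlapping <- function(modules, overlap_threshold = 0.65,
                              overlap_fun = c("min", "jaccard")) {
  overlap_fun <- match.arg(overlap_fun)
  defs <- module_definitions(modules)
  ids <- names(defs)
  n <- length(ids)
  edges <- NULL
  if (n > 1L) {
    pr <- combn(n, 2L)
    ov <- vapply(seq_len(ncol(pr)), function(ix) {
      a <- defs[[pr[1L, ix]]]; b <- defs[[pr[2L, ix]]]
      inter <- length(intersect(a, b))
      den <- if (overlap_fun == "min") min(length(a), length(b)) else
        length(union(a, b))
      inter / den
    }, 0)
    edges <- pr[, ov >= overlap_threshold, drop = FALSE]
  }
  ed <- if (is.null(edges) || !ncol(edges))
    data.frame(from = character(0), to = character(0))
  else data.frame(from = ids[edges[1L, ]], to = ids[edges[2L, ]])
  g <- igraph::graph_from_data_frame(d = ed, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  cats <- lapply(split(ids, comp), function(members) {
    sizes <- lengths(defs[members])
    rep_id <- sort(members[sizes == max(sizes)])[1L]
    list(category_id = rep_id, member_modules = sort(members),
         ko_union = sort(unique(unlist(defs[members], use.names = FALSE))))
  })
  names(cats) <- vapply(cats, `[[`, "", "category_id")
  cats <- cats[order(names(cats))]
  map <- data.frame(
    module_id = unlist(lapply(cats, `[[`, "member_modules"),
                       use.names = FALSE),
    category_id = rep(names(cats),
                      vapply(cats, function(x) length(x$member_modules), 0L)),
    stringsAsFactors = FALSE)
  structure(list(categories = cats, map = map),
            class = "merged_categories")
}

#' @param x a `merged_categories` object.
#' @param ... ignored.
#' @rdname merge_overlapping
#' @export
print.merged_categories <- function(x, ...) {
  cat(length(x$categories), "categories from", nrow(x$map), "modules\n")
  for (cat_id in names(x$categories)) {
    c0 <- x$categories[[cat_id]]
    cat("  ", cat_id, ": ", length(c0$member_modules), " module(s), ",
        length(c0$ko_union), " KOs\n", sep = "")
  }
  invisible(x)
}

# distinct genes of one genome hitting any KO of the category union
.category_counts <- function(annotations, categories, genomes) {
  counts <- matrix(0L, length(genomes), length(categories$categories),
                   dimnames = list(genomes, names(categories$categories)))
  ann <- split(annotations[c("gene_id", "ko_id")], annotations$genome_id)
  for (g in intersect(genomes, names(ann))) {
    a <- ann[[g]]
    for (cat_id in names(categories$categories)) {
      hit <- a$ko_id %in% categories$categories[[cat_id]]$ko_union
      counts[g, cat_id] <- length(unique(a$gene_id[hit]))
    }
  }
  counts
}

#' Isolate-standardized per-category gene counts
#'
#' For each genome and merged category, the raw count is the number of
#' distinct genes assigned to any KO of the category (a gene claimed by
#' several member modules counts once). Raw counts are divided by the
#' median raw count over cultured-isolate genomes, which puts categories
#' with very different gene-count scales on one axis. When the isolate
#' median is 0 the median over all compared genomes is used instead; a
#' category whose fallback median is also 0 is dropped with a message.
#'
#' @param annotations `annotations` table for the compared (SAG/MAG)
#'   genomes.
#' @param categories a [merge_overlapping()] result.
#' @param isolate_annotations `annotations` table for the isolate
#'   genomes.
#' @param genomes,isolate_genomes optional character vectors fixing the
#'   genome universes (default: genomes present in each table).
#' @return a data.frame with `genome_id`, `category_id`,
#'   `raw_gene_count`, `standardized_count`, `isolate_median`.
#' @export
standardized_counts <- function(annotations, categories,
                                isolate_annotations, genomes = NULL,
                                isolate_genomes = NULL) {
  annotations <- validate_table(annotations, "annotations")
  isolate_annotations <- validate_table(isolate_annotations, "annotations")
  if (!nrow(isolate_annotations) && is.null(isolate_genomes))
    stop("no isolates supplied", call. = FALSE)
  if (is.null(genomes)) genomes <- sort(unique(annotations$genome_id))
  if (is.null(isolate_genomes))
    isolate_genomes <- sort(unique(isolate_annotations$genome_id))
  cc <- .category_counts(annotations, categories, genomes)
  ic <- .category_counts(isolate_annotations, categories, isolate_genomes)
  med <- apply(ic, 2L, median)
  fallback <- apply(cc, 2L, median)
  use_fb <- med == 0
  med[use_fb] <- fallback[use_fb]
  drop <- names(med)[med == 0]
  if (length(drop))
    message("dropping categor", if (length(drop) > 1L) "ies" else "y",
            " with zero median everywhere: ", paste(drop, collapse = ", "))
  keep <- setdiff(colnames(cc), drop)
  out <- data.frame(
    genome_id = rep(rownames(cc), times = length(keep)),
    category_id = rep(keep, each = nrow(cc)),
    raw_gene_count = as.vector(cc[, keep, drop = FALSE]),
    isolate_median = rep(unname(med[keep]), each = nrow(cc)),
    stringsAsFactors = FALSE)
  out$standardized_count <- out$raw_gene_count / out$isolate_median
  out[c("genome_id", "category_id", "raw_gene_count", "standardized_count",
        "isolate_median")]
}

#' Compare standardized category counts between SAGs and MAGs
#'
#' Per category, a two-group Games-Howell test of the standardized gene
#' counts of SAG versus MAG genomes. The sign of the estimated
#' difference (SAG minus MAG) reports which collection is enriched;
#' significance is `p < p_cutoff`. Categories with zero variance in
#' either collection are excluded and reported via the `"excluded"`
#' attribute.
#'
#' @param counts a [standardized_counts()] table.
#' @param collections named character vector genome -> collection.
#' @param p_cutoff significance cutoff (default 1e-3).
#' @param conf_level confidence level for intervals.
#' @return data.frame with one row per testable category: `category_id`,
#'   `estimated_difference`, `standard_error`, `p_value`, `ci_low`,
#'   `ci_high`, `significant`, `enriched_in`.
#' @export
compare_categories <- function(counts, collections, p_cutoff = 1e-3,
                               conf_level = 0.95) {
  cl <- collections[counts$genome_id]
  if (anyNA(cl)) stop("genome(s) without collection label", call. = FALSE)
  excluded <- character(0)
  rows <- lapply(sort(unique(counts$category_id)), function(cat_id) {
    sub <- counts[counts$category_id == cat_id, ]
    grp <- list(SAG = sub$standardized_count[cl[sub$genome_id] == "SAG"],
                MAG = sub$standardized_count[cl[sub$genome_id] == "MAG"])
    if (length(grp$SAG) < 2L || length(grp$MAG) < 2L ||
        var(grp$SAG) == 0 || var(grp$MAG) == 0) {
      excluded <<- c(excluded, cat_id)
      return(NULL)
    }
    gh <- games_howell(grp, conf_level = conf_level)
    data.frame(category_id = cat_id,
               estimated_difference = gh$estimated_difference,
               standard_error = gh$standard_error, p_value = gh$p_value,
               ci_low = gh$ci_low, ci_high = gh$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(category_id = character(0),
                                      estimated_difference = numeric(0),
                                      standard_error = numeric(0),
                                      p_value = numeric(0),
                                      ci_low = numeric(0),
                                      ci_high = numeric(0))
  out$significant <- out$p_value < p_cutoff
  out$enriched_in <- ifelse(out$estimated_difference > 0, "SAG", "MAG")
  attr(out, "excluded") <- excluded
  out
}
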