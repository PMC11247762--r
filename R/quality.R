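# Assembly-quality rules: completeness/contamination prefilters, default
# chimera calls from the clade separation score, estimator incongruence,
# the stringent consensus chimera caller, and 16S-vs-genome taxonomy
# conflict auditing.

RANKS_ABOVE <- function(rank) {
  rank <- normalize_rank(rank)
  TAX_RANKS[seq_len(match(rank, TAX_RANKS) - 1L)]
}

#' Completeness/contamination prefilter
#'
#' Retains genomes with completeness at or above `min_completeness` and
#' contamination at or below `max_contamination` (both boundaries
#' inclusive). Whitelisted genomes are retained regardless of their
#' metrics -- the escape hatch for assemblies that pass manual review
#' despite a high single-copy-gene contamination estimate.
#'
#' @param genomes a `genomes` table.
#' @param min_completeness percent (default 50).
#' @param max_contamination percent (default 10).
#' @param whitelist genome ids retained unconditionally.
#' @return the retained subset, order preserved.
#' @export
checkm_prefilter <- function(genomes, min_completeness = 50,
                             max_contamination = 10,
                             whitelist = character(0)) {
  genomes <- validate_table(genomes, "genomes")
  keep <- (genomes$completeness >= min_completeness &
             genomes$contamination <= max_contamination) |
    genomes$genome_id %in% whitelist
  genomes[keep, , drop = FALSE]
}

.gunc_by_genome <- function(gunc) {
  gunc <- validate_table(gunc, "gunc")
  split(gunc[c("rank", "css", "rrs", "contamination_portion")],
        gunc$genome_id)
}

#' Default chimera call from the clade separation score
#'
#' A genome is called chimeric when its clade separation score (CSS)
#' exceeds `css_cutoff` (strictly) at any taxonomic rank. With
#' `require_rrs` set, only ranks whose reference representation score
#' (RRS) exceeds that value are eligible -- the "well-represented
#' genomes only" restricted view.
#'
#' @param gunc a `gunc` table (per-genome, per-rank `css`, `rrs`,
#'   `contamination_portion`).
#' @param css_cutoff default 0.45 (the estimator's default).
#' @param require_rrs optional RRS eligibility cutoff (e.g. 0.5), or
#'   `NULL` for all ranks.
#' @return named logical vector, one element per genome.
#' @export
gunc_default_call <- function(gunc, css_cutoff = 0.45, require_rrs = NULL) {
  by_g <- .gunc_by_genome(gunc)
  vapply(by_g, function(ev) {
    if (!is.null(require_rrs)) ev <- ev[ev$rrs > require_rrs, , drop = FALSE]
    nrow(ev) > 0L && any(ev$css > css_cutoff)
  }, NA)
}

#' Stringent consensus chimera caller
#'
#' Calls a genome a consensus chimera only when two independent
#' estimators agree: there is a taxonomic rank strictly above
#' `min_rank_above` (family, order, class, phylum or domain by default)
#' at which CSS >= `css_min` and RRS >= `rrs_min`, and in addition the
#' second estimator's contamination fraction is at least `mdm_min`.
#' Every consensus call is also a default call at its evidence rank,
#' since `css_min` exceeds the default CSS cutoff.
#'
#' @param gunc a `gunc` table.
#' @param mdm an `mdm` table (`genome_id`, `contamination_fraction`).
#' @param rrs_min minimum reference representation score (default 0.5).
#' @param css_min minimum clade separation score (default 0.85).
#' @param min_rank_above evidence must lie strictly above this rank
#'   (default `"genus"`).
#' @param mdm_min minimum second-estimator contamination fraction
#'   (default 0.10).
#' @param css_default cutoff for the accompanying default call
#'   (default 0.45, strict).
#' @return a data.frame of class `"chimera_calls"`: `genome_id`,
#'   `default_call`, `consensus_call`, `evidence_rank` (the qualifying
#'   rank with highest CSS, or `NA`), `reasons` (per-condition
#'   pass/fail labels).
#' @export
consensus_chimera_call <- function(gunc, mdm, rrs_min = 0.5,
                                   css_min = 0.85,
                                   min_rank_above = "genus",
                                   mdm_min = 0.10, css_default = 0.45) {
  by_g <- .gunc_by_genome(gunc)
  mdm <- validate_table(mdm, "mdm")
  mdm_of <- setNames(mdm$contamination_fraction, mdm$genome_id)
  missing_mdm <- setdiff(names(by_g), names(mdm_of))
  if (length(missing_mdm))
    stop("genome(s) without an mdm contamination estimate: ",
         paste(missing_mdm, collapse = ", "), call. = FALSE)
  eligible_ranks <- RANKS_ABOVE(min_rank_above)
  rows <- lapply(names(by_g), function(g) {
    ev <- by_g[[g]]
    above <- ev[ev$rank %in% eligible_ranks, , drop = FALSE]
    qual <- above[above$css >= css_min & above$rrs >= rrs_min, ,
                  drop = FALSE]
    cond_abc <- nrow(qual) > 0L
    cond_d <- mdm_of[[g]] >= mdm_min
    consensus <- cond_abc && cond_d
    evidence_rank <- if (cond_abc) qual$rank[which.max(qual$css)] else
      NA_character_
    reasons <- paste0(
      c("rrs_min", "css_min", "above_rank", "mdm_min"), ":",
      ifelse(c(any(above$rrs >= rrs_min),
               any(above$css >= css_min),
               cond_abc, cond_d), "pass", "fail"),
      collapse = ";")
    data.frame(genome_id = g,
               default_call = any(ev$css > css_default),
               consensus_call = consensus,
               evidence_rank = evidence_rank,
               reasons = reasons, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("chimera_calls", "data.frame")
  out
}

#' @param x a `chimera_calls` table.
#' @param ... ignored.
#' @rdname consensus_chimera_call
#' @export
print.chimera_calls <- function(x, ...) {
  cat("Chimera calls for ", nrow(x), " genomes: ", sum(x$default_call),
      " default (CSS), ", sum(x$consensus_call), " consensus\n", sep = "")
  hits <- x[x$consensus_call, c("genome_id", "evidence_rank")]
  if (nrow(hits)) print.data.frame(hits, row.names = FALSE)
  invisible(x)
}

#' Incongruence between two contamination estimators
#'
#' Per genome, contrasts the clade-based contamination fraction (taken
#' at the genome's maximum-CSS rank) with the second estimator's
#' fraction, and summarizes their relation by ordinary least squares of
#' the second estimator on the first.
#'
#' @inheritParams consensus_chimera_call
#' @return a list of class `"incongruence"`: `table` (genome_id,
#'   gunc_fraction, mdm_fraction, difference), `slope`, `intercept`,
#'   `r_squared`, `p_value` (two-sided slope test).
#' @export
contamination_incongruence <- function(gunc, mdm) {
  by_g <- .gunc_by_genome(gunc)
  mdm <- validate_table(mdm, "mdm")
  mdm_of <- setNames(mdm$contamination_fraction, mdm$genome_id)
  missing_mdm <- setdiff(names(by_g), names(mdm_of))
  if (length(missing_mdm))
    stop("genome(s) without an mdm estimate: ",
         paste(missing_mdm, collapse = ", "), call. = FALSE)
  tab <- do.call(rbind, lapply(names(by_g), function(g) {
    ev <- by_g[[g]]
    data.frame(genome_id = g,
               gunc_fraction = ev$contamination_portion[which.max(ev$css)],
               mdm_fraction = mdm_of[[g]], stringsAsFactors = FALSE)
  }))
  tab$difference <- tab$gunc_fraction - tab$mdm_fraction
  if (nrow(tab) < 3L) stop("need >= 3 genomes for the fit", call. = FALSE)
  fit <- lm(mdm_fraction ~ gunc_fraction, data = tab)
  sm <- summary(fit)
  slope_p <- if (nrow(sm$coefficients) > 1L) sm$coefficients[2L, 4L] else
    NA_real_
  structure(list(table = tab,
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p_value = slope_p),
            class = "incongruence")
}

#' @param x an `incongruence` result.
#' @param ... ignored.
#' @rdname contamination_incongruence
#' @export
print.incongruence <- function(x, ...) {
  cat("Contamination incongruence over ", nrow(x$table), " genomes\n",
      "  OLS: mdm = ", format(x$intercept, digits = 3), " + ",
      format(x$slope, digits = 3), " * gunc; r^2 = ",
      format(x$r_squared, digits = 3), ", p = ",
      format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Audit 16S rRNA taxonomy against genome taxonomy
#'
#' A genome mismatches at a rank when both its genome-level taxonomy and
#' at least one of its 16S assignments carry a (non-empty) label there
#' and the labels differ; unassigned labels never conflict. A genome has
#' a multi-copy conflict at a rank when two or more of its own 16S
#' copies carry different non-empty labels. Mismatches are counted per
#' collection at the domain, phylum and class ranks, and the fraction of
#' genomes with any recovered 16S sequence is reported per collection.
#'
#' @param genomes a `genomes` table (taxonomy + collection per genome).
#' @param rrna an `rrna` table (`genome_id`, `seq_id`, `taxonomy`); every
#'   row must reference a genome.
#' @param ranks ranks audited (default domain, phylum, class).
#' @return a list of class `"conflict_16s"`: `mismatch_counts`
#'   (collection x rank matrix), `mismatches` (per-genome detail),
#'   `multi_copy_conflicts` (data.frame genome_id, rank),
#'   `recovery_fraction` (named per collection).
#' @export
conflict_16s <- function(genomes, rrna,
                         ranks = c("domain", "phylum", "class")) {
  genomes <- validate_table(genomes, "genomes")
  rrna <- validate_table(rrna, "rrna")
  ranks <- normalize_rank(ranks)
  orphan <- setdiff(rrna$genome_id, genomes$genome_id)
  if (length(orphan))
    stop("rrna rows for unknown genome(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  gt <- parse_taxonomy(genomes$taxonomy)
  rownames(gt) <- genomes$genome_id
  rt <- parse_taxonomy(rrna$taxonomy)
  coll <- setNames(genomes$collection, genomes$genome_id)
  collections <- sort(unique(genomes$collection))
  mm <- matrix(0L, length(collections), length(ranks),
               dimnames = list(collections, ranks))
  mismatches <- list(); conflicts <- list()
  for (g in unique(rrna$genome_id)) {
    rows <- which(rrna$genome_id == g)
    for (r in ranks) {
      glab <- gt[g, r]
      slabs <- rt[rows, r]
      ns <- slabs[nzchar(slabs)]
      if (nzchar(glab) && length(ns) && any(ns != glab)) {
        mm[coll[[g]], r] <- mm[coll[[g]], r] + 1L
        mismatches[[length(mismatches) + 1L]] <-
          data.frame(genome_id = g, rank = r, genome_label = glab,
                     rrna_labels = paste(unique(ns), collapse = "|"),
                     stringsAsFactors = FALSE)
      }
      if (length(unique(ns)) > 1L)
        conflicts[[length(conflicts) + 1L]] <-
          data.frame(genome_id = g, rank = r, stringsAsFactors = FALSE)
    }
  }
  recovered <- vapply(split(genomes$genome_id %in% rrna$genome_id,
                            genomes$collection), mean, 0)
  empty <- function(l, cols) if (length(l)) do.call(rbind, l) else
    as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  structure(list(
    mismatch_counts = mm,
    mismatches = empty(mismatches, c("genome_id", "rank", "genome_label",
                                     "rrna_labels")),
    multi_copy_conflicts = empty(conflicts, c("genome_id", "rank")),
    recovery_fraction = recovered[collections]),
    class = "conflict_16s")
}

#' @param x a `conflict_16s` result.
#' @param ... ignored.
#' @rdname conflict_16s
#' @export
print.conflict_16s <- function(x, ...) {
  cat("16S taxonomic conflict audit\n\nmismatch counts:\n")
  print(x$mismatch_counts)
  cat("\nmulti-copy conflicts: ", nrow(x$multi_copy_conflicts),
      "\nrecovery fraction:\n", sep = "")
  print(round(x$recovery_fraction, 3))
  invisible(x)
}
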