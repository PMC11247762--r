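# Fragment-recruitment comparison: per-sample recruited-read fractions
# at identity thresholds for each reference set, compared across samples
# by the exact paired Wilcoxon signed-rank test.

DEFAULT_IDENTITY_THRESHOLDS <- c(1.00, 0.98, 0.95, 0.90, 0.85, 0.80)

#' Recruited-read fraction per sample and reference set
#'
#' The fraction of a sample's reads recruited by a reference set at an
#' identity threshold: reads whose best alignment reaches
#' `identity >= identity_threshold` and `aln_length >= min_aln_length`,
#' divided by the sample's total read count. Unaligned reads simply have
#' no row in the table.
#'
#' @param aln an `alignments` table (one best alignment per read per
#'   reference set, with `sample_total_reads` constant within a sample).
#' @param identity_threshold minimum best identity in `[0,1]`.
#' @param min_aln_length minimum alignment length in bp (default 100).
#' @return data.frame `sample_id`, `reference_set`, `fraction`.
#' @export
recruitment_fraction <- function(aln, identity_threshold,
                                 min_aln_length = 100L) {
  aln <- validate_table(aln, "alignments")
  tot <- tapply(aln$sample_total_reads, aln$sample_id,
                function(v) length(unique(v)))
  if (any(tot != 1L))
    stop("inconsistent sample_total_reads in sample(s): ",
         paste(names(tot)[tot != 1L], collapse = ", "), call. = FALSE)
  totals <- tapply(aln$sample_total_reads, aln$sample_id, `[`, 1L)
  hit <- aln$identity >= identity_threshold &
    aln$aln_length >= min_aln_length
  keys <- unique(aln[c("sample_id", "reference_set")])
  keys <- keys[order(keys$sample_id, keys$reference_set), , drop = FALSE]
  keys$fraction <- mapply(function(s, rs) {
    sum(hit & aln$sample_id == s & aln$reference_set == rs) / totals[[s]]
  }, keys$sample_id, keys$reference_set)
  rownames(keys) <- NULL
  keys
}

#' Paired comparison of recruitment between reference sets
#'
#' At each identity threshold, compares the per-sample recruited
#' fractions of the SAG and MAG reference sets with the exact two-sided
#' paired Wilcoxon signed-rank test across samples. Comparisons with
#' `p >= 0.05` are labeled `"ns"`.
#'
#' @inheritParams recruitment_fraction
#' @param thresholds identity thresholds (default
#'   `c(1, 0.98, 0.95, 0.90, 0.85, 0.80)`).
#' @return data.frame `threshold`, `n_samples`, `statistic` (W),
#'   `p_value`, `label`.
#' @export
compare_recruitment <- function(aln, thresholds = DEFAULT_IDENTITY_THRESHOLDS,
                                min_aln_length = 100L) {
  aln <- validate_table(aln, "alignments")
  rows <- lapply(thresholds, function(th) {
    fr <- recruitment_fraction(aln, th, min_aln_length)
    wide <- merge(fr[fr$reference_set == "SAG", c("sample_id", "fraction")],
                  fr[fr$reference_set == "MAG", c("sample_id", "fraction")],
                  by = "sample_id", suffixes = c("_sag", "_mag"))
    missing <- setdiff(unique(fr$sample_id), wide$sample_id)
    if (length(missing))
      stop("sample(s) missing one reference set: ",
           paste(missing, collapse = ", "), call. = FALSE)
    w <- wilcoxon_signed_rank_paired(wide$fraction_sag, wide$fraction_mag)
    data.frame(threshold = th, n_samples = nrow(wide),
               statistic = w$statistic, p_value = w$p_value,
               label = if (w$p_value >= 0.05) "ns" else
                 format(w$p_value, digits = 3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
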