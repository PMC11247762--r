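# Fixture builders used across test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

make_genomes <- function(n = 10, collection = rep(c("SAG", "MAG"),
                                                  length.out = n),
                         completeness = round(runif(n, 50, 100), 2),
                         contamination = round(runif(n, 0, 10), 2),
                         depth_m = runif(n, 0, 50),
                         latitude_deg = runif(n, -35, 35),
                         region_flag = "open_ocean",
                         taxonomy = NULL) {
  if (is.null(taxonomy))
    taxonomy <- sprintf(
      "d__Bacteria;p__Phylum%02d;c__Class%02d;o__Order%02d;f__Family%02d;g__Genus%02d;s__Species%02d",
      (seq_len(n) - 1L) %/% 8L + 1L, (seq_len(n) - 1L) %/% 4L + 1L,
      (seq_len(n) - 1L) %/% 2L + 1L, seq_len(n), seq_len(n), seq_len(n))
  data.frame(
    genome_id = sprintf("g%03d", seq_len(n)),
    collection = collection,
    taxonomy = taxonomy,
    completeness = completeness,
    contamination = contamination,
    sample_id = sprintf("s%02d", rep_len(1:4, n)),
    depth_m = depth_m,
    latitude_deg = latitude_deg,
    region_flag = rep_len(region_flag, n),
    stringsAsFactors = FALSE)
}

make_counts <- function(counts_by_method, rank = "order") {
  # counts_by_method: named list method -> matrix lineage x sample
  rows <- list()
  for (m in names(counts_by_method)) {
    mat <- counts_by_method[[m]]
    for (s in seq_len(ncol(mat)))
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, sample_id = sprintf("%s_s%02d", m, s),
        lineage = rownames(mat), rank = rank,
        count = as.integer(mat[, s]), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

random_dna_seqs <- function(n, len_range = c(20, 40), prefix = "q") {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  sequence_records(
    seq_id = sprintf("%s%03d", prefix, seq_len(n)),
    genome_id = sprintf("G%02d", rep_len(1:3, n)),
    alphabet = "nucleotide",
    residues = vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), ""))
}

# sequences drawn from a few mutated "families" so clustering instances
# contain both mergeable and distinct pairs
family_seqs <- function(n, n_fam = 3, len = 30, sub_rate = 0.05) {
  anc <- replicate(n_fam, paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = ""))
  res <- vapply(seq_len(n), function(i) {
    ch <- strsplit(anc[[sample(n_fam, 1)]], "")[[1]]
    hit <- runif(len) < sub_rate
    ch[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
    paste(ch, collapse = "")
  }, "")
  sequence_records(sprintf("m%03d", seq_len(n)),
                   sprintf("G%02d", rep_len(1:2, n)),
                   "nucleotide", res)
}
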