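#' GTDB-style ranked taxonomy strings
#'
#' A taxonomy is a fixed vector of seven rank labels (domain, phylum, class,
#' order, family, genus, species). An empty label means "unassigned" at that
#' rank; an empty label never compares equal to anything, including another
#' empty label. Serialization is the GTDB convention
#' `"d__X;p__Y;c__;o__;f__;g__;s__"`, with empty labels kept as bare
#' prefixes; the parser tolerates missing trailing ranks.
#'
#' @param x character vector of taxonomy strings.
#' @return `parse_taxonomy()`: a character matrix with one row per input and
#'   the seven ranks as columns. `format_taxonomy()`: a character vector of
#'   GTDB-style strings.
#' @examples
#' m <- parse_taxonomy("d__Bacteria;p__Proteobacteria")
#' m[, "phylum"]
#' format_taxonomy(m)
#' @export
parse_taxonomy <- function(x) {
  stopifnot(is.character(x))
  out <- matrix("", nrow = length(x), ncol = 7L,
                dimnames = list(NULL, TAX_RANKS))
  for (i in seq_along(x)) {
    if (is.na(x[i]) || !nzchar(x[i])) next
    parts <- strsplit(x[i], ";", fixed = TRUE)[[1L]]
    parts <- trimws(parts)
    for (p in parts) {
      if (!nzchar(p)) next
      hit <- which(startsWith(p, RANK_PREFIX))
      if (length(hit) != 1L)
        stop("malformed taxonomy segment '", p, "' in '", x[i], "'",
             call. = FALSE)
      out[i, hit] <- substring(p, 4L)
    }
  }
  out
}

#' @param m a seven-column taxonomy matrix as returned by [parse_taxonomy()],
#'   or a character vector of length 7.
#' @rdname parse_taxonomy
#' @export
format_taxonomy <- function(m) {
  if (is.vector(m)) m <- matrix(m, nrow = 1L, dimnames = list(NULL, TAX_RANKS))
  stopifnot(ncol(m) == 7L)
  apply(m, 1L, function(r) paste0(RANK_PREFIX, r, collapse = ";"))
}

# Label comparison where "" (unassigned) equals nothing. Case-sensitive.
labels_match <- function(a, b) nzchar(a) & nzchar(b) & a == b

# Normalize an external rank word ("kingdom" -> "domain") and validate.
normalize_rank <- function(rank) {
  rank <- tolower(rank)
  rank[rank == "kingdom"] <- "domain"
  bad <- setdiff(unique(rank), TAX_RANKS)
  if (length(bad))
    stop("unknown taxonomic rank(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  rank
}

# Extract rank labels from either a genomes table, a character vector of
# taxonomy strings, or an already-parsed matrix.
taxonomy_labels <- function(taxa, rank) {
  rank <- normalize_rank(rank)
  if (is.data.frame(taxa)) taxa <- taxa$taxonomy
  if (is.character(taxa)) taxa <- parse_taxonomy(taxa)
  taxa[, rank]
}
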