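# Tabular I/O: every pipeline table is tab-separated UTF-8 with a mandatory
# header. Empty cell = missing; "." is forbidden as a numeric placeholder.
# Comment lines starting with '#' (provenance headers) are ignored on read.

.col_types <- function(schema) {
  switch(schema,
    genomes = c(genome_id = "character", collection = "character",
                taxonomy = "character", completeness = "numeric",
                contamination = "numeric", sample_id = "character",
                depth_m = "numeric", latitude_deg = "numeric",
                region_flag = "character"),
    counts = c(method = "character", sample_id = "character",
               lineage = "character", rank = "character", count = "integer"),
    annotations = c(genome_id = "character", gene_id = "character",
                    ko_id = "character"),
    modules = c(module_id = "character", ko_id = "character"),
    gunc = c(genome_id = "character", rank = "character", css = "numeric",
             rrs = "numeric", contamination_portion = "numeric"),
    mdm = c(genome_id = "character", contamination_fraction = "numeric"),
    rrna = c(genome_id = "character", seq_id = "character",
             taxonomy = "character"),
    alignments = c(sample_id = "character", reference_set = "character",
                   read_id = "character", identity = "numeric",
                   aln_length = "integer", sample_total_reads = "integer"),
    clusters = c(member_id = "character", cluster_id = "character",
                 is_representative = "logical"),
    stop("unknown table schema '", schema, "'", call. = FALSE)
  )
}

#' Names of the declared table schemas
#' @return character vector of schema names usable with [read_table()].
#' @export
table_schemas <- function() {
  c("genomes", "counts", "annotations", "modules", "gunc", "mdm", "rrna",
    "alignments", "clusters")
}

.fail_rows <- function(bad, what) {
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    rows <- which(bad | is.na(bad))
    stop(what, " (row", if (length(rows) > 1L) "s", " ",
         paste(head(rows, 5L), collapse = ", "),
         if (length(rows) > 5L) ", ...", ")", call. = FALSE)
  }
  invisible(NULL)
}

.in_range <- function(x, lo, hi) !is.na(x) & x >= lo & x <= hi

validate_table <- function(rows, schema) {
  types <- .col_types(schema)
  missing_cols <- setdiff(names(types), names(rows))
  if (length(missing_cols))
    stop("schema '", schema, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(rows), names(types))
  if (length(extra))
    stop("schema '", schema, "': unknown column(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
  rows <- rows[names(types)]
  for (cn in names(types)) {
    v <- rows[[cn]]
    ok <- switch(types[[cn]],
      character = is.character(v),
      numeric = is.numeric(v),
      integer = is.numeric(v) && all(is.na(v) | v == floor(v)),
      logical = is.logical(v) || all(v %in% c("TRUE", "FALSE", NA)))
    if (!ok)
      stop("schema '", schema, "': column '", cn, "' has the wrong type",
           call. = FALSE)
    if (types[[cn]] == "integer") rows[[cn]] <- as.integer(v)
    if (types[[cn]] == "logical") rows[[cn]] <- as.logical(v)
  }
  switch(schema,
    genomes = {
      dup <- duplicated(rows$genome_id)
      .fail_rows(dup, "duplicate genome_id")
      .fail_rows(!rows$collection %in% COLLECTIONS,
                 "collection must be one of SAG, MAG, ISOLATE")
      .fail_rows(!.in_range(rows$completeness, 0, 100),
                 "completeness outside [0,100]")
      .fail_rows(!.in_range(rows$contamination, 0, 100),
                 "contamination outside [0,100]")
      .fail_rows(!(!is.na(rows$depth_m) & rows$depth_m >= 0),
                 "depth_m must be nonnegative")
      .fail_rows(!.in_range(rows$latitude_deg, -90, 90),
                 "latitude_deg outside [-90,90]")
      .fail_rows(!rows$region_flag %in%
                   c("open_ocean", "coastal", "inland_sea"),
                 "region_flag must be open_ocean, coastal or inland_sea")
      invisible(parse_taxonomy(rows$taxonomy))   # errors on malformed strings
    },
    counts = {
      .fail_rows(!rows$method %in% METHODS,
                 "method must be one of SAG, MAG, AMPLICON, SHOTGUN")
      .fail_rows(!(!is.na(rows$count) & rows$count >= 0L),
                 "count must be a nonnegative integer")
      key <- paste(rows$method, rows$sample_id, rows$rank, rows$lineage,
                   sep = "\r")
      .fail_rows(duplicated(key),
                 "duplicate (method, sample_id, lineage) row")
    },
    gunc = {
      rows$rank <- normalize_rank(rows$rank)
      .fail_rows(!.in_range(rows$css, 0, 1), "css outside [0,1]")
      .fail_rows(!.in_range(rows$rrs, 0, 1), "rrs outside [0,1]")
      .fail_rows(!.in_range(rows$contamination_portion, 0, 1),
                 "contamination_portion outside [0,1]")
      .fail_rows(duplicated(paste(rows$genome_id, rows$rank, sep = "\r")),
                 "duplicate (genome_id, rank) row")
    },
    mdm = {
      .fail_rows(!.in_range(rows$contamination_fraction, 0, 1),
                 "contamination_fraction outside [0,1]")
      .fail_rows(duplicated(rows$genome_id), "duplicate genome_id")
    },
    alignments = {
      .fail_rows(!rows$reference_set %in% c("SAG", "MAG"),
                 "reference_set must be SAG or MAG")
      .fail_rows(!.in_range(rows$identity, 0, 1), "identity outside [0,1]")
      .fail_rows(!(!is.na(rows$aln_length) & rows$aln_length >= 1L),
                 "aln_length must be >= 1")
      .fail_rows(!(!is.na(rows$sample_total_reads) &
                     rows$sample_total_reads >= 1L),
                 "sample_total_reads must be >= 1")
      .fail_rows(duplicated(paste(rows$sample_id, rows$reference_set,
                                  rows$read_id, sep = "\r")),
                 "duplicate (sample, reference_set, read) row")
    },
    clusters = {
      .fail_rows(duplicated(rows$member_id), "member appears more than once")
      reps <- rows$member_id[rows$is_representative]
      n_rep <- table(factor(rows$cluster_id[rows$is_representative],
                            levels = unique(rows$cluster_id)))
      if (any(n_rep != 1L))
        stop("each cluster needs exactly one representative; violated by ",
             paste(names(n_rep)[n_rep != 1L], collapse = ", "), call. = FALSE)
    },
    NULL)
  rows
}

#' Read or write a typed pipeline table
#'
#' All pipeline tables are tab-separated with a mandatory header whose
#' column names must match the declared schema exactly (see
#' [table_schemas()]). Rows are validated against the schema's type and
#' bound constraints; violations are reported with row numbers. Reals are
#' serialized with 15 significant digits so that
#' `read_table(write_table(x))` round-trips text and integers bit-exactly
#' and reals to better than 1e-12 relative error.
#'
#' @param path file path.
#' @param schema one of [table_schemas()].
#' @param rows a data.frame satisfying the schema.
#' @param header_comments optional character vector written as leading
#'   `#`-prefixed provenance lines.
#' @return `read_table()`: a validated data.frame. `write_table()`:
#'   `path`, invisibly.
#' @export
read_table <- function(path, schema) {
  types <- .col_types(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[!startsWith(first, "#")]
  if (!length(first)) stop("file has no header row: ", path, call. = FALSE)
  hdr <- strsplit(first[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(hdr, names(types)))
    stop("header of ", path, " does not match schema '", schema,
         "': expected [", paste(names(types), collapse = ", "), "], found [",
         paste(hdr, collapse = ", "), "]", call. = FALSE)
  rows <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                     colClasses = "character", na.strings = NULL,
                     stringsAsFactors = FALSE, quote = "",
                     fileEncoding = "UTF-8")
  for (cn in names(types)) {
    v <- rows[[cn]]
    if (types[[cn]] == "character") next
    if (any(v == "."))
      stop("schema '", schema, "': column '", cn,
           "' uses '.' as a placeholder; empty cell means missing",
           call. = FALSE)
    v[v == ""] <- NA
    conv <- switch(types[[cn]],
                   numeric = suppressWarnings(as.numeric(v)),
                   integer = suppressWarnings(as.numeric(v)),
                   logical = as.logical(v))
    .fail_rows(!is.na(v) & is.na(conv),
               paste0("column '", cn, "': type violation"))
    if (types[[cn]] == "integer") {
      .fail_rows(!is.na(conv) & conv != floor(conv),
                 paste0("column '", cn, "': not an integer"))
      conv <- as.integer(conv)
    }
    rows[[cn]] <- conv
  }
  validate_table(rows, schema)
}

#' @rdname read_table
#' @export
write_table <- function(rows, path, schema, header_comments = NULL) {
  rows <- validate_table(as.data.frame(rows), schema)
  out <- rows
  for (cn in names(out))
    if (is.double(out[[cn]])) out[[cn]] <- sprintf("%.15g", out[[cn]])
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_comments))
    writeLines(paste0("# ", header_comments), con)
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Toy sequence records and FASTA I/O
#'
#' Sequences are held as a data.frame with columns `seq_id`, `genome_id`,
#' `alphabet` (`"nucleotide"` or `"protein"`) and `residues`. Residues are
#' restricted to the declared alphabet plus the `N`/`X` wildcards, which
#' count as alignment columns but never as matches. FASTA headers are
#' written as `seq_id genome_id`.
#'
#' @param seq_id,genome_id,residues character vectors of equal length.
#' @param alphabet `"nucleotide"` or `"protein"` (recycled).
#' @return a validated `sequence record` data.frame.
#' @export
sequence_records <- function(seq_id, genome_id, alphabet, residues) {
  df <- data.frame(seq_id = as.character(seq_id),
                   genome_id = as.character(genome_id),
                   alphabet = rep_len(alphabet, length(seq_id)),
                   residues = toupper(as.character(residues)),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$alphabet %in% c("nucleotide", "protein")))
  if (any(!nzchar(df$residues)))
    stop("empty sequence(s): ",
         paste(df$seq_id[!nzchar(df$residues)], collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$seq_id))
    stop("duplicate seq_id", call. = FALSE)
  ok_nt <- !grepl("[^ACGTN]", df$residues)
  ok_aa <- !grepl("[^ACDEFGHIKLMNPQRSTVWYX]", df$residues)
  bad <- ifelse(df$alphabet == "nucleotide", !ok_nt, !ok_aa)
  if (any(bad))
    stop("residues outside declared alphabet: ",
         paste(df$seq_id[bad], collapse = ", "), call. = FALSE)
  df
}

#' @param path FASTA file path.
#' @rdname sequence_records
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  hdr <- strsplit(names(set), "[ \t]+")
  sequence_records(
    seq_id = vapply(hdr, `[`, "", 1L),
    genome_id = vapply(hdr, function(h) if (length(h) > 1L) h[2L] else "", ""),
    alphabet = alphabet,
    residues = as.character(set))
}

#' @param seqs a sequence record data.frame.
#' @rdname sequence_records
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(setNames(
    seqs$residues, trimws(paste(seqs$seq_id, seqs$genome_id))))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Filter genomes on geographic and depth metadata
#'
#' Mirrors the selection of open-ocean, epipelagic genomes: keeps genomes
#' sampled at or above `max_depth_m`, within the latitude band, and not
#' flagged as coming from an excluded region (coastal areas and inland
#' seas by default). Row order is preserved and the operation is
#' idempotent.
#'
#' @param genomes a `genomes` table (see [read_table()]).
#' @param max_depth_m maximum sampling depth in meters (default 100, an
#'   epipelagic configuration choice).
#' @param lat_min,lat_max inclusive latitude band in degrees (defaults
#'   -40 and 40).
#' @param exclude_regions region flags to drop.
#' @return the retained subset of `genomes`.
#' @export
filter_genomes_metadata <- function(genomes, max_depth_m = 100,
                                    lat_min = -40, lat_max = 40,
                                    exclude_regions = c("coastal",
                                                        "inland_sea")) {
  genomes <- validate_table(genomes, "genomes")
  keep <- genomes$depth_m <= max_depth_m &
    genomes$latitude_deg >= lat_min & genomes$latitude_deg <= lat_max &
    !genomes$region_flag %in% exclude_regions
  genomes[keep, , drop = FALSE]
}
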