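# Greedy identity-threshold clustering, used three ways: species-like
# genome dereplication on an ANI matrix, nucleotide "unigene" clustering,
# and protein-family clustering.

#' Clustering parameters
#'
#' @param identity_threshold minimum pairwise identity in (0,1] for a
#'   sequence to join a cluster.
#' @param coverage_threshold minimum alignment coverage in (0,1].
#' @param coverage_mode which sequence the coverage requirement applies
#'   to: `"shorter"` (the shorter of the pair, the CD-HIT `-aS` flavor),
#'   `"query"` (the incoming sequence), or `"bidirectional"` (both).
#' @return a list of class `"cluster_params"`.
#' @export
cluster_params <- function(identity_threshold = 0.95,
                           coverage_threshold = 0.9,
                           coverage_mode = c("shorter", "query",
                                             "bidirectional")) {
  coverage_mode <- match.arg(coverage_mode)
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            coverage_threshold > 0, coverage_threshold <= 1)
  structure(list(identity_threshold = identity_threshold,
                 coverage_threshold = coverage_threshold,
                 coverage_mode = coverage_mode),
            class = "cluster_params")
}

.wildcards_for <- function(alphabet) {
  if (alphabet == "nucleotide") "N" else "X"
}

#' Pairwise identity and coverage by global alignment
#'
#' Aligns two sequences globally (Needleman-Wunsch with affine gap
#' costs, end gaps penalized). Identity is matches divided by alignment
#' columns after excluding terminal gap columns, so a short sequence
#' contained in a longer one can reach identity 1 while coverage of the
#' longer sequence stays low. Wildcard residues (`N` for nucleotide,
#' `X` for protein) count as columns but never as matches. The result is
#' deterministic: score ties are resolved by preferring more matches,
#' then more aligned columns, then substitution over gap moves.
#'
#' @param a,b single sequence records (one-row data.frames from
#'   [sequence_records()]) or plain character strings.
#' @param alphabet required when `a`, `b` are plain strings.
#' @param match,mismatch substitution scores (defaults +1 / -1).
#' @param gap_open,gap_extend affine gap scores; a gap of length g costs
#'   `gap_open + g * gap_extend` (defaults -3 and -1).
#' @return a list with `identity`, `coverage_shorter`, `coverage_query`
#'   (coverage of `a`), `coverage_target` (coverage of `b`), plus the raw
#'   `score`, `matches` and column counts.
#' @export
pairwise_identity <- function(a, b, alphabet = NULL, match = 1,
                              mismatch = -1, gap_open = -3,
                              gap_extend = -1) {
  get_seq <- function(s) {
    if (is.data.frame(s)) {
      stopifnot(nrow(s) == 1L)
      list(res = s$residues, alph = s$alphabet)
    } else list(res = as.character(s), alph = alphabet)
  }
  sa <- get_seq(a); sb <- get_seq(b)
  if (is.null(sa$alph) || is.null(sb$alph))
    stop("alphabet must be given for plain character sequences",
         call. = FALSE)
  if (!identical(sa$alph, sb$alph))
    stop("alphabet mismatch: ", sa$alph, " vs ", sb$alph, call. = FALSE)
  if (!nzchar(sa$res) || !nzchar(sb$res))
    stop("empty sequence", call. = FALSE)
  r <- .align_affine(sa$res, sb$res, match, mismatch, gap_open, gap_extend,
                     .wildcards_for(sa$alph))
  shorter_is_a <- nchar(sa$res) <= nchar(sb$res)
  r$coverage_shorter <- if (shorter_is_a) r$coverage_query else
    r$coverage_target
  r
}

.coverage_ok <- function(aln, params) {
  cov <- switch(params$coverage_mode,
                shorter = aln$coverage_shorter,
                query = aln$coverage_query,
                bidirectional = min(aln$coverage_query, aln$coverage_target))
  cov >= params$coverage_threshold
}

#' Greedy incremental sequence clustering
#'
#' Sequences are processed in order of decreasing length (ties broken by
#' lexicographic `seq_id`). Each sequence is compared against the
#' representatives of all existing clusters and joins the best-scoring
#' one (highest identity; ties to the earliest-created cluster) among
#' those meeting both the identity and the coverage threshold; if none
#' qualifies it founds a new cluster with itself as representative.
#' Because representatives are always at least as long as later members,
#' every member satisfies the thresholds against its representative.
#'
#' @param seqs a sequence record data.frame ([sequence_records()]).
#' @param params a [cluster_params()] object.
#' @param ... alignment scoring arguments passed to [pairwise_identity()].
#' @return a `clusters` table: `member_id`, `cluster_id` (the
#'   representative's `seq_id`), `is_representative`.
#' @export
greedy_cluster <- function(seqs, params = cluster_params(), ...) {
  stopifnot(is.data.frame(seqs), nrow(seqs) >= 1L)
  ord <- order(-nchar(seqs$residues), seqs$seq_id)
  seqs <- seqs[ord, , drop = FALSE]
  rep_ix <- integer(0)         # row indices of representatives, creation order
  assign_to <- integer(nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    best <- 0L; best_id <- -1
    for (ci in seq_along(rep_ix)) {
      aln <- pairwise_identity(seqs[i, ], seqs[rep_ix[ci], ], ...)
      if (aln$identity >= params$identity_threshold &&
          .coverage_ok(aln, params) && aln$identity > best_id) {
        best_id <- aln$identity; best <- ci
      }
    }
    if (best == 0L) {
      rep_ix <- c(rep_ix, i)
      assign_to[i] <- length(rep_ix)
    } else assign_to[i] <- best
  }
  out <- data.frame(member_id = seqs$seq_id,
                    cluster_id = seqs$seq_id[rep_ix[assign_to]],
                    is_representative = seq_len(nrow(seqs)) %in% rep_ix,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  validate_table(out, "clusters")
}

#' Species-like genome dereplication on an ANI matrix
#'
#' Greedy dereplication at an average-nucleotide-identity threshold
#' (default 95%, the species-level criterion). Genomes are processed in
#' ranking order (descending completeness, ties by `genome_id`); each
#' joins the first existing representative with ANI at or above the
#' threshold, otherwise it founds a new cluster. The founding genome is
#' the cluster representative.
#'
#' @param genomes a `genomes` table.
#' @param ani symmetric matrix of percent identities with `genome_id`
#'   dimnames, diagonal 100, values in `[0,100]`.
#' @param threshold ANI percent threshold (default 95).
#' @return a `clusters` table keyed by `genome_id`.
#' @export
ani_dereplicate <- function(genomes, ani, threshold = 95) {
  genomes <- validate_table(genomes, "genomes")
  ids <- genomes$genome_id
  if (is.null(dimnames(ani)) ||
      !all(ids %in% rownames(ani)) || !all(ids %in% colnames(ani)))
    stop("ani matrix must carry all genome_ids as dimnames", call. = FALSE)
  ani <- ani[ids, ids, drop = FALSE]
  if (anyNA(ani)) stop("missing ANI pair(s)", call. = FALSE)
  if (max(abs(ani - t(ani))) > 1e-9)
    stop("ani matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(ani) - 100) > 1e-9))
    stop("ani diagonal must be 100", call. = FALSE)
  if (any(ani < 0 | ani > 100)) stop("ani outside [0,100]", call. = FALSE)
  ord <- order(-genomes$completeness, ids)
  ranked <- ids[ord]
  reps <- character(0)
  cluster_of <- character(length(ranked))
  for (i in seq_along(ranked)) {
    g <- ranked[i]
    hit <- which(ani[g, reps] >= threshold)
    if (length(hit)) cluster_of[i] <- reps[hit[1L]]
    else { reps <- c(reps, g); cluster_of[i] <- g }
  }
  out <- data.frame(member_id = ranked, cluster_id = cluster_of,
                    is_representative = ranked == cluster_of,
                    stringsAsFactors = FALSE)
  validate_table(out, "clusters")
}
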