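# Independent oracles: brute-force or closed-form reimplementations used
# to check the package's fast paths. These deliberately share no code
# with the implementation beyond validated primitives.

# --- exhaustive global-alignment enumeration ---------------------------

# all monotone alignment paths as move vectors (1 = diagonal, 2 = gap in
# b consuming a, 3 = gap in a consuming b)
enum_alignments <- function(la, lb) {
  res <- list()
  rec <- function(i, j, moves) {
    if (i == 0L && j == 0L) {
      res[[length(res) + 1L]] <<- rev(moves)
      return(invisible(NULL))
    }
    if (i > 0L && j > 0L) rec(i - 1L, j - 1L, c(moves, 1L))
    if (i > 0L) rec(i - 1L, j, c(moves, 2L))
    if (j > 0L) rec(i, j - 1L, c(moves, 3L))
  }
  rec(la, lb, integer(0))
  res
}

score_alignment <- function(a, b, mv, match = 1, mismatch = -1,
                            gap_open = -3, gap_extend = -1,
                            wildcard = "N") {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  i <- 0L; j <- 0L; sc <- 0; matches <- 0L; mcols <- 0L; prev <- 0L
  for (m in mv) {
    if (m == 1L) {
      i <- i + 1L; j <- j + 1L; mcols <- mcols + 1L
      is_m <- ca[i] == cb[j] && !(ca[i] %in% wildcard)
      sc <- sc + if (is_m) match else mismatch
      if (is_m) matches <- matches + 1L
    } else {
      sc <- sc + gap_extend + if (m != prev) gap_open else 0
      if (m == 2L) i <- i + 1L else j <- j + 1L
    }
    prev <- m
  }
  lead <- 0L
  while (lead < length(mv) && mv[lead + 1L] != 1L) lead <- lead + 1L
  trail <- 0L
  while (trail < length(mv) - lead && mv[length(mv) - trail] != 1L)
    trail <- trail + 1L
  core <- length(mv) - lead - trail
  list(score = sc, matches = matches, mcols = mcols,
       identity = if (core > 0L) matches / core else 0)
}

# best score / max identity among optimal alignments, by enumeration
enum_alignment_optimum <- function(a, b, ...) {
  alns <- enum_alignments(nchar(a), nchar(b))
  scored <- lapply(alns, function(mv) score_alignment(a, b, mv, ...))
  key <- vapply(scored, function(s)
    s$score * 1e6 + s$matches * 1e3 + s$mcols, 0)
  best <- which(key == max(key))
  list(score = max(vapply(scored, `[[`, 0, "score")),
       identity = max(vapply(scored[best], `[[`, 0, "identity")))
}

# --- greedy clustering replay ------------------------------------------

# independent replay of the greedy rule: recompute all identities and
# coverages, process in decreasing length / lexicographic order, join
# the best acceptable representative (ties: earliest cluster)
replay_greedy <- function(seqs, params) {
  seqs <- seqs[order(-nchar(seqs$residues), seqs$seq_id), , drop = FALSE]
  reps <- character(0)
  assign_to <- character(nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    best_id <- -Inf; best_rep <- NA_character_
    for (r in reps) {
      aln <- pairwise_identity(seqs[i, ],
                               seqs[seqs$seq_id == r, , drop = FALSE])
      cov <- switch(params$coverage_mode,
                    shorter = aln$coverage_shorter,
                    query = aln$coverage_query,
                    bidirectional = min(aln$coverage_query,
                                        aln$coverage_target))
      if (aln$identity >= params$identity_threshold &&
          cov >= params$coverage_threshold && aln$identity > best_id) {
        best_id <- aln$identity; best_rep <- r
      }
    }
    if (is.na(best_rep)) {
      reps <- c(reps, seqs$seq_id[i])
      assign_to[i] <- seqs$seq_id[i]
    } else assign_to[i] <- best_rep
  }
  setNames(assign_to, seqs$seq_id)
}

# --- exact signed-rank enumeration -------------------------------------

brute_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.vector(signs %*% r)
  p <- min(1, 2 * min(mean(w_all <= w_obs + 1e-9),
                      mean(w_all >= w_obs - 1e-9)))
  list(statistic = w_obs, p_value = p)
}

# --- misc closed forms --------------------------------------------------

ols_normal_equations <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  t_stat <- slope / se
  p <- 2 * pt(abs(t_stat), n - 2, lower.tail = FALSE)
  list(slope = slope, intercept = intercept, r_squared = r2, p_value = p)
}

# transitive closure of an overlap relation by repeated expansion
closure_components <- function(ids, edges) {
  comp <- setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (e in edges) {
      ca <- comp[[e[1]]]; cb <- comp[[e[2]]]
      if (ca != cb) {
        comp[comp == max(ca, cb)] <- min(ca, cb)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(comp), comp)
}

# Monte-Carlo studentized range upper tail
mc_tukey_sf <- function(q, k, df, n_draws, seed) {
  set.seed(seed)
  z <- matrix(rnorm(n_draws * k), ncol = k)
  s <- sqrt(rchisq(n_draws, df) / df)
  rng <- (apply(z, 1L, max) - apply(z, 1L, min)) / s
  vapply(q, function(qi) mean(rng >= qi), 0)
}
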