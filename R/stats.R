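#' Centered log-ratio transform
#'
#' Maps a strictly positive composition to an unconstrained space:
#' `clr(x)_i = ln(x_i) - mean_j ln(x_j)`. The result sums to zero and is
#' invariant to multiplying the input by any positive scalar, which is what
#' makes it suitable for relative-abundance (compositional) data.
#'
#' @param x strictly positive numeric vector, or a matrix whose columns are
#'   compositions (each column is transformed independently).
#' @return vector or matrix of the same shape.
#' @examples
#' clr_transform(c(1, exp(2)))   # -1, 1
#' @export
clr_transform <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("clr_transform requires strictly positive entries", call. = FALSE)
  lx <- log(x)
  if (is.matrix(x)) sweep(lx, 2L, colMeans(lx), "-") else lx - mean(lx)
}

#' Dirichlet Monte-Carlo instances for one sample's counts
#'
#' Draws `n_mc` probability vectors from the Dirichlet posterior with
#' concentration `counts + prior_mass`, the Monte-Carlo device used to
#' propagate count uncertainty before log-ratio analysis. With the default
#' half-count prior, zero counts are handled entirely through the prior.
#'
#' @param counts nonnegative integer vector (length >= 2).
#' @param n_mc number of instances (default 1000).
#' @param prior_mass per-cell prior concentration (default 0.5).
#' @param seed integer seed; the draw is reproducible given
#'   `(counts, n_mc, prior_mass, seed)`.
#' @return a `length(counts) x n_mc` matrix; each column is strictly
#'   positive and sums to 1. Attributes record `n_mc`, `prior_mass`, `seed`.
#' @export
dirichlet_mc_instances <- function(counts, n_mc = 1000, prior_mass = 0.5,
                                   seed) {
  if (length(counts) < 2L) stop("counts must have length >= 2", call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (n_mc < 1L) stop("n_mc must be >= 1", call. = FALSE)
  if (prior_mass <= 0) stop("prior_mass must be > 0", call. = FALSE)
  alpha <- counts + prior_mass
  g <- with_seed(seed,
    matrix(rgamma(length(alpha) * n_mc, shape = alpha), nrow = length(alpha)))
  inst <- sweep(g, 2L, colSums(g), "/")
  structure(inst, n_mc = as.integer(n_mc), prior_mass = prior_mass,
            seed = as.integer(seed))
}

#' Survival function of the studentized range distribution
#'
#' `P(Q_{k,df} >= q)` for the range of `k` independent standard normals
#' divided by an independent estimate of their standard deviation with
#' `df` degrees of freedom. This is the reference distribution of the
#' Games-Howell test statistic. At `k = 2` it reduces to the two-sided
#' Student-t tail at `|t| = q / sqrt(2)`.
#'
#' The implementation integrates the standard double-integral form
#' (outer integral over the chi scale factor, inner over the normal
#' range CDF) with Gauss-Legendre quadrature tuned to an absolute error
#' below 1e-8, and is vectorized over `(q, df)` pairs -- the property
#' that makes Monte-Carlo-scale Games-Howell testing affordable.
#'
#' @param q nonnegative quantile(s).
#' @param k number of groups (>= 2).
#' @param df degrees of freedom (> 0), length 1 or `length(q)`.
#' @return upper-tail probability in `[0,1]`, vectorized over `q`.
#' @export
studentized_range_sf <- function(q, k, df) {
  if (length(k) != 1L || k < 2) stop("k must be >= 2", call. = FALSE)
  if (any(df <= 0)) stop("df must be > 0", call. = FALSE)
  if (any(q < 0, na.rm = TRUE)) stop("q must be nonnegative", call. = FALSE)
  if (length(df) != 1L && length(df) != length(q))
    df <- rep_len(df, length(q))
  .tukey_sf_cpp(as.numeric(q), as.integer(k), as.numeric(df))
}

#' Games-Howell post-hoc test
#'
#' Pairwise comparison of group means that assumes neither equal variances
#' nor equal sample sizes: each pair uses its own Welch standard error and
#' Welch-Satterthwaite degrees of freedom, and the statistic is referred to
#' the studentized range distribution with `k` groups, which controls the
#' familywise error across all pairs.
#'
#' For pair (i, j): difference `d = mean_i - mean_j`,
#' `SE = sqrt(s2_i/n_i + s2_j/n_j)`, `t = d / SE`,
#' `df = (s2_i/n_i + s2_j/n_j)^2 / ((s2_i/n_i)^2/(n_i-1) +
#' (s2_j/n_j)^2/(n_j-1))`, `p = P(Q_{k,df} >= |t| * sqrt(2))`, and the
#' confidence interval has half-width `q_{1-alpha,k,df} * SE / sqrt(2)`.
#'
#' @param groups named list of numeric vectors, one per group (each with
#'   n >= 2 and nonzero variance).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return a data.frame of class `"games_howell"` with one row per
#'   unordered pair: `group_a`, `group_b`, `estimated_difference`,
#'   `standard_error`, `t_statistic`, `welch_df`, `p_value`, `ci_low`,
#'   `ci_high`.
#' @examples
#' games_howell(list(a = c(0, 0, 1, 1, 2), b = c(5, 6, 7, 8, 9)))
#' @export
games_howell <- function(groups, conf_level = 0.95) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need >= 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named", call. = FALSE)
  n <- vapply(groups, length, 0L)
  if (any(n < 2L))
    stop("group(s) with n < 2: ",
         paste(names(groups)[n < 2L], collapse = ", "), call. = FALSE)
  s2 <- vapply(groups, var, 0)
  if (any(s2 == 0))
    stop("zero-variance group(s): ",
         paste(names(groups)[s2 == 0], collapse = ", "), call. = FALSE)
  m <- vapply(groups, mean, 0)
  k <- length(groups)
  pairs <- combn(names(groups), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(ix) {
    a <- pairs[1L, ix]; b <- pairs[2L, ix]
    va <- s2[[a]] / n[[a]]; vb <- s2[[b]] / n[[b]]
    se <- sqrt(va + vb)
    d <- m[[a]] - m[[b]]
    t_stat <- d / se
    df <- (va + vb)^2 / (va^2 / (n[[a]] - 1L) + vb^2 / (n[[b]] - 1L))
    p <- studentized_range_sf(abs(t_stat) * sqrt(2), k, df)
    hw <- qtukey(conf_level, nmeans = k, df = df) * se / sqrt(2)
    data.frame(group_a = a, group_b = b, estimated_difference = d,
               standard_error = se, t_statistic = t_stat, welch_df = df,
               p_value = p, ci_low = d - hw, ci_high = d + hw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "conf_level") <- conf_level
  attr(out, "k") <- k
  class(out) <- c("games_howell", "data.frame")
  out
}

#' @param x a `games_howell` result.
#' @param ... ignored.
#' @rdname games_howell
#' @export
print.games_howell <- function(x, ...) {
  cat("Games-Howell post-hoc test (", attr(x, "k"), " groups, ",
      format(100 * attr(x, "conf_level")), "% CI)\n\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

# Exact null distribution of the positive-rank sum W over all 2^m sign
# assignments, as counts over the doubled (hence integer) rank scale.
# Mid-ranks from ties are halves, so 2*rank is always integral.
.signrank_counts <- function(r2) {
  total <- sum(r2)
  cnt <- numeric(total + 1L)  # index i-1 = doubled rank sum
  cnt[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), cnt[seq_len(total + 1L - r)])
    cnt <- cnt + shifted
  }
  cnt
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided paired test of the hypothesis that the distribution of
#' within-pair differences is symmetric about zero. Zero differences are
#' discarded before ranking by default (classic Wilcoxon policy; the
#' zero-inclusive Pratt variant, which ranks zeros but drops their
#' contribution, is available via `zero_policy = "pratt"`); ties among
#' absolute differences receive mid-ranks. The p-value is exact --
#' computed from the full distribution of the statistic over all `2^m`
#' sign assignments (including with mid-ranks) -- whenever the number of
#' nonzero differences `m` is at most `exact_max_n`; beyond that a
#' normal approximation with tie correction and a 0.5 continuity
#' correction is used. If every difference is zero the p-value is 1.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max_n largest `m` for which the exact distribution is
#'   enumerated (default 25).
#' @param zero_policy `"discard"` (default) or `"pratt"`.
#' @return a list with `statistic` (W, the positive-rank sum), `p_value`,
#'   `n_nonzero`, and `exact` (logical).
#' @examples
#' wilcoxon_signed_rank_paired(1:8 + 0.02, 1:8)$p_value  # 2/2^8
#' @export
wilcoxon_signed_rank_paired <- function(x, y, exact_max_n = 25L,
                                        zero_policy = c("discard",
                                                        "pratt")) {
  zero_policy <- match.arg(zero_policy)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (!length(x)) stop("empty input", call. = FALSE)
  d0 <- x - y
  d <- d0[d0 != 0]
  m <- length(d)
  if (m == 0L)
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L, exact = TRUE))
  r <- if (zero_policy == "pratt") rank(abs(d0))[d0 != 0] else
    rank(abs(d))
  w <- sum(r[d > 0])
  if (m <= exact_max_n) {
    r2 <- as.integer(round(2 * r))
    cnt <- .signrank_counts(r2)
    w2 <- as.integer(round(2 * w))
    tot <- 2^m
    p_le <- sum(cnt[seq_len(w2 + 1L)]) / tot
    p_ge <- sum(cnt[seq.int(w2 + 1L, length(cnt))]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = w, p_value = p, n_nonzero = m, exact = TRUE)
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)   # mid-rank form absorbs the tie correction
    z <- (w - mu - sign(w - mu) * 0.5) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    list(statistic = w, p_value = p, n_nonzero = m, exact = FALSE)
  }
}
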