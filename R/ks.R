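#' Kolmogorov-Smirnov enrichment statistic for a set of query ranks
#'
#' Given the ranks R_1 <= ... <= R_M of the matched query kinases inside a
#' drug's rank-ordered profile of N kinases, computes
#' \deqn{a = \max_{j=1..M} (j/M - R_j/N), \quad
#'       b = \max_{j=1..M} (R_j/N - (j-1)/M)}
#' and the signed statistic KS = a if a > b, KS = -b if b > a (the tie
#' a == b resolves to the positive branch, KS = a). A large positive KS
#' means the query kinases crowd the top (most potently inhibited end) of
#' the profile; a large negative KS means they crowd the bottom.
#'
#' @param query_ranks Integer vector of distinct ranks in 1..`n_ref`
#'   (order irrelevant; sorted internally).
#' @param n_ref Number of kinases in the drug's profile (N).
#' @return A list of class `ks_result`: `a`, `b`, `ks`, `n_matched` (M),
#'   `n_ref` (N), `matched_query_ranks` (sorted).
#' @examples
#' ks_statistic(c(1, 2), 10)$ks   # 0.8: query at the very top
#' ks_statistic(c(9, 10), 10)$ks  # -0.9: query at the very bottom
#' @export
ks_statistic <- function(query_ranks, n_ref) {
  r <- as.integer(query_ranks)
  n_ref <- as.integer(n_ref)
  if (length(r) == 0L)
    stop("empty query rank set", call. = FALSE)
  if (anyNA(r) || any(r < 1L) || any(r > n_ref))
    stop("query ranks must lie in 1..", n_ref, call. = FALSE)
  if (anyDuplicated(r))
    stop("duplicate query ranks", call. = FALSE)
  r <- sort(r)
  m <- length(r)
  j <- seq_len(m)
  a <- max(j / m - r / n_ref)
  b <- max(r / n_ref - (j - 1) / m)
  ks <- if (a >= b) a else -b
  structure(
    list(a = a, b = b, ks = ks, n_matched = m, n_ref = n_ref,
         matched_query_ranks = r),
    class = "ks_result"
  )
}

# Signed KS for each column of a matrix of sorted rank subsets.
# `ranks`: m x T integer matrix, each column a sorted m-subset of 1..n_ref.
# Used by the permutation engine; same mathematics as ks_statistic().
ks_columns <- function(ranks, n_ref) {
  m <- nrow(ranks)
  j <- seq_len(m)
  top <- j / m - ranks / n_ref          # recycles j down columns
  bot <- ranks / n_ref - (j - 1) / m
  a <- apply(top, 2L, max)
  b <- apply(bot, 2L, max)
  ifelse(a >= b, a, -b)
}

#' Running enrichment sum down a ranked profile
#'
#' The position-by-position enrichment curve D(r) = hits(r)/M - r/N for
#' r = 1..N, where hits(r) is the number of matched query ranks <= r. Its
#' maximum over r equals the `a` component of [ks_statistic()], and D(N) = 0
#' whenever all M query kinases are in the profile.
#'
#' @inheritParams ks_statistic
#' @return Numeric vector of length `n_ref`.
#' @examples
#' d <- running_sum(c(1, 2), 10)
#' max(d) == ks_statistic(c(1, 2), 10)$a
#' @export
running_sum <- function(query_ranks, n_ref) {
  r <- sort(as.integer(query_ranks))
  n_ref <- as.integer(n_ref)
  if (length(r) == 0L)
    stop("empty query rank set", call. = FALSE)
  if (anyNA(r) || any(r < 1L) || any(r > n_ref))
    stop("query ranks must lie in 1..", n_ref, call. = FALSE)
  if (anyDuplicated(r))
    stop("duplicate query ranks", call. = FALSE)
  m <- length(r)
  pos <- seq_len(n_ref)
  hits <- findInterval(pos, r)  # number of query ranks <= pos
  hits / m - pos / n_ref
}

#' Connectivity scores from per-drug KS statistics
#'
#' Rescales the signed KS statistics of one query against one reference
#' database so the extremes are +/-1: with P = max(KS) and Q = min(KS),
#' S = KS/P when KS > 0, S = -KS/Q when KS < 0, and S = 0 when KS = 0.
#' At least one drug attains S = 1 whenever any KS is positive, and S = -1
#' whenever any is negative. `NA` inputs (drugs with no matched query
#' kinase) pass through as `NA` and do not enter P or Q.
#'
#' @param ks_values Numeric vector of signed KS statistics, possibly with
#'   `NA` for unscored drugs.
#' @return Numeric vector of S values in \[-1, 1\] (with `NA` preserved).
#' @examples
#' connectivity_scores(c(0.8, -0.9, 0.4))  # 1.0 -1.0 0.5
#' @export
connectivity_scores <- function(ks_values) {
  s <- rep(NA_real_, length(ks_values))
  ok <- !is.na(ks_values)
  if (!any(ok)) return(s)
  ks <- ks_values[ok]
  p <- max(ks)
  q <- min(ks)
  out <- numeric(length(ks))
  pos <- ks > 0
  neg <- ks < 0
  if (any(pos)) out[pos] <- ks[pos] / p   # p > 0 here
  if (any(neg)) out[neg] <- -ks[neg] / q  # q < 0 here
  s[ok] <- out
  s
}

#' Map connectivity scores onto \[0, 1\]
#'
#' The affine map (S + 1)/2: S = -1 maps to 0, S = 0 to 0.5, S = 1 to 1.
#' Strictly increasing, so drug ordering is unchanged and the sign of S is
#' recoverable (normalized score above/below 0.5).
#'
#' @param s_values Numeric vector of connectivity scores in \[-1, 1\].
#' @return Numeric vector in \[0, 1\].
#' @export
normalize_scores <- function(s_values) {
  if (any(!is.na(s_values) & (s_values < -1 | s_values > 1)))
    stop("connectivity scores must lie in [-1, 1]", call. = FALSE)
  (s_values + 1) / 2
}
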