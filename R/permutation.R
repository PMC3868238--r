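# run `expr` under a fixed seed without disturbing the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic 31-bit substream seed from (seed, character id); keeps
# per-drug p-values independent of drug iteration order
mix_seed <- function(seed, id) {
  h <- 0
  for (k in utf8ToInt(as.character(id))) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

#' Permutation p-value for an observed KS statistic
#'
#' Draws `trials` uniform random size-`m` subsets (without replacement) of
#' the ranks 1..`n_ref`, computes the signed KS statistic for each, and
#' counts the exceedances f. The default two-sided rule counts
#' |KS_t| >= |KS_0|; `mode = "literal-one-sided"` counts KS_t >= KS_0.
#' The p-value is the raw frequency f/`trials` (no pseudocount), so p = 0 is
#' representable; set `pseudocount = TRUE` for (f+1)/(T+1).
#'
#' Given identical `(seed, trials, n_ref, m, ks0)` the result is
#' deterministic; the caller's RNG state is left untouched.
#'
#' @param n_ref Profile size N.
#' @param m Query size M (number of matched query kinases), 1 <= m <= N.
#' @param ks0 Observed signed KS statistic.
#' @param trials Number of permutations T (default 500).
#' @param seed Integer seed for this drug's subset draws.
#' @param mode `"two-sided-abs"` (default) or `"literal-one-sided"`.
#' @param pseudocount If `TRUE`, report (f+1)/(T+1) instead of f/T.
#' @return A list of class `permutation_result`: `ks0`, `trials`,
#'   `exceedances` (f), `p_value`, `seed`, `mode`.
#' @examples
#' permutation_pvalue(n_ref = 50, m = 3, ks0 = 0.9, trials = 500, seed = 1)
#' @export
permutation_pvalue <- function(n_ref, m, ks0, trials = 500L, seed = 1L,
                               mode = c("two-sided-abs", "literal-one-sided"),
                               pseudocount = FALSE) {
  mode <- match.arg(mode)
  n_ref <- as.integer(n_ref)
  m <- as.integer(m)
  trials <- as.integer(trials)
  if (m < 1L || m > n_ref)
    stop("m must satisfy 1 <= m <= n_ref", call. = FALSE)
  if (trials < 1L)
    stop("trials must be >= 1 (use trials = 0 upstream to disable p-values)",
         call. = FALSE)

  ks_t <- with_local_seed(seed, {
    draws <- vapply(seq_len(trials),
                    function(t) sort.int(sample.int(n_ref, m)),
                    integer(m))
    ks_columns(matrix(draws, nrow = m), n_ref)
  })

  f <- if (mode == "two-sided-abs") sum(abs(ks_t) >= abs(ks0))
       else sum(ks_t >= ks0)
  p <- if (pseudocount) (f + 1) / (trials + 1) else f / trials
  structure(
    list(ks0 = ks0, trials = trials, exceedances = f, p_value = p,
         seed = as.integer(seed), mode = mode),
    class = "permutation_result"
  )
}

#' Exact exceedance p-value by exhaustive subset enumeration
#'
#' Enumerates every size-`m` subset of 1..`n_ref` (C(n_ref, m) of them),
#' computes the signed KS statistic for each, and returns the exact fraction
#' whose statistic meets or exceeds the observed one under the chosen
#' sidedness rule. Monte-Carlo estimates from [permutation_pvalue()]
#' converge to this value as the trial count grows; it is practical only
#' while C(n_ref, m) stays below `cap`.
#'
#' @inheritParams permutation_pvalue
#' @param cap Maximum number of subsets to enumerate (default 1e5).
#' @return Exact p-value in \[0, 1\].
#' @examples
#' exhaustive_pvalue(4, 2, ks0 = 0.5)  # 5/6
#' @export
exhaustive_pvalue <- function(n_ref, m, ks0,
                              mode = c("two-sided-abs", "literal-one-sided"),
                              cap = 1e5) {
  mode <- match.arg(mode)
  n_ref <- as.integer(n_ref)
  m <- as.integer(m)
  if (m < 1L || m > n_ref)
    stop("m must satisfy 1 <= m <= n_ref", call. = FALSE)
  n_subsets <- choose(n_ref, m)
  if (n_subsets > cap)
    stop(sprintf(
      "C(%d, %d) = %.0f subsets exceeds cap %g; use permutation_pvalue()",
      n_ref, m, n_subsets, cap), call. = FALSE)
  subsets <- utils::combn(n_ref, m)     # columns already sorted ascending
  ks_t <- ks_columns(subsets, n_ref)
  f <- if (mode == "two-sided-abs") sum(abs(ks_t) >= abs(ks0))
       else sum(ks_t >= ks0)
  f / n_subsets
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation p-value: %.4g (f = %d / T = %d, mode = %s, seed = %d)\n",
              x$p_value, x$exceedances, x$trials, x$mode, x$seed))
  invisible(x)
}
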