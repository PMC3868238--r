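#' Score every inhibitor in a reference database against a query
#'
#' For each drug, the query kinases present in that drug's profile are
#' located (per-drug M = number matched, N = profile size), the signed KS
#' statistic is computed, and the statistics are rescaled into connectivity
#' scores S in \[-1, 1\] (P/Q scaling over the scored drugs of this database
#' only) and normalized scores in \[0, 1\]. Optionally a permutation
#' p-value is attached per drug. Drugs assaying none of the query kinases
#' are reported separately and never scored.
#'
#' @param reference A [rank_profiles()] result.
#' @param query A [parse_query()]/[expand_family()]/[expand_go()] result, or
#'   a plain character vector of kinase symbols.
#' @param permutations Number of permutation trials T per drug (default 500,
#'   the conventional choice); 0 disables p-values.
#' @param seed Integer master seed; each drug draws from a substream derived
#'   deterministically from `(seed, drug id)`, so p-values do not depend on
#'   drug iteration order.
#' @param pvalue_mode Exceedance rule, see [permutation_pvalue()].
#' @param keep_running_sums If `TRUE` (default), attach each scored drug's
#'   running-sum curve.
#' @return An object of class `connectivity_table`: list with
#'   \describe{
#'     \item{table}{data.frame, one row per scored drug, ordered by
#'       `normalized_score` descending (ties by ascending drug id):
#'       `rank`, `drug`, `n_matched`, `n_ref`, `a`, `b`, `ks`, `score`,
#'       `normalized_score`, `p_value` (NA when `permutations = 0`).}
#'     \item{unscored}{character vector of drugs with no matched query kinase.}
#'     \item{running_sums}{named list of numeric vectors (or `NULL`).}
#'     \item{query, assay_type, permutations, seed, pvalue_mode}{provenance.}
#'   }
#' @examples
#' m <- matrix(c(0.001, 0.002, 50, 60, 9, 0.004), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("dA", "dB", "dC"), c("MET", "ALK")))
#' ref <- rank_profiles(activity_matrix(m, "kd"))
#' connect_query(ref, "MET", permutations = 0)$table
#' @export
connect_query <- function(reference, query, permutations = 500L, seed = 1L,
                          pvalue_mode = c("two-sided-abs", "literal-one-sided"),
                          keep_running_sums = TRUE) {
  stopifnot(inherits(reference, "ranked_reference"))
  pvalue_mode <- match.arg(pvalue_mode)
  permutations <- as.integer(permutations)
  if (is.character(query))
    query <- parse_query(query, reference$kinases)
  stopifnot(inherits(query, "query_set"))

  qk <- query$kinases[query$kinases %in% reference$kinases]
  not_in_universe <- setdiff(query$kinases, reference$kinases)
  if (length(qk) == 0L)
    stop("query shares no kinase with the reference universe; query was: ",
         paste(query$kinases, collapse = ", "), call. = FALSE)

  drugs <- names(reference$profiles)
  per_drug <- lapply(reference$profiles, function(prof) {
    hits <- prof[names(prof) %in% qk]
    if (length(hits) == 0L) return(NULL)
    ks_statistic(unname(hits), length(prof))
  })
  scored <- !vapply(per_drug, is.null, logical(1))
  unscored <- drugs[!scored]
  if (!any(scored)) {
    warning("no drug assays any query kinase; returning an empty table",
            call. = FALSE)
    empty <- empty_connectivity_frame()
    return(new_connectivity_table(empty, unscored, NULL, query,
                                  reference$assay_type, permutations,
                                  seed, pvalue_mode))
  }

  res <- per_drug[scored]
  tab <- data.frame(
    drug = drugs[scored],
    n_matched = vapply(res, `[[`, integer(1), "n_matched"),
    n_ref = vapply(res, `[[`, integer(1), "n_ref"),
    a = vapply(res, `[[`, numeric(1), "a"),
    b = vapply(res, `[[`, numeric(1), "b"),
    ks = vapply(res, `[[`, numeric(1), "ks"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$score <- connectivity_scores(tab$ks)
  tab$normalized_score <- normalize_scores(tab$score)

  if (permutations > 0L) {
    tab$p_value <- mapply(function(d, n, m, ks0) {
      permutation_pvalue(n, m, ks0, trials = permutations,
                         seed = mix_seed(seed, d), mode = pvalue_mode)$p_value
    }, tab$drug, tab$n_ref, tab$n_matched, tab$ks)
  } else {
    tab$p_value <- NA_real_
  }

  ord <- order(-tab$normalized_score, tab$drug, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab <- tab[, c("rank", "drug", "n_matched", "n_ref", "a", "b", "ks",
                 "score", "normalized_score", "p_value")]

  rs <- NULL
  if (keep_running_sums) {
    rs <- lapply(res, function(x) running_sum(x$matched_query_ranks, x$n_ref))
    rs <- rs[tab$drug]
  }
  if (length(not_in_universe))
    query$unmatched_inputs <- union(query$unmatched_inputs, not_in_universe)

  new_connectivity_table(tab, unscored, rs, query, reference$assay_type,
                         permutations, seed, pvalue_mode)
}

empty_connectivity_frame <- function() {
  data.frame(rank = integer(0), drug = character(0), n_matched = integer(0),
             n_ref = integer(0), a = numeric(0), b = numeric(0),
             ks = numeric(0), score = numeric(0),
             normalized_score = numeric(0), p_value = numeric(0),
             stringsAsFactors = FALSE)
}

new_connectivity_table <- function(table, unscored, running_sums, query,
                                   assay_type, permutations, seed, mode) {
  structure(
    list(table = table, unscored = unscored, running_sums = running_sums,
         query = query, assay_type = assay_type,
         permutations = permutations, seed = as.integer(seed),
         pvalue_mode = mode),
    class = "connectivity_table"
  )
}

#' @export
print.connectivity_table <- function(x, n = 10L, ...) {
  cat(sprintf("connectivity_table (%s): %d scored drug(s), %d unscored\n",
              x$assay_type, nrow(x$table), length(x$unscored)))
  cat(sprintf("  query (%s): %s\n", x$query$provenance,
              paste(x$query$kinases, collapse = ", ")))
  if (x$permutations > 0L)
    cat(sprintf("  permutations: T = %d, seed = %d, mode = %s\n",
                x$permutations, x$seed, x$pvalue_mode))
  top <- utils::head(x$table, n)
  top$a <- NULL; top$b <- NULL
  print(format_scores(top), row.names = FALSE)
  if (nrow(x$table) > n) cat("  ...", nrow(x$table) - n, "more row(s)\n")
  invisible(x)
}

format_scores <- function(tab) {
  for (col in c("ks", "score", "normalized_score"))
    if (col %in% names(tab)) tab[[col]] <- sprintf("%.4f", tab[[col]])
  if ("p_value" %in% names(tab))
    tab$p_value <- ifelse(is.na(tab$p_value), "", sprintf("%.3f", tab$p_value))
  tab
}
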