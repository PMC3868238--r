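#' Convert activity profiles into rank-ordered reference profiles
#'
#' Each drug's assayed kinases are ranked 1..N_i, rank 1 being the most
#' potently hit kinase: the lowest Kd for a `"kd"` matrix, the highest
#' percent inhibition for an `"ic50"` matrix. Ties in the activity value are
#' broken by ascending (bytewise) kinase symbol so ranks are a deterministic
#' permutation of 1..N_i. Kinases not assayed for a drug carry no rank for
#' that drug; N_i is therefore per-drug. Drugs with zero assayed kinases are
#' dropped with a warning.
#'
#' @param matrix An [activity_matrix()].
#' @return An object of class `ranked_reference`: a list with `assay_type`,
#'   `kinases` (the global kinase universe), and `profiles`, a named list
#'   mapping each drug to an integer vector of ranks named by kinase symbol
#'   (sorted by rank; rank 1 first).
#' @examples
#' m <- matrix(c(0.001, 0.1, 10), nrow = 1,
#'             dimnames = list("d1", c("A", "B", "C")))
#' rank_profiles(activity_matrix(m, "kd"))$profiles$d1
#' @export
rank_profiles <- function(matrix) {
  stopifnot(inherits(matrix, "activity_matrix"))
  v <- matrix$values
  # orient so that smaller = more potent, then rank ascending
  key <- if (matrix$assay_type == "kd") v else -v

  profiles <- lapply(seq_len(nrow(key)), function(i) {
    row <- key[i, ]
    assayed <- which(!is.na(row))
    if (length(assayed) == 0L) return(NULL)
    syms <- matrix$kinases[assayed]
    ord <- order(row[assayed], syms, method = "radix")
    ranks <- seq_along(ord)
    names(ranks) <- syms[ord]
    ranks
  })
  names(profiles) <- matrix$drugs

  empty <- vapply(profiles, is.null, logical(1))
  if (any(empty)) {
    warning("dropping ", sum(empty), " drug(s) with no assayed kinases: ",
            paste(matrix$drugs[empty], collapse = ", "), call. = FALSE)
    profiles <- profiles[!empty]
  }
  if (length(profiles) == 0L)
    stop("no drug has any assayed kinase", call. = FALSE)

  structure(
    list(assay_type = matrix$assay_type,
         kinases = matrix$kinases,
         profiles = profiles),
    class = "ranked_reference"
  )
}

#' @export
print.ranked_reference <- function(x, ...) {
  ns <- lengths(x$profiles)
  cat(sprintf("ranked_reference (%s): %d drugs, %d kinases in universe\n",
              x$assay_type, length(x$profiles), length(x$kinases)))
  cat(sprintf("  kinases per drug: %d-%d (median %d)\n",
              min(ns), max(ns), as.integer(stats::median(ns))))
  invisible(x)
}

#' Flatten a ranked reference into a long table
#'
#' @param reference A `ranked_reference`.
#' @return A data.frame with columns `drug`, `kinase`, `rank` (rank 1 = most
#'   potent), one row per assayed (drug, kinase) pair.
#' @export
ranked_reference_table <- function(reference) {
  stopifnot(inherits(reference, "ranked_reference"))
  data.frame(
    drug = rep(names(reference$profiles), lengths(reference$profiles)),
    kinase = unlist(lapply(reference$profiles, names), use.names = FALSE),
    rank = unlist(reference$profiles, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
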