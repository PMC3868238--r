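# atomic write: assemble in a sibling temp file, then rename into place
write_atomically <- function(path, writer) {
  tmp <- tempfile(pattern = ".kinconn", tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move output into place at ", path, call. = FALSE)
  invisible(path)
}

#' Write a connectivity table as TSV
#'
#' Writes the ranked table with a `#`-prefixed provenance header (package
#' version, assay type, query, permutation count, seed, sidedness rule, and
#' optional input-file MD5 digests). Scores are printed with 4 decimals and
#' p-values with 3, so identical runs produce byte-identical files; use
#' [write_connectivity_json()] for full precision and running sums. Output
#' is written atomically (no partial file on error). Drugs with no matched
#' query kinase are listed in trailing comment lines.
#'
#' @param result A [connect_query()] result.
#' @param path Output file path.
#' @param input_digests Optional named character vector of file digests to
#'   record in the header (e.g. from [tools::md5sum()]).
#' @return `path`, invisibly.
#' @export
write_connectivity_tsv <- function(result, path, input_digests = NULL) {
  stopifnot(inherits(result, "connectivity_table"))
  header <- c(
    sprintf("# kinconn %s", as.character(utils::packageVersion("kinconn"))),
    sprintf("# assay_type: %s", result$assay_type),
    sprintf("# query (%s): %s", result$query$provenance,
            paste(result$query$kinases, collapse = ",")),
    if (length(result$query$unmatched_inputs))
      sprintf("# unmatched query tokens: %s",
              paste(result$query$unmatched_inputs, collapse = ",")),
    sprintf("# permutations: %d", result$permutations),
    sprintf("# seed: %d", result$seed),
    sprintf("# pvalue_mode: %s", result$pvalue_mode),
    if (!is.null(input_digests))
      sprintf("# input %s: md5=%s", names(input_digests), input_digests)
  )
  tab <- result$table[, c("rank", "drug", "n_matched", "n_ref", "ks",
                          "score", "normalized_score", "p_value")]
  tab <- format_scores(tab)
  write_atomically(path, function(tmp) {
    con <- file(tmp, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(paste(names(tab), collapse = "\t"), con)
    if (nrow(tab))
      writeLines(do.call(paste, c(unname(tab), sep = "\t")), con)
    if (length(result$unscored))
      writeLines(sprintf("# unscored (no query kinase assayed): %s",
                         paste(result$unscored, collapse = ",")), con)
  })
}

#' Write a connectivity table as JSON
#'
#' Full-precision export including the per-drug running-sum curves (when
#' kept), the unscored drug list, and the run provenance.
#'
#' @inheritParams write_connectivity_tsv
#' @return `path`, invisibly.
#' @export
write_connectivity_json <- function(result, path) {
  stopifnot(inherits(result, "connectivity_table"))
  payload <- list(
    tool = "kinconn",
    version = as.character(utils::packageVersion("kinconn")),
    assay_type = result$assay_type,
    query = list(kinases = result$query$kinases,
                 provenance = result$query$provenance,
                 selection = result$query$selection,
                 unmatched_inputs = result$query$unmatched_inputs),
    permutations = result$permutations,
    seed = result$seed,
    pvalue_mode = result$pvalue_mode,
    table = result$table,
    unscored = result$unscored,
    running_sums = result$running_sums
  )
  write_atomically(path, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  })
}

#' Write an activity matrix as a long-format TSV
#'
#' Emits the three-column (drug, kinase, value) layout accepted by
#' [load_activity_matrix()] with `layout = "long"`; missing cells are
#' omitted.
#'
#' @param matrix An [activity_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_activity_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "activity_matrix"))
  v <- matrix$values
  idx <- which(!is.na(v), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  lines <- sprintf("%s\t%s\t%.10g",
                   matrix$drugs[idx[, 1]], matrix$kinases[idx[, 2]],
                   v[idx])
  write_atomically(path, function(tmp) {
    con <- file(tmp, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(sprintf("# kinconn simulated matrix (%s)", matrix$assay_type), con)
    writeLines("drug\tkinase\tvalue", con)
    writeLines(lines, con)
  })
}
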