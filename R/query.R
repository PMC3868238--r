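#' Build a query set from directly entered kinase symbols
#'
#' Tokens are whitespace-trimmed, uppercased and deduplicated, then split
#' into those found in the reference kinase universe (which will be scored)
#' and those not found (preserved for reporting, never silently dropped).
#'
#' @param tokens Character vector of kinase symbols (any case).
#' @param universe Character vector of reference kinase symbols, e.g.
#'   `ranked_reference$kinases`.
#' @return An object of class `query_set`: list with `kinases` (matched,
#'   uppercased), `provenance` (`"direct"`), `selection` (`NA`),
#'   `unmatched_inputs`.
#' @examples
#' parse_query(c("met", " MET ", "ALK"), universe = c("MET", "ALK", "KIT"))
#' @export
parse_query <- function(tokens, universe) {
  if (length(tokens) == 0L)
    stop("empty query", call. = FALSE)
  norm <- unique(normalize_symbols(tokens))
  norm <- norm[nzchar(norm)]
  if (length(norm) == 0L)
    stop("query contains no non-empty tokens", call. = FALSE)
  uni <- normalize_symbols(universe)
  matched <- norm[norm %in% uni]
  unmatched <- norm[!norm %in% uni]
  if (length(matched) == 0L)
    stop("no query kinase found in the reference universe; unmatched: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  new_query_set(matched, "direct", NA_character_, unmatched)
}

new_query_set <- function(kinases, provenance, selection, unmatched) {
  structure(
    list(kinases = kinases, provenance = provenance,
         selection = selection, unmatched_inputs = unmatched),
    class = "query_set"
  )
}

#' @export
print.query_set <- function(x, ...) {
  sel <- if (is.na(x$selection)) "" else sprintf(" [%s]", x$selection)
  cat(sprintf("query_set (%s%s): %d kinase(s)\n", x$provenance, sel,
              length(x$kinases)))
  cat(" ", paste(x$kinases, collapse = ", "), "\n")
  if (length(x$unmatched_inputs))
    cat("  unmatched inputs:", paste(x$unmatched_inputs, collapse = ", "), "\n")
  invisible(x)
}

#' Read kinase annotation maps from TSV
#'
#' `read_family_map()` expects two columns (kinase, family); each kinase may
#' belong to exactly one family (the conventional grouping of the human
#' kinome into conserved catalytic-domain families, or any user taxonomy).
#' `read_go_map()` expects three columns (kinase, go_id, go_name); a kinase
#' may carry many GO terms. Headers are required; `#` comment lines skipped.
#'
#' @param path Path to a TSV file.
#' @return An object of class `annotation_map`: list with `family` and/or
#'   `go` data.frames (kinase symbols uppercased).
#' @name annotation_maps
#' @export
read_family_map <- function(path) {
  tab <- read_map_tsv(path, 2L, c("kinase", "family"))
  tab$kinase <- normalize_symbols(tab$kinase)
  tab$family <- trimws(tab$family)
  tab <- unique(tab)
  dup <- duplicated(tab$kinase)
  if (any(dup))
    stop("kinase(s) mapped to more than one family: ",
         paste(unique(tab$kinase[dup]), collapse = ", "), call. = FALSE)
  structure(list(family = tab, go = NULL), class = "annotation_map")
}

#' @rdname annotation_maps
#' @export
read_go_map <- function(path) {
  tab <- read_map_tsv(path, 3L, c("kinase", "go_id", "go_name"))
  tab$kinase <- normalize_symbols(tab$kinase)
  tab$go_id <- trimws(tab$go_id)
  tab$go_name <- trimws(tab$go_name)
  structure(list(family = NULL, go = unique(tab)), class = "annotation_map")
}

read_map_tsv <- function(path, ncols, colnames) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           quote = "\"", fileEncoding = "UTF-8")
  if (ncol(tab) != ncols)
    stop(basename(path), ": expected ", ncols, " columns (",
         paste(colnames, collapse = ", "), "), got ", ncol(tab), call. = FALSE)
  names(tab) <- colnames
  tab
}

#' Merge annotation maps
#'
#' Combines a family map and a GO map into one `annotation_map`.
#' @param family,go `annotation_map` objects (or `NULL`).
#' @return An `annotation_map` carrying both tables.
#' @export
combine_annotation_maps <- function(family = NULL, go = NULL) {
  structure(
    list(family = if (!is.null(family)) family$family,
         go = if (!is.null(go)) go$go),
    class = "annotation_map"
  )
}

#' Expand a kinase-family selection into a query set
#'
#' @param family Family name (case-insensitive).
#' @param map An `annotation_map` with a family table
#'   (see [read_family_map()]).
#' @return A `query_set` with provenance `"family"` containing every kinase
#'   annotated to that family.
#' @export
expand_family <- function(family, map) {
  stopifnot(inherits(map, "annotation_map"))
  if (is.null(map$family))
    stop("annotation map has no kinase-family table", call. = FALSE)
  fams <- unique(map$family$family)
  hit <- fams[tolower(fams) == tolower(trimws(family))]
  if (length(hit) == 0L)
    stop("unknown kinase family '", family, "'; available: ",
         paste(sort(fams), collapse = ", "), call. = FALSE)
  kin <- sort(unique(map$family$kinase[map$family$family == hit[1]]))
  new_query_set(kin, "family", hit[1], character(0))
}

#' Expand a Gene Ontology term into a query set
#'
#' `term` may be a GO identifier (`GO:nnnnnnn`, matched case-insensitively
#' and exactly) or a substring of a term name (case-insensitive; must
#' resolve to exactly one term id, otherwise the candidates are listed).
#' A term's kinase set is exactly its listed kinases; no ontology-graph
#' propagation is performed.
#'
#' @param term GO id or name substring.
#' @param map An `annotation_map` with a GO table (see [read_go_map()]).
#' @return A `query_set` with provenance `"go"`.
#' @export
expand_go <- function(term, map) {
  stopifnot(inherits(map, "annotation_map"))
  if (is.null(map$go))
    stop("annotation map has no GO table", call. = FALSE)
  go <- map$go
  term <- trimws(term)
  if (grepl("^go:", term, ignore.case = TRUE)) {
    ids <- unique(go$go_id[tolower(go$go_id) == tolower(term)])
    if (length(ids) == 0L)
      stop("GO id '", term, "' not found in the annotation map", call. = FALSE)
  } else {
    cand <- unique(go[grepl(term, go$go_name, ignore.case = TRUE),
                      c("go_id", "go_name")])
    if (nrow(cand) == 0L)
      stop("no GO term name matches '", term, "'", call. = FALSE)
    if (nrow(cand) > 1L)
      stop("ambiguous GO term '", term, "'; candidates: ",
           paste(sprintf("%s (%s)", cand$go_id, cand$go_name), collapse = "; "),
           call. = FALSE)
    ids <- cand$go_id
  }
  sel <- go$go_id == ids[1]
  label <- sprintf("%s (%s)", ids[1], go$go_name[sel][1])
  kin <- sort(unique(go$kinase[sel]))
  new_query_set(kin, "go", label, character(0))
}
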