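#' Assemble and validate a full run configuration
#'
#' Bundles everything one end-to-end run needs: the reference matrix file
#' and how to parse it, the query source (exactly one of direct tokens, a
#' query file, a family, or a GO term), permutation settings, and output
#' paths. All paths and mutual-exclusion rules are checked here, before any
#' computation.
#'
#' @param reference Path to the activity-matrix file.
#' @param assay_type,layout,delimiter,na_token Passed to
#'   [load_activity_matrix()].
#' @param query Character vector of kinase symbols (direct entry).
#' @param query_file Path to a text file, one kinase symbol per line.
#' @param family Kinase-family name (requires `family_map`).
#' @param go GO id or name substring (requires `go_map`).
#' @param family_map,go_map Paths to annotation TSVs
#'   (see [read_family_map()], [read_go_map()]).
#' @param permutations,seed,pvalue_mode Passed to [connect_query()].
#' @param out_tsv Output TSV path (required).
#' @param out_json Optional output JSON path (includes running sums).
#' @return A validated `run_config` list.
#' @export
run_config <- function(reference, assay_type = c("ic50", "kd"),
                       layout = c("wide", "long"), delimiter = NULL,
                       na_token = "NA",
                       query = NULL, query_file = NULL,
                       family = NULL, go = NULL,
                       family_map = NULL, go_map = NULL,
                       permutations = 500L, seed = 1L,
                       pvalue_mode = c("two-sided-abs", "literal-one-sided"),
                       out_tsv, out_json = NULL) {
  assay_type <- match.arg(assay_type)
  layout <- match.arg(layout)
  pvalue_mode <- match.arg(pvalue_mode)
  if (!file.exists(reference))
    stop("reference file not found: ", reference, call. = FALSE)
  sources <- c(direct = !is.null(query), file = !is.null(query_file),
               family = !is.null(family), go = !is.null(go))
  if (sum(sources) != 1L)
    stop("exactly one query source required (query / query_file / family / go); got ",
         sum(sources), call. = FALSE)
  if (!is.null(family) && is.null(family_map))
    stop("'family' query requires 'family_map'", call. = FALSE)
  if (!is.null(go) && is.null(go_map))
    stop("'go' query requires 'go_map'", call. = FALSE)
  if (!is.null(query_file) && !file.exists(query_file))
    stop("query file not found: ", query_file, call. = FALSE)
  if (missing(out_tsv))
    stop("'out_tsv' is required", call. = FALSE)
  structure(
    list(reference = reference, assay_type = assay_type, layout = layout,
         delimiter = delimiter, na_token = na_token,
         query = query, query_file = query_file, family = family, go = go,
         family_map = family_map, go_map = go_map,
         permutations = as.integer(permutations), seed = as.integer(seed),
         pvalue_mode = pvalue_mode, out_tsv = out_tsv, out_json = out_json),
    class = "run_config"
  )
}

#' Run the full load / rank / query / connect / write pipeline
#'
#' Loads the reference matrix, ranks it, resolves the configured query,
#' scores every drug with permutation p-values, and writes the ranked TSV
#' (and optional JSON). Given the same config and seed the TSV output is
#' byte-identical across runs. Outputs are written atomically, so a failed
#' run leaves no partial files.
#'
#' @param config A [run_config()].
#' @return The [connect_query()] result, invisibly.
#' @export
run_connect <- function(config) {
  stopifnot(inherits(config, "run_config"))
  am <- load_activity_matrix(config$reference, config$assay_type,
                             config$layout, config$delimiter,
                             config$na_token)
  ref <- rank_profiles(am)

  digests <- c(reference = unname(tools::md5sum(config$reference)))
  if (!is.null(config$query)) {
    qs <- parse_query(config$query, ref$kinases)
  } else if (!is.null(config$query_file)) {
    tokens <- readLines(config$query_file, encoding = "UTF-8", warn = FALSE)
    tokens <- tokens[!grepl("^\\s*(#|$)", tokens)]
    qs <- parse_query(tokens, ref$kinases)
    digests <- c(digests, query_file = unname(tools::md5sum(config$query_file)))
  } else if (!is.null(config$family)) {
    qs <- expand_family(config$family, read_family_map(config$family_map))
    digests <- c(digests, family_map = unname(tools::md5sum(config$family_map)))
  } else {
    qs <- expand_go(config$go, read_go_map(config$go_map))
    digests <- c(digests, go_map = unname(tools::md5sum(config$go_map)))
  }

  res <- connect_query(ref, qs, permutations = config$permutations,
                       seed = config$seed, pvalue_mode = config$pvalue_mode)
  write_connectivity_tsv(res, config$out_tsv, input_digests = digests)
  if (!is.null(config$out_json))
    write_connectivity_json(res, config$out_json)
  invisible(res)
}
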