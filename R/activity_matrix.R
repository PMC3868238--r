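#' Construct a drug-by-kinase activity matrix
#'
#' An `activity_matrix` holds raw quantitative kinase-inhibitor measurements:
#' either percent kinase inhibition (assay type `"ic50"`, values in
#' \[0, 100\]) or dissociation constants Kd in micromolar (assay type `"kd"`,
#' strictly positive). Missing cells (`NA`) mark kinases not assayed for a
#' drug. Kinase symbols are uppercased and whitespace-trimmed; drug and
#' kinase identifiers must be unique after normalization.
#'
#' @param values Numeric matrix, drugs in rows, kinases in columns, with
#'   dimnames. `NA` entries mark unassayed (drug, kinase) pairs.
#' @param assay_type `"ic50"` (percent inhibition) or `"kd"` (Kd, micromolar).
#' @return An object of class `activity_matrix`: a list with elements
#'   `values`, `assay_type`, `drugs`, `kinases`.
#' @examples
#' m <- matrix(c(0.001, 0.5, 10, 0.2), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("d1", "d2"), c("ABL1", "KIT")))
#' am <- activity_matrix(m, "kd")
#' am$kinases
#' @export
activity_matrix <- function(values, assay_type = c("ic50", "kd")) {
  assay_type <- match.arg(assay_type)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have drug rownames and kinase colnames", call. = FALSE)

  drugs <- trimws(rownames(values))
  kinases <- normalize_symbols(colnames(values))
  if (anyDuplicated(drugs))
    stop("duplicate drug identifiers: ",
         paste(unique(drugs[duplicated(drugs)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(kinases))
    stop("duplicate kinase symbols after uppercasing: ",
         paste(unique(kinases[duplicated(kinases)]), collapse = ", "), call. = FALSE)
  rownames(values) <- drugs
  colnames(values) <- kinases

  validate_activity_values(values, assay_type)

  structure(
    list(values = values, assay_type = assay_type,
         drugs = drugs, kinases = kinases),
    class = "activity_matrix"
  )
}

# range checks; NA = not assayed, always allowed
validate_activity_values <- function(values, assay_type) {
  v <- values[!is.na(values)]
  if (assay_type == "ic50") {
    bad <- v < 0 | v > 100
    if (any(bad))
      stop("ic50 (percent inhibition) values must lie in [0, 100]; found ",
           paste(utils::head(signif(v[bad], 4), 5), collapse = ", "),
           call. = FALSE)
  } else {
    bad <- v <= 0
    if (any(bad))
      stop("kd values must be strictly positive (micromolar); found ",
           paste(utils::head(signif(v[bad], 4), 5), collapse = ", "),
           call. = FALSE)
  }
  invisible(TRUE)
}

normalize_symbols <- function(x) toupper(trimws(x))

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("activity_matrix: %d drugs x %d kinases (%s)\n",
              length(x$drugs), length(x$kinases), x$assay_type))
  n_na <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.1f%%)\n",
              n_na, 100 * n_na / length(x$values)))
  invisible(x)
}

#' Load an activity matrix from a delimited text file
#'
#' Reads a drug-by-kinase activity table in either wide layout (first column
#' = drug identifier, remaining column headers = kinase symbols) or long
#' layout (three columns: drug, kinase, value). Lines starting with `#` are
#' skipped; empty cells or the `na_token` string are treated as missing.
#' Values are range-checked according to `assay_type` (see
#' [activity_matrix()]).
#'
#' @param path Path to a UTF-8 TSV or CSV file.
#' @param assay_type `"ic50"` or `"kd"`.
#' @param layout `"wide"` or `"long"`; never sniffed.
#' @param delimiter Field delimiter; default chosen from the file extension
#'   (`,` for `.csv`, tab otherwise).
#' @param na_token String marking a missing value (besides an empty cell).
#' @return An [activity_matrix()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("drug\tkinase\tvalue", "d1\tabl1\t0.001", "d1\tkit\t0.5"), tf)
#' load_activity_matrix(tf, assay_type = "kd", layout = "long")
#' @export
load_activity_matrix <- function(path, assay_type = c("ic50", "kd"),
                                 layout = c("wide", "long"),
                                 delimiter = NULL, na_token = "NA") {
  assay_type <- match.arg(assay_type)
  layout <- match.arg(layout)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           comment.char = "#", na.strings = c("", na_token),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", fileEncoding = "UTF-8")
  if (layout == "long") {
    if (ncol(tab) != 3L)
      stop("long layout requires exactly 3 columns (drug, kinase, value), got ",
           ncol(tab), call. = FALSE)
    names(tab) <- c("drug", "kinase", "value")
    tab$drug <- trimws(as.character(tab$drug))
    tab$kinase <- normalize_symbols(as.character(tab$kinase))
    if (!is.numeric(tab$value)) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab$value))) & !is.na(tab$value))
      if (length(bad))
        stop("non-numeric value at data row ", bad[1], ": '",
             tab$value[bad[1]], "'", call. = FALSE)
      tab$value <- as.numeric(tab$value)
    }
    dup <- duplicated(tab[c("drug", "kinase")])
    if (any(dup))
      stop("duplicate (drug, kinase) cell at data row ", which(dup)[1], ": ",
           tab$drug[which(dup)[1]], " / ", tab$kinase[which(dup)[1]],
           call. = FALSE)
    drugs <- unique(tab$drug)
    kinases <- sort(unique(tab$kinase))
    values <- matrix(NA_real_, length(drugs), length(kinases),
                     dimnames = list(drugs, kinases))
    values[cbind(match(tab$drug, drugs), match(tab$kinase, kinases))] <- tab$value
  } else {
    if (ncol(tab) < 2L)
      stop("wide layout requires a drug column plus >= 1 kinase column",
           call. = FALSE)
    drugs <- trimws(as.character(tab[[1]]))
    values <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(values) <- "double"
    rownames(values) <- drugs
  }
  activity_matrix(values, assay_type)
}
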