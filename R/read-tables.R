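# Flat-file readers for the TSV dialects the package consumes. All files are
# UTF-8 tab-separated with a header row; lines starting with '#' are comments;
# multi-valued cells use a configurable delimiter (default ';').

#' Read a reaction table
#'
#' Reads a gene-protein-reaction table: one row per enzymatic reaction with
#' the catalysing gene symbols, the major substrate and product metabolites,
#' a reversibility flag and optional pathway annotations. Multi-valued cells
#' (genes, substrates, products, pathways) are split on `multi_delim` and
#' whitespace-trimmed; empty tokens are dropped.
#'
#' @param path Path to a TSV file with columns `reaction_id`, `genes`,
#'   `substrates`, `products`, `reversible`, `pathways`. `'#'`-prefixed lines
#'   are ignored.
#' @param multi_delim Delimiter separating values inside a multi-valued cell.
#' @return A tibble with one row per reaction; `genes`, `substrates`,
#'   `products` and `pathways` are list-columns of character vectors,
#'   `reversible` is logical.
#' @examples
#' path <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "reaction_id\tgenes\tsubstrates\tproducts\treversible\tpathways",
#'   "R1\tgeneA\tA\tB\tfalse\tP1",
#'   "R2\tgeneB;geneC\tB\tC\ttrue\t"
#' ), path)
#' read_reaction_table(path)
#' @export
read_reaction_table <- function(path, multi_delim = ";") {
  if (!file.exists(path)) {
    stop("reaction table not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("reaction_id", "genes", "substrates", "products",
                "reversible", "pathways")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("reaction table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  reaction_id <- trimws(raw$reaction_id)
  if (anyNA(reaction_id) || any(!nzchar(reaction_id))) {
    stop("reaction table contains empty reaction_id values", call. = FALSE)
  }
  dup <- unique(reaction_id[duplicated(reaction_id)])
  if (length(dup) > 0) {
    stop("duplicate reaction_id values: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  records <- tibble::tibble(
    reaction_id = reaction_id,
    genes = split_multi(raw$genes, multi_delim),
    substrates = split_multi(raw$substrates, multi_delim),
    products = split_multi(raw$products, multi_delim),
    reversible = parse_flag(raw$reversible),
    pathways = split_multi(raw$pathways, multi_delim)
  )
  validate_reaction_records(records)
  records
}

split_multi <- function(x, delim) {
  purrr::map(x, function(cell) {
    if (is.na(cell)) return(character(0))
    tokens <- trimws(strsplit(cell, delim, fixed = TRUE)[[1]])
    unique(tokens[nzchar(tokens)])
  })
}

parse_flag <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes", "y")] <- TRUE
  out[x %in% c("0", "false", "f", "no", "n")] <- FALSE
  if (anyNA(out)) {
    stop("unparseable 'reversible' value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

validate_reaction_records <- function(records) {
  no_gene <- lengths(records$genes) == 0
  if (any(no_gene)) {
    stop("reaction(s) with no gene symbol: ",
         paste(records$reaction_id[no_gene], collapse = ", "), call. = FALSE)
  }
  no_met <- lengths(records$substrates) + lengths(records$products) == 0
  if (any(no_met)) {
    stop("reaction(s) with neither substrates nor products: ",
         paste(records$reaction_id[no_met], collapse = ", "), call. = FALSE)
  }
  invisible(records)
}

#' Read a circadian phase table
#'
#' @param path Path to a TSV file with columns `gene` and `phase_h` (peak time
#'   in hours on `[0, 24)`). `'#'`-prefixed lines are ignored.
#' @return A tibble with columns `gene` (character) and `phase_h` (double).
#' @export
read_phase_table <- function(path) {
  if (!file.exists(path)) {
    stop("phase table not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(c("gene", "phase_h"), names(raw))
  if (length(missing_cols) > 0) {
    stop("phase table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  phases <- tibble::tibble(
    gene = trimws(raw$gene),
    phase_h = suppressWarnings(as.numeric(raw$phase_h))
  )
  if (anyNA(phases$phase_h) || any(!is.finite(phases$phase_h))) {
    stop("phase table contains non-numeric phase_h values", call. = FALSE)
  }
  if (any(phases$phase_h < 0 | phases$phase_h >= 24)) {
    stop("phase_h values must lie in [0, 24)", call. = FALSE)
  }
  dup <- unique(phases$gene[duplicated(phases$gene)])
  if (length(dup) > 0) {
    stop("duplicate gene symbols in phase table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  phases
}

#' Read an expression or metabolite intensity matrix
#'
#' @param path TSV file whose first column (`feature`) names the measured
#'   features; the remaining columns are samples.
#' @return A tibble with a `feature` column and one numeric column per sample.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) {
    stop("expression matrix not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         col_types = readr::cols())
  if (ncol(raw) < 2) {
    stop("expression matrix needs a feature column plus >= 1 sample column",
         call. = FALSE)
  }
  names(raw)[1] <- "feature"
  raw$feature <- as.character(raw$feature)
  value_cols <- names(raw)[-1]
  bad <- value_cols[!vapply(raw[value_cols], is.numeric, logical(1))]
  if (length(bad) > 0) {
    stop("non-numeric sample column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  raw
}

#' Read a sample sheet
#'
#' @param path TSV file with columns `sample`, `timepoint_h`, `condition`,
#'   `replicate`.
#' @return A tibble with those four columns.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) {
    stop("sample sheet not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(c("sample", "timepoint_h", "condition", "replicate"),
                          names(raw))
  if (length(missing_cols) > 0) {
    stop("sample sheet is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    sample = trimws(raw$sample),
    timepoint_h = as.numeric(raw$timepoint_h),
    condition = trimws(raw$condition),
    replicate = as.integer(raw$replicate)
  )
}

#' Write a reaction table in the dialect read by [read_reaction_table()]
#'
#' @param records Reaction tibble as produced by [read_reaction_table()] or
#'   [simulate_reaction_network()].
#' @param path Output TSV path.
#' @param multi_delim Delimiter joining multi-valued cells.
#' @return `path`, invisibly.
#' @export
write_reaction_table <- function(records, path, multi_delim = ";") {
  collapse <- function(col) {
    vapply(col, paste, character(1), collapse = multi_delim)
  }
  out <- tibble::tibble(
    reaction_id = records$reaction_id,
    genes = collapse(records$genes),
    substrates = collapse(records$substrates),
    products = collapse(records$products),
    reversible = ifelse(records$reversible, "true", "false"),
    pathways = collapse(records$pathways)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
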