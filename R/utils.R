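# ID normalisation used for all cross-table matching.

#' Normalise gene identifiers
#'
#' Uppercases and strips surrounding whitespace. Matching between the
#' expression screen, methylation screen, interaction tables and gene-set
#' collections is by exact symbol after this normalisation; no alias
#' resolution is attempted.
#'
#' @param x Character vector of gene symbols.
#' @return Normalised character vector.
#' @export
norm_gene_id <- function(x) toupper(trimws(as.character(x)))

#' Normalise miRNA identifiers
#'
#' Lowercases, strips surrounding whitespace and the species prefix
#' `"hsa-"`. Arm suffixes (`-5p`/`-3p`) are kept distinct, so
#' `"hsa-miR-30a-5p"` and `"miR-30a"` remain different identifiers while
#' `"hsa-miR-30a"` and `"miR-30a"` match.
#'
#' @param x Character vector of miRNA identifiers.
#' @return Normalised character vector.
#' @export
norm_mirna_id <- function(x) {
  x <- tolower(trimws(as.character(x)))
  sub("^hsa-", "", x)
}

# Stop unless `cond`; message names the violated requirement.
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

# First column of a feature x sample data frame is the feature ID; the
# rest are numeric sample columns. Returns a base matrix with rownames.
as_feature_matrix <- function(df, id_col = 1L) {
  df <- as.data.frame(df)
  ids <- as.character(df[[id_col]])
  m <- as.matrix(df[, -id_col, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}
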