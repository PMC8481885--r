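# Readers and writers for every file the pipeline touches. All tabular
# formats are TSV; matrices carry the feature ID in the first column and
# one column per sample.

#' Read a feature x sample matrix from TSV
#'
#' @param path TSV with a header row of sample IDs; first column is the
#'   feature identifier.
#' @return Tibble, first column the feature ID.
#' @export
read_labeled_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a feature x sample matrix to TSV
#' @param mat Tibble (first column feature ID) or matrix with rownames.
#' @param path Output path.
#' @export
write_labeled_matrix <- function(mat, path) {
  if (is.matrix(mat)) {
    mat <- as_tibble(mat, rownames = "feature_id")
  }
  readr::write_tsv(mat, path, progress = FALSE)
}

#' Read a sample-to-group table
#' @param path Two-column TSV `sample_id`, `group`.
#' @return Tibble.
#' @export
read_groups <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_that(all(c("sample_id", "group") %in% names(g)),
             "groups file needs columns sample_id and group")
  g
}

#' Read a two-column interaction edge list
#'
#' @param path TSV with a header naming the two endpoint columns.
#' @param type Declared edge type, one of `"mrna-mirna"`,
#'   `"mirna-lncrna"`, `"ppi"`; sets the expected column names on the
#'   returned tibble.
#' @return Edge tibble with no duplicate rows and no self-edges.
#' @export
read_interaction_table <- function(path,
                                   type = c("mrna-mirna", "mirna-lncrna",
                                            "ppi")) {
  type <- match.arg(type)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_that(ncol(tbl) >= 2, "interaction table needs two columns")
  tbl <- tbl[, 1:2]
  names(tbl) <- switch(type,
                       "mrna-mirna" = c("mrna", "mirna"),
                       "mirna-lncrna" = c("mirna", "lncrna"),
                       "ppi" = c("protein_a", "protein_b"))
  tbl <- distinct(tbl)
  tbl[tbl[[1]] != tbl[[2]], , drop = FALSE]
}

#' Read a curated miRNA list (one ID per line)
#' @param path Plain-text file.
#' @return Character vector (raw IDs; normalisation happens at match
#'   time).
#' @export
read_curated_mirnas <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Write a simulated study to disk
#'
#' Writes every component of a [simulate_cerna_study()] result in the
#' formats the pipeline's own readers consume: matrices and edge lists
#' as TSV, the curated miRNA list as plain text, ground truth as JSON.
#'
#' @param study A `"cerna_study"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cerna_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    lnc_expression = file.path(dir, "lnc_expression.tsv"),
    groups = file.path(dir, "groups.tsv"),
    mrna_mirna = file.path(dir, "mrna_mirna.tsv"),
    mirna_lncrna = file.path(dir, "mirna_lncrna.tsv"),
    curated_mirnas = file.path(dir, "curated_mirnas.txt"),
    truth = file.path(dir, "ground_truth.json"))
  readr::write_tsv(study$expression, paths[["expression"]], progress = FALSE)
  readr::write_tsv(study$methylation, paths[["methylation"]], progress = FALSE)
  readr::write_tsv(study$lnc_expression, paths[["lnc_expression"]],
                   progress = FALSE)
  readr::write_tsv(study$groups, paths[["groups"]], progress = FALSE)
  readr::write_tsv(study$mrna_mirna, paths[["mrna_mirna"]], progress = FALSE)
  readr::write_tsv(study$mirna_lncrna, paths[["mirna_lncrna"]],
                   progress = FALSE)
  writeLines(study$curated_mirnas, paths[["curated_mirnas"]])
  truth <- study$truth
  truth$true_triples <- as.data.frame(truth$true_triples)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = FALSE,
                       digits = NA)
  invisible(paths)
}

#' Read a simulated study back from disk
#' @param dir Directory written by [write_cerna_study()].
#' @return A `"cerna_study"`-shaped list (without `config`).
#' @export
read_cerna_study <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  truth$true_triples <- as_tibble(truth$true_triples)
  structure(list(
    expression = read_labeled_matrix(file.path(dir, "expression.tsv")),
    methylation = read_labeled_matrix(file.path(dir, "methylation.tsv")),
    lnc_expression = read_labeled_matrix(file.path(dir, "lnc_expression.tsv")),
    groups = read_groups(file.path(dir, "groups.tsv")),
    mrna_mirna = read_interaction_table(file.path(dir, "mrna_mirna.tsv"),
                                        "mrna-mirna"),
    mirna_lncrna = read_interaction_table(file.path(dir, "mirna_lncrna.tsv"),
                                          "mirna-lncrna"),
    curated_mirnas = read_curated_mirnas(file.path(dir, "curated_mirnas.txt")),
    truth = truth), class = "cerna_study")
}

#' Export a network in SIF format
#'
#' One line per edge: `source <TAB> interaction-type <TAB> target`, the
#' interaction type being `mrna-mirna` or `mirna-lncrna`.
#'
#' @param net A `"cerna_network"`.
#' @param path Output `.sif` path.
#' @export
write_sif <- function(net, path) {
  type_of <- setNames(net$nodes$type, net$nodes$node)
  rel <- paste(type_of[net$edges$from], type_of[net$edges$to], sep = "-")
  writeLines(paste(net$edges$from, rel, net$edges$to, sep = "\t"), path)
}

#' Export a network in GraphML format
#'
#' Nodes carry a `type` attribute in `{mrna, mirna, lncrna}`.
#'
#' @param net A `"cerna_network"`.
#' @param path Output `.graphml` path.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
}
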