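#' Read a GMT gene-set collection
#'
#' Standard tab-delimited GMT: set name, description, then member gene
#' IDs. The description field is kept as the set's category label
#' (e.g. BP/CC/MF/pathway), which is why this reader retains it rather
#' than discarding it as most GMT loaders do.
#'
#' @param path Path to a `.gmt` file.
#' @return Tibble with columns `term`, `category` and a `genes` list
#'   column of normalised gene IDs.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) abort("GMT lines must have a name, description and >= 1 gene")
  out <- tibble(
    term = vapply(parts, `[[`, character(1), 1),
    category = vapply(parts, `[[`, character(1), 2),
    genes = lapply(parts, function(p) unique(norm_gene_id(p[-(1:2)]))))
  check_that(!anyDuplicated(out$term), "duplicate set names in GMT")
  out
}

#' Hypergeometric over-representation analysis
#'
#' Scores a query gene list against each set of a collection with the
#' same cumulative hypergeometric core used for ceRNA pair testing
#' (upper tail, `P(X >= overlap)`), with universe `N = |background|`,
#' draw `n = |query|` and `m` the set's size within the background. Plain
#' hypergeometric throughout — no EASE-style overlap deflation.
#'
#' @param query Character vector of genes of interest; must be a subset
#'   of `background`.
#' @param background Character vector, the gene universe (size >= 2).
#' @param collection Tibble from [read_gmt()] (columns `term`,
#'   `category`, `genes`).
#' @param p_threshold Retain sets with `p < p_threshold` (strict);
#'   default 0.05. Use `1 + 1e-9`-like values or `Inf` to keep all.
#' @return Tibble `category`, `term`, `count` (overlap size), `percent`
#'   (100 x overlap / |query|), `p`, sorted ascending by `p`.
#' @export
ora <- function(query, background, collection, p_threshold = 0.05) {
  query <- unique(norm_gene_id(query))
  background <- unique(norm_gene_id(background))
  check_that(length(background) >= 2, "background must have >= 2 genes")
  stray <- setdiff(query, background)
  if (length(stray) > 0) {
    abort(paste0("query genes missing from background: ",
                 paste(sort(stray), collapse = ", ")))
  }
  N <- length(background)
  nq <- length(query)
  res <- purrr::map_dfr(seq_len(nrow(collection)), function(i) {
    set_bg <- intersect(collection$genes[[i]], background)
    ov <- length(intersect(query, set_bg))
    tibble(category = collection$category[i],
           term = collection$term[i],
           count = ov,
           percent = 100 * ov / nq,
           p = hypergeom_cerna_p(N, nq, length(set_bg), ov, tail = "ge"))
  })
  res %>% filter(.data$p < p_threshold) %>% arrange(.data$p, .data$term)
}
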