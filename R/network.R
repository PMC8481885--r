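#' Build the tripartite ceRNA network from triples
#'
#' Each triple contributes undirected edges (mRNA, miRNA) and (miRNA,
#' lncRNA); duplicates collapse. Node types are inferred from triple
#' roles, and an identifier appearing in two roles (e.g. as both mRNA
#' and lncRNA) is a hard error naming the ID — same-type or mRNA-lncRNA
#' edges can never arise, so the network is tripartite by construction.
#'
#' @param triples Tibble with columns `mrna`, `mirna`, `lncrna` (extra
#'   columns ignored).
#' @return An object of class `"cerna_network"`: a list with `graph`
#'   (igraph, node attribute `type`), `nodes` and `edges` tibbles.
#' @export
build_cerna_network <- function(triples) {
  check_that(all(c("mrna", "mirna", "lncrna") %in% names(triples)),
             "`triples` needs columns mrna, mirna, lncrna")
  roles <- bind_rows(
    tibble(node = unique(triples$mrna), type = "mrna"),
    tibble(node = unique(triples$mirna), type = "mirna"),
    tibble(node = unique(triples$lncrna), type = "lncrna"))
  dup <- roles$node[duplicated(roles$node)]
  if (length(dup) > 0) {
    abort(paste0("identifier(s) appear in more than one role: ",
                 paste(sort(unique(dup)), collapse = ", ")))
  }
  edges <- distinct(bind_rows(
    tibble(from = triples$mrna, to = triples$mirna),
    tibble(from = triples$mirna, to = triples$lncrna)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = roles)
  structure(list(graph = g, nodes = roles, edges = edges),
            class = "cerna_network")
}

#' Degree and betweenness for every network node
#'
#' Degree is the incident-edge count. Betweenness is the classical
#' unnormalised form: for node v, the sum over unordered node pairs
#' (s, t), s != t != v, of the fraction of (unweighted, undirected)
#' shortest s-t paths passing through v. Disconnected components are
#' allowed; unreachable pairs contribute 0.
#'
#' @param net A `"cerna_network"` (or any igraph object).
#' @return Tibble `node`, `type`, `degree`, `betweenness`, sorted by
#'   decreasing degree then betweenness then node ID.
#' @export
network_metrics <- function(net) {
  g <- if (inherits(net, "cerna_network")) net$graph else net
  check_that(igraph::vcount(g) > 0, "network is empty")
  type <- igraph::vertex_attr(g, "type")
  tibble(node = igraph::V(g)$name,
         type = if (is.null(type)) NA_character_ else type,
         degree = as.integer(igraph::degree(g)),
         betweenness = unname(igraph::betweenness(g, directed = FALSE,
                                                  normalized = FALSE))) %>%
    arrange(desc(.data$degree), desc(.data$betweenness), .data$node)
}

#' Select hub genes from a PPI edge list
#'
#' Tallies the degree of every protein in an undirected PPI edge list
#' (self-loops and duplicate edges removed) and keeps genes whose degree
#' strictly exceeds the threshold, ranked by degree descending with ties
#' broken lexicographically.
#'
#' @param ppi_edges Two-column data frame of interacting gene pairs.
#' @param degree_threshold Strict lower bound; default 10 (a degree of
#'   exactly 10 is not a hub).
#' @return Tibble `gene`, `degree`.
#' @export
select_hubs <- function(ppi_edges, degree_threshold = 10) {
  if (is.null(ppi_edges) || nrow(ppi_edges) == 0) {
    return(tibble(gene = character(), degree = integer()))
  }
  a <- norm_gene_id(ppi_edges[[1]])
  b <- norm_gene_id(ppi_edges[[2]])
  keep <- a != b
  und <- distinct(tibble(from = pmin(a[keep], b[keep]),
                         to = pmax(a[keep], b[keep])))
  tibble(gene = c(und$from, und$to)) %>%
    count(.data$gene, name = "degree") %>%
    filter(.data$degree > degree_threshold) %>%
    arrange(desc(.data$degree), .data$gene)
}

#' Candidate biomarkers from hub genes and the ceRNA network
#'
#' Matches PPI hub genes against the mRNA nodes of the ceRNA network.
#' For each such "critical gene" the report lists its partner miRNAs and
#' the lncRNAs reachable through them (one row per gene-miRNA-lncRNA
#' path), and ranks the partner lncRNAs by their network degree, then
#' betweenness, then lexicographically. Degree ties at the top are
#' flagged.
#'
#' @param hubs Character vector of hub genes, or the tibble from
#'   [select_hubs()].
#' @param net A `"cerna_network"`.
#' @param metrics Optional precomputed [network_metrics()] for `net`.
#' @return A list of class `"biomarker_report"`: `critical_genes`,
#'   `table` (tibble `gene`, `mirna`, `lncrna`), `lncrna_ranking`
#'   (tibble `lncrna`, `degree`, `betweenness`, `tied_top`).
#' @export
biomarker_candidates <- function(hubs, net, metrics = NULL) {
  if (is.data.frame(hubs)) hubs <- hubs[[1]]
  hubs <- norm_gene_id(hubs)
  if (is.null(metrics)) metrics <- network_metrics(net)
  g <- net$graph
  critical <- intersect(hubs, net$nodes$node[net$nodes$type == "mrna"])
  if (length(critical) == 0) {
    warn("no hub gene present among the network's mRNA nodes; empty report")
    return(structure(list(critical_genes = character(),
                          table = tibble(gene = character(),
                                         mirna = character(),
                                         lncrna = character()),
                          lncrna_ranking = tibble(lncrna = character(),
                                                  degree = integer(),
                                                  betweenness = numeric(),
                                                  tied_top = logical())),
                     class = "biomarker_report"))
  }
  lnc_nodes <- net$nodes$node[net$nodes$type == "lncrna"]
  rows <- purrr::map_dfr(sort(critical), function(gene) {
    mirs <- igraph::neighbors(g, gene)$name
    purrr::map_dfr(sort(mirs), function(mir) {
      lncs <- intersect(igraph::neighbors(g, mir)$name, lnc_nodes)
      if (length(lncs) == 0) return(NULL)
      tibble(gene = gene, mirna = mir, lncrna = sort(lncs))
    })
  })
  ranking <- metrics %>%
    filter(.data$node %in% unique(rows$lncrna)) %>%
    rename(lncrna = "node") %>%
    arrange(desc(.data$degree), desc(.data$betweenness), .data$lncrna) %>%
    mutate(tied_top = .data$degree == max(.data$degree)) %>%
    select("lncrna", "degree", "betweenness", "tied_top")
  structure(list(critical_genes = sort(critical), table = rows,
                 lncrna_ranking = ranking),
            class = "biomarker_report")
}

#' @export
print.cerna_network <- function(x, ...) {
  tt <- table(x$nodes$type)
  cat("Tripartite ceRNA network:",
      sum(tt), "nodes (", paste(names(tt), tt, collapse = ", "), "),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat("Biomarker report:", length(x$critical_genes),
      "critical gene(s):", paste(x$critical_genes, collapse = ", "), "\n")
  cat(nrow(x$table), "gene-miRNA-lncRNA rows;",
      nrow(x$lncrna_ranking), "ranked lncRNA(s)\n")
  if (nrow(x$lncrna_ranking) > 0) {
    top <- x$lncrna_ranking[x$lncrna_ranking$tied_top, ]
    cat("Top lncRNA(s) by degree:",
        paste(top$lncrna, "(degree", paste0(top$degree, ")"),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a ceRNA network into node metrics
#' @param x A `"cerna_network"`.
#' @param ... Unused.
#' @return The [network_metrics()] tibble.
#' @export
tidy.cerna_network <- function(x, ...) network_metrics(x)

#' One-row summary of a ceRNA network
#' @param x A `"cerna_network"`.
#' @param ... Unused.
#' @return One-row tibble of node-type and edge counts.
#' @export
glance.cerna_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes),
         n_mrna = sum(x$nodes$type == "mrna"),
         n_mirna = sum(x$nodes$type == "mirna"),
         n_lncrna = sum(x$nodes$type == "lncrna"),
         n_edges = nrow(x$edges))
}
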