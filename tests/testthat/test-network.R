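test_that("network construction collapses duplicates and types nodes", {
  one <- tibble::tibble(mrna = "G", mirna = "m", lncrna = "L")
  net1 <- build_cerna_network(one)
  expect_equal(nrow(net1$nodes), 3)
  expect_equal(nrow(net1$edges), 2)

  two <- tibble::tibble(mrna = c("G", "G"), mirna = c("m", "m"),
                        lncrna = c("L1", "L2"))
  net2 <- build_cerna_network(two)
  expect_equal(nrow(net2$nodes), 4)
  expect_equal(nrow(net2$edges), 3)

  # an ID in two roles is a hard error naming the ID
  bad <- tibble::tibble(mrna = c("G", "X"), mirna = c("m", "m2"),
                        lncrna = c("X", "L"))
  expect_error(build_cerna_network(bad), "X")
})

test_that("degree and betweenness match hand values on canonical graphs", {
  # path G - m - L: the middle node bridges the single pair
  path <- build_cerna_network(tibble::tibble(mrna = "G", mirna = "m",
                                             lncrna = "L"))
  mt <- network_metrics(path)
  expect_equal(mt$betweenness[mt$node == "m"], 1)
  expect_equal(mt$betweenness[mt$node != "m"], c(0, 0))

  # star with centre m and 4 leaves: degree 4, betweenness C(4,2) = 6
  star <- build_cerna_network(tibble::tibble(
    mrna = c("G1", "G2"), mirna = "m", lncrna = c("L1", "L2")))
  mt <- network_metrics(star)
  expect_equal(mt$degree[mt$node == "m"], 4L)
  expect_equal(mt$betweenness[mt$node == "m"], 6)
})

test_that("metrics agree with exhaustive path enumeration on random networks", {
  set.seed(33)
  for (i in 1:25) {
    tr <- random_triples(n_mrna = sample(2:4, 1), n_mirna = sample(2:4, 1),
                         n_lncrna = sample(2:4, 1),
                         n_triples = sample(2:8, 1))
    net <- build_cerna_network(tr)
    mt <- network_metrics(net)
    bt <- oracle_betweenness(net$nodes$node, net$edges)
    expect_equal(mt$betweenness, unname(bt[mt$node]), tolerance = 1e-9)
    deg_oracle <- table(c(net$edges$from, net$edges$to))
    expect_equal(mt$degree, as.integer(deg_oracle[mt$node]))
    expect_equal(sum(mt$degree), 2L * nrow(net$edges))
  }
})

test_that("mRNA-lncRNA shortest paths have even length through a miRNA", {
  set.seed(5)
  tr <- random_triples(3, 4, 4, 10)
  net <- build_cerna_network(tr)
  mrnas <- net$nodes$node[net$nodes$type == "mrna"]
  lncs <- net$nodes$node[net$nodes$type == "lncrna"]
  d <- igraph::distances(net$graph, v = mrnas, to = lncs)
  finite <- d[is.finite(d)]
  expect_true(all(finite %% 2 == 0))
  expect_true(all(finite >= 2))
})

test_that("hub selection applies a strict degree cutoff with ranked output", {
  star_edges <- function(n) {
    tibble::tibble(a = "HUB", b = paste0("p", seq_len(n)))
  }
  expect_equal(select_hubs(star_edges(11))$gene, "HUB")
  expect_equal(nrow(select_hubs(star_edges(10))), 0)  # exactly 10 is not a hub
  expect_equal(nrow(select_hubs(tibble::tibble(a = character(),
                                               b = character()))), 0)

  set.seed(12)
  edges <- tibble::tibble(a = sample(paste0("g", 1:20), 300, replace = TRUE),
                          b = sample(paste0("g", 1:20), 300, replace = TRUE))
  hubs <- select_hubs(edges, degree_threshold = 5)
  # brute-force tally on the deduplicated undirected edge set
  e <- edges[edges$a != edges$b, ]
  key <- unique(paste(pmin(toupper(e$a), toupper(e$b)),
                      pmax(toupper(e$a), toupper(e$b))))
  cnt <- table(unlist(strsplit(key, " ")))
  expect_equal(setNames(hubs$degree, hubs$gene),
               setNames(as.integer(cnt[hubs$gene]), hubs$gene))
  expect_true(all(hubs$degree > 5))
  expect_false(is.unsorted(rev(hubs$degree)))
})

test_that("biomarker matching reports hub genes with their partners", {
  tr <- tibble::tibble(mrna = c("G", "H"), mirna = c("m", "m2"),
                       lncrna = c("L", "L2"))
  net <- build_cerna_network(tr)
  rep1 <- biomarker_candidates("G", net)
  expect_equal(rep1$critical_genes, "G")
  expect_equal(rep1$table,
               tibble::tibble(gene = "G", mirna = "m", lncrna = "L"))

  expect_warning(rep0 <- biomarker_candidates("ZZZ", net), "no hub gene")
  expect_equal(nrow(rep0$table), 0)

  # a planted high-degree lncRNA ranks first
  tr2 <- tibble::tibble(
    mrna = rep("G", 4), mirna = paste0("m", 1:4),
    lncrna = c("LTOP", "LTOP", "LTOP", "LOTHER"))
  rep2 <- biomarker_candidates("G", build_cerna_network(tr2))
  expect_equal(rep2$lncrna_ranking$lncrna[1], "LTOP")
  expect_equal(rep2$lncrna_ranking$degree[1], 3L)
})

test_that("network exports round-trip node types and edges", {
  tr <- random_triples(2, 3, 3, 5)
  net <- build_cerna_network(tr)
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_sif(net, sif)
  lines <- readLines(sif)
  expect_length(lines, nrow(net$edges))
  expect_true(all(grepl("\t(mrna-mirna|mirna-lncrna)\t", lines)))
  write_network_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), nrow(net$nodes))
  expect_equal(igraph::ecount(back), nrow(net$edges))
  expect_setequal(igraph::vertex_attr(back, "type"), net$nodes$type)
})
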