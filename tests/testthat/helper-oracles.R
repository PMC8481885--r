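# Independent oracles, kept deliberately naive: direct formulas and
# exhaustive enumeration, never sharing code with the implementation.

# Hypergeometric tail by exhaustive pmf enumeration with choose().
oracle_hyper_tail <- function(N, n, m, x, tail = "ge") {
  ks <- 0:min(n, m)
  pmf <- choose(m, ks) * choose(N - m, n - ks) / choose(N, n)
  lo <- if (tail == "ge") x else x + 1
  sum(pmf[ks >= lo])
}

# Benjamini-Hochberg step-up, written from the definition:
# q(i) = min_{j >= i} p(j) * m / j over the sorted p-values.
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Pooled-variance two-sample t from the textbook formula.
oracle_student_t <- function(case, control) {
  n1 <- length(case); n2 <- length(control)
  sp <- sqrt(((n1 - 1) * var(case) + (n2 - 1) * var(control)) /
               (n1 + n2 - 2))
  (mean(case) - mean(control)) / (sp * sqrt(1 / n1 + 1 / n2))
}

# Unnormalised betweenness by exhaustive shortest-path enumeration:
# BFS distances, then DFS enumeration of every geodesic per node pair.
oracle_betweenness <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  bfs_dist <- function(s) {
    d <- setNames(rep(Inf, length(nodes)), nodes)
    d[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- character(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (is.infinite(d[w])) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
      }
      frontier <- unique(nxt)
    }
    d
  }
  all_geodesics <- function(s, t, d) {
    # every path s -> t of length d[t], found by stepping down distance
    paths <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { paths[[length(paths) + 1]] <<- path; return() }
      for (w in adj[[v]]) if (d[w] == d[v] + 1) walk(c(path, w))
    }
    walk(s)
    paths
  }
  bt <- setNames(rep(0, length(nodes)), nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    s <- nodes[i]; t <- nodes[j]
    d <- bfs_dist(s)
    if (is.infinite(d[t])) next
    paths <- all_geodesics(s, t, d)
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      bt[interior] <- bt[interior] + 1 / length(paths)
    }
  }
  bt
}

# Random valid tripartite triple tables for topology tests.
random_triples <- function(n_mrna = 3, n_mirna = 4, n_lncrna = 4,
                           n_triples = 5) {
  tibble::tibble(
    mrna = sample(paste0("g", seq_len(n_mrna)), n_triples, replace = TRUE),
    mirna = sample(paste0("mi", seq_len(n_mirna)), n_triples, replace = TRUE),
    lncrna = sample(paste0("l", seq_len(n_lncrna)), n_triples,
                    replace = TRUE))
}

# Small study used by several files; memoised per test run.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cerna_study(sim_config(
        n_genes = 300, n_mirnas = 60, n_lncrnas = 80,
        planted_triples = 8, seed = 11L))
    }
    cache
  }
})

triple_key <- function(d) paste(d$mrna, d$mirna, d$lncrna)
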