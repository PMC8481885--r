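#' Restrict an mRNA-miRNA table to a gene class
#'
#' Sub-table of the mRNA-miRNA interactions whose mRNA endpoint belongs
#' to the supplied gene set. The distinct miRNAs of this sub-table form
#' the universe `N` for the run's cumulative hypergeometric tests.
#'
#' @param genes Character vector of gene symbols (an aberrant class).
#' @param mrna_mirna Edge tibble with columns `mrna`, `mirna`.
#' @return Filtered edge tibble (normalised IDs, no duplicates). A
#'   warning is emitted when the result is empty.
#' @export
match_dmg_mirna <- function(genes, mrna_mirna) {
  tbl <- mrna_mirna %>%
    mutate(mrna = norm_gene_id(.data$mrna),
           mirna = norm_mirna_id(.data$mirna)) %>%
    distinct() %>%
    filter(.data$mrna %in% norm_gene_id(genes))
  if (nrow(tbl) == 0) {
    warn("no mRNA-miRNA interactions match the gene set; downstream stages will be empty")
  }
  tbl
}

#' Enumerate candidate ceRNA pairs with the shared-miRNA test
#'
#' Every (mRNA, lncRNA) pair sharing at least one miRNA between the
#' DMG-restricted mRNA-miRNA table and the miRNA-lncRNA table is scored
#' with [hypergeom_cerna_p()]. The universe `N` is the distinct-miRNA
#' count of `dmg_mirna`; the lncRNA's partner count `m` is taken after
#' restricting its miRNAs to that universe, so `m <= N` always holds.
#'
#' @param dmg_mirna Output of [match_dmg_mirna()].
#' @param mirna_lncrna Edge tibble with columns `mirna`, `lncrna`.
#' @param tail Tail convention passed to [hypergeom_cerna_p()].
#' @return Tibble with one row per candidate pair: `mrna`, `lncrna`,
#'   `N`, `n`, `m`, `x`, `shared_mirnas` (list column), `p_hyper`.
#' @export
cerna_pairs <- function(dmg_mirna, mirna_lncrna, tail = c("ge", "gt")) {
  tail <- match.arg(tail)
  empty <- tibble(mrna = character(), lncrna = character(),
                  N = integer(), n = integer(), m = integer(),
                  x = integer(), shared_mirnas = list(),
                  p_hyper = numeric())
  if (nrow(dmg_mirna) == 0) return(empty)
  ml <- mirna_lncrna %>%
    mutate(mirna = norm_mirna_id(.data$mirna),
           lncrna = toupper(trimws(.data$lncrna))) %>%
    distinct() %>%
    filter(.data$mirna %in% unique(dmg_mirna$mirna))
  if (nrow(ml) == 0) return(empty)

  N <- n_distinct(dmg_mirna$mirna)
  n_mrna <- count(dmg_mirna, .data$mrna, name = "n")
  m_lnc <- count(ml, .data$lncrna, name = "m")

  inner_join(dmg_mirna, ml, by = "mirna",
             relationship = "many-to-many") %>%
    group_by(.data$mrna, .data$lncrna) %>%
    summarise(x = n(), shared_mirnas = list(sort(.data$mirna)),
              .groups = "drop") %>%
    left_join(n_mrna, by = "mrna") %>%
    left_join(m_lnc, by = "lncrna") %>%
    mutate(N = N,
           p_hyper = hypergeom_cerna_p(N, .data$n, .data$m, .data$x,
                                       tail = tail)) %>%
    select("mrna", "lncrna", "N", "n", "m", "x", "shared_mirnas",
           "p_hyper") %>%
    arrange(.data$p_hyper, .data$mrna, .data$lncrna)
}

# Pearson r and its exact-under-normality two-sided p via the
# t-transform t = r sqrt((s - 2) / (1 - r^2)) with s samples.
cor_test_p <- function(r, s) {
  p <- ifelse(abs(r) >= 1, 0,
              2 * pt(-abs(r * sqrt((s - 2) / (1 - r^2))), s - 2))
  pmin(pmax(p, 0), 1)
}

#' Co-expression filter for ceRNA pairs
#'
#' Adds the Pearson correlation of each pair's mRNA and lncRNA profiles
#' across all samples, a correlation-test p-value, and a
#' Benjamini-Hochberg FDR computed over all pairs in the call; retains
#' pairs with `pcc > pcc_threshold` and `fdr < fdr_threshold` (both
#' strict). Pairs whose mRNA or lncRNA is missing from the matrices, or
#' whose profile has zero variance, are dropped with a warning.
#'
#' @param pairs Pair tibble from [cerna_pairs()].
#' @param mrna_expr,lnc_expr Feature x sample data frames (first column
#'   the feature ID) with identical ordered sample columns.
#' @param pcc_threshold,fdr_threshold Strict cutoffs; defaults 0.5 and
#'   0.05.
#' @param keep_all Keep non-passing pairs (annotated, for inspection)?
#' @return The pair tibble with `pcc`, `p_cor`, `fdr` columns; filtered
#'   unless `keep_all`.
#' @export
coexpression_filter <- function(pairs, mrna_expr, lnc_expr,
                                pcc_threshold = 0.5, fdr_threshold = 0.05,
                                keep_all = FALSE) {
  if (nrow(pairs) == 0) {
    return(mutate(pairs, pcc = numeric(0), p_cor = numeric(0),
                  fdr = numeric(0)))
  }
  me <- as_feature_matrix(mrna_expr)
  le <- as_feature_matrix(lnc_expr)
  rownames(me) <- norm_gene_id(rownames(me))
  rownames(le) <- toupper(trimws(rownames(le)))
  check_that(identical(colnames(me), colnames(le)),
             "mRNA and lncRNA matrices must share the same ordered sample IDs")
  s <- ncol(me)

  present <- pairs$mrna %in% rownames(me) & pairs$lncrna %in% rownames(le)
  if (any(!present)) {
    warn(sprintf("%d pair(s) dropped: mRNA or lncRNA absent from the expression matrices",
                 sum(!present)))
  }
  out <- pairs[present, , drop = FALSE]
  if (nrow(out) == 0) {
    return(mutate(out, pcc = numeric(0), p_cor = numeric(0),
                  fdr = numeric(0)))
  }
  xm <- me[out$mrna, , drop = FALSE]
  xl <- le[out$lncrna, , drop = FALSE]
  sd0 <- apply(xm, 1, stats::sd) == 0 | apply(xl, 1, stats::sd) == 0
  if (any(sd0)) {
    warn(sprintf("%d pair(s) dropped: zero-variance expression profile", sum(sd0)))
    out <- out[!sd0, , drop = FALSE]
    xm <- xm[!sd0, , drop = FALSE]
    xl <- xl[!sd0, , drop = FALSE]
  }
  if (nrow(out) == 0) {
    return(mutate(out, pcc = numeric(0), p_cor = numeric(0),
                  fdr = numeric(0)))
  }
  r <- vapply(seq_len(nrow(out)),
              function(i) stats::cor(xm[i, ], xl[i, ]), numeric(1))
  out <- out %>%
    mutate(pcc = r, p_cor = cor_test_p(r, s), fdr = bh_fdr(.data$p_cor))
  if (keep_all) out else
    filter(out, .data$pcc > pcc_threshold, .data$fdr < fdr_threshold)
}

#' Assemble competing triplets
#'
#' Full ceRNA inference for one gene class: enumerate candidate pairs,
#' keep those with hypergeometric `p < p_threshold` (strict, raw — no
#' multiplicity adjustment at this stage), apply the co-expression
#' filter, then expand each surviving pair into one triple per shared
#' miRNA.
#'
#' @inheritParams cerna_pairs
#' @inheritParams coexpression_filter
#' @param p_threshold Strict hypergeometric p cutoff; default 0.05.
#' @return Tibble with one row per (mRNA, miRNA, lncRNA) triple carrying
#'   all parent-pair statistics plus a `curated` flag (`NA` until
#'   [restrict_to_curated()]).
#' @export
assemble_triples <- function(dmg_mirna, mirna_lncrna, mrna_expr, lnc_expr,
                             p_threshold = 0.05, tail = c("ge", "gt"),
                             pcc_threshold = 0.5, fdr_threshold = 0.05) {
  tail <- match.arg(tail)
  pairs <- cerna_pairs(dmg_mirna, mirna_lncrna, tail = tail) %>%
    filter(.data$p_hyper < p_threshold) %>%
    coexpression_filter(mrna_expr, lnc_expr,
                        pcc_threshold = pcc_threshold,
                        fdr_threshold = fdr_threshold)
  pairs %>%
    mutate(mirna = .data$shared_mirnas) %>%
    tidyr::unnest("mirna") %>%
    mutate(curated = NA) %>%
    select("mrna", "mirna", "lncrna", "N", "n", "m", "x", "p_hyper",
           "pcc", "fdr", "curated")
}

#' Restrict triples to curated disease-risk miRNAs
#'
#' Keeps triples whose miRNA appears in a curated risk list, matching
#' after [norm_mirna_id()] normalisation (so `"hsa-miR-30a"` in a triple
#' matches a curated entry `"miR-30a"`). Never increases the triple
#' count.
#'
#' @param triples Triple tibble from [assemble_triples()].
#' @param curated Non-empty character vector of curated miRNA IDs.
#' @return The retained triples with `curated = TRUE`.
#' @export
restrict_to_curated <- function(triples, curated) {
  check_that(length(curated) > 0, "`curated` must be non-empty")
  keep <- norm_mirna_id(triples$mirna) %in% norm_mirna_id(curated)
  triples[keep, , drop = FALSE] %>% mutate(curated = TRUE)
}
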