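test_that("hypergeometric tails match enumeration, phyper and each other", {
  # N=10, n=3, m=4, x=3: P(X >= 3) = C(4,3)C(6,0)/C(10,3) = 4/120
  expect_equal(hypergeom_cerna_p(10, 3, 4, 3, "ge"), 4 / 120,
               tolerance = 1e-14)
  # full-support x under the strict tail is impossible
  expect_equal(hypergeom_cerna_p(10, 3, 4, 3, "gt"), 0)
  # x = 0 under ge is the certain event
  expect_equal(hypergeom_cerna_p(17, 5, 9, 0, "ge"), 1)

  set.seed(8)
  for (i in 1:50) {
    N <- sample(2:60, 1)
    n <- sample(seq_len(N), 1)
    m <- sample(seq_len(N), 1)
    x <- sample(0:min(n, m), 1)
    ge <- hypergeom_cerna_p(N, n, m, x, "ge")
    gt <- hypergeom_cerna_p(N, n, m, x, "gt")
    expect_equal(ge, oracle_hyper_tail(N, n, m, x, "ge"), tolerance = 1e-12)
    expect_equal(gt, oracle_hyper_tail(N, n, m, x, "gt"), tolerance = 1e-12)
    expect_gte(ge, gt)
    # survival-function cross-check
    expect_equal(ge, phyper(x - 1, m, N - m, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # monotone non-increasing in x at fixed N, n, m
  p_seq <- hypergeom_cerna_p(40, 12, 15, 0:12, "ge")
  expect_true(all(diff(p_seq) <= 1e-15))
})

test_that("hypergeometric preconditions raise named errors", {
  expect_error(hypergeom_cerna_p(0, 0, 0, 0), "N >= 1")
  expect_error(hypergeom_cerna_p(5, 6, 2, 1), "n <= N")
  expect_error(hypergeom_cerna_p(5, 2, 6, 1), "m <= N")
  expect_error(hypergeom_cerna_p(5, 2, 3, 3), "min\\(n, m\\)")
})

test_that("BH adjustment matches the step-up oracle and its identities", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(rep(0.3, 5)), rep(0.3, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-14)

  set.seed(2)
  for (i in 1:20) {
    pv <- runif(sample(1:40, 1))
    adj <- bh_fdr(pv)
    expect_equal(adj, oracle_bh(pv), tolerance = 1e-13)
    expect_true(all(adj >= pv))
    # monotone: adjustment preserves the ordering of the p-values
    expect_true(all(diff(adj[order(pv)]) >= -1e-15))
  }
})

test_that("gene-set restriction of the mRNA-miRNA table defines the universe", {
  tbl <- tibble::tibble(mrna = c("G1", "G2"), mirna = c("miR-a", "miR-b"))
  sub <- match_dmg_mirna("G1", tbl)
  expect_equal(nrow(sub), 1)
  expect_equal(dplyr::n_distinct(sub$mirna), 1)
  expect_warning(empty <- match_dmg_mirna("NOPE", tbl), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("pair enumeration counts N, n, m, x correctly on a toy table", {
  mm <- tibble::tibble(
    mrna = c("G1", "G1", "G1", "G2", "G2"),
    mirna = c("m1", "m2", "m3", "m3", "m4"))
  ml <- tibble::tibble(
    mirna = c("m1", "m2", "m5", "m4"),
    lncrna = c("L1", "L1", "L1", "L2"))
  dm <- match_dmg_mirna(c("G1", "G2"), mm)
  pairs <- cerna_pairs(dm, ml)
  # universe: m1..m4 (m5 is outside); L1 shares {m1,m2} with G1 only
  expect_equal(nrow(pairs), 2)
  p1 <- pairs[pairs$mrna == "G1" & pairs$lncrna == "L1", ]
  expect_equal(p1$N, 4); expect_equal(p1$n, 3)
  expect_equal(p1$m, 2)  # restricted to the universe, m5 dropped
  expect_equal(p1$x, 2)
  expect_equal(p1$p_hyper, oracle_hyper_tail(4, 3, 2, 2, "ge"),
               tolerance = 1e-12)
  expect_equal(p1$shared_mirnas[[1]], c("m1", "m2"))
  # a pair sharing zero miRNAs is never enumerated
  expect_false(any(pairs$mrna == "G1" & pairs$lncrna == "L2"))
})

test_that("co-expression filtering computes PCC and is strict at the cutoffs", {
  expr <- tibble::tibble(gene_id = c("G1", "G2"),
                         s1 = c(1, 1), s2 = c(2, 2), s3 = c(3, 4),
                         s4 = c(4, 3), s5 = c(5, 5))
  lnc <- tibble::tibble(lncrna_id = c("L1", "L2"),
                        s1 = c(2, 5), s2 = c(4, 4), s3 = c(6, 3),
                        s4 = c(8, 2), s5 = c(10, 1))
  pairs <- tibble::tibble(mrna = c("G1", "G1"), lncrna = c("L1", "L2"),
                          N = 10L, n = 3L, m = 3L, x = 2L,
                          shared_mirnas = list(c("a", "b"), c("a", "b")),
                          p_hyper = 0.01)
  out <- coexpression_filter(pairs, expr, lnc, keep_all = TRUE)
  expect_equal(out$pcc[out$lncrna == "L1"], 1)           # perfect linearity
  expect_equal(out$pcc[out$lncrna == "L2"], -1)
  # cross-check p-value against stats::cor.test
  r <- cor(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  ct <- cor.test(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(cernet:::cor_test_p(r, 5), ct$p.value, tolerance = 1e-12)

  kept <- coexpression_filter(pairs, expr, lnc)
  expect_equal(kept$lncrna, "L1")  # negative correlation rejected

  # pcc exactly at the threshold is rejected (strict inequality)
  fake <- tibble::tibble(mrna = "G1", lncrna = "L1", N = 10L, n = 3L,
                         m = 3L, x = 2L, shared_mirnas = list("a"),
                         p_hyper = 0.01, pcc = 0.5, p_cor = 1e-9, fdr = 1e-9)
  expect_equal(nrow(dplyr::filter(fake, .data$pcc > 0.5, .data$fdr < 0.05)), 0)

  # absent and zero-variance members are dropped with warnings
  bad <- tibble::tibble(mrna = c("G1", "GX"), lncrna = c("L1", "L1"),
                        N = 10L, n = 3L, m = 3L, x = 2L,
                        shared_mirnas = list("a", "a"), p_hyper = 0.01)
  expect_warning(res <- coexpression_filter(bad, expr, lnc, keep_all = TRUE),
                 "absent")
  expect_equal(nrow(res), 1)
})

test_that("triple assembly recovers planted units and the expansion identity", {
  st <- small_study()
  truth <- st$truth
  gene_set <- c(truth$true_hyperlow, truth$true_hypohigh)
  dm <- match_dmg_mirna(gene_set, st$mrna_mirna)
  pairs <- cerna_pairs(dm, st$mirna_lncrna) |>
    dplyr::filter(.data$p_hyper < 0.05)
  surv <- coexpression_filter(pairs, st$expression, st$lnc_expression)
  triples <- assemble_triples(dm, st$mirna_lncrna, st$expression,
                              st$lnc_expression)
  # expansion identity: one triple per shared miRNA of a surviving pair
  expect_equal(nrow(triples), sum(surv$x))
  # every planted (mRNA, miRNA) edge survives restriction
  tt <- dplyr::mutate(truth$true_triples, mirna = norm_mirna_id(mirna))
  expect_true(all(paste(tt$mrna, tt$mirna) %in% paste(dm$mrna, dm$mirna)))
  # planted triples recovered
  expect_gte(mean(triple_key(tt) %in% triple_key(triples)), 0.8)
  # no fabricated edges: every reported edge exists in the input tables
  mm <- match_dmg_mirna(unique(triples$mrna), st$mrna_mirna)
  expect_true(all(paste(triples$mrna, triples$mirna) %in%
                    paste(mm$mrna, mm$mirna)))
  ml_norm <- dplyr::mutate(st$mirna_lncrna, mirna = norm_mirna_id(mirna))
  expect_true(all(paste(triples$mirna, triples$lncrna) %in%
                    paste(ml_norm$mirna, ml_norm$lncrna)))
})

test_that("curated restriction normalises IDs and never adds triples", {
  triples <- tibble::tibble(
    mrna = c("G1", "G2"), mirna = c("hsa-miR-30a", "hsa-miR-99b"),
    lncrna = c("L1", "L2"), N = 10L, n = 3L, m = 3L, x = 1L,
    p_hyper = 0.01, pcc = 0.8, fdr = 0.01, curated = NA)
  kept <- restrict_to_curated(triples, "miR-30a")
  expect_equal(kept$mrna, "G1")
  expect_true(all(kept$curated))
  all_kept <- restrict_to_curated(triples, c("mir-30a", "MIR-99B"))
  expect_equal(nrow(all_kept), 2)
  expect_lte(nrow(kept), nrow(triples))
  expect_error(restrict_to_curated(triples, character(0)), "non-empty")
})
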