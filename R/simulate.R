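#' Simulation configuration
#'
#' Validated parameter set for [simulate_cerna_study()]. Defaults describe
#' the study conditions used throughout the package's own checks: a
#' monocyte-microarray-like two-group design with 25 cases and 25
#' controls, 2,000 genes of which 10% are differentially expressed
#' (log2-scale shift of 2 against unit noise) and 10% differentially
#' methylated (beta-value shift of 0.2), 20 planted competing triplets
#' whose mRNA and lncRNA are co-expressed at Pearson r = 0.8, and sparse
#' background interaction tables (2% edge density).
#'
#' @param n_case,n_control Samples per group; each must be at least 3 or
#'   the downstream t-statistic is degenerate.
#' @param n_genes,n_mirnas,n_lncrnas Feature-space sizes.
#' @param frac_de Fraction of genes differentially expressed (split
#'   evenly up/down).
#' @param de_effect Mean case-vs-control shift, log2 expression units.
#' @param frac_dm Fraction of genes differentially methylated (split
#'   evenly hyper/hypo).
#' @param dm_effect Beta-value shift in `[0, 1]`; shifted values are
#'   clamped back into `[0, 1]`.
#' @param noise_sd Within-group expression noise standard deviation.
#' @param planted_triples Number of planted ceRNA mRNA-lncRNA units; each
#'   shares 4 miRNAs between its mRNA and lncRNA.
#' @param planted_rho Target Pearson correlation of planted mRNA-lncRNA
#'   expression profiles, `|planted_rho| <= 1`.
#' @param edge_density Probability of each possible background
#'   interaction edge.
#' @param seed Integer random seed; identical configurations with
#'   identical seeds reproduce identical datasets.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_case = 25, n_control = 25,
                       n_genes = 2000, n_mirnas = 150, n_lncrnas = 300,
                       frac_de = 0.1, de_effect = 2,
                       frac_dm = 0.1, dm_effect = 0.2,
                       noise_sd = 1,
                       planted_triples = 20, planted_rho = 0.8,
                       edge_density = 0.02, seed = 1L) {
  cfg <- list(n_case = n_case, n_control = n_control, n_genes = n_genes,
              n_mirnas = n_mirnas, n_lncrnas = n_lncrnas,
              frac_de = frac_de, de_effect = de_effect,
              frac_dm = frac_dm, dm_effect = dm_effect,
              noise_sd = noise_sd, planted_triples = planted_triples,
              planted_rho = planted_rho, edge_density = edge_density,
              seed = as.integer(seed))
  counts <- c("n_case", "n_control", "n_genes", "n_mirnas", "n_lncrnas")
  for (f in counts) {
    check_that(length(cfg[[f]]) == 1 && cfg[[f]] > 0 &&
                 cfg[[f]] == round(cfg[[f]]),
               paste0("`", f, "` must be a positive integer"))
  }
  check_that(n_case >= 3 && n_control >= 3,
             "need at least 3 samples per group (t-statistic degenerate below that)")
  check_that(frac_de >= 0 && frac_de <= 1, "`frac_de` must lie in [0, 1]")
  check_that(frac_dm >= 0 && frac_dm <= 1, "`frac_dm` must lie in [0, 1]")
  check_that(dm_effect >= 0 && dm_effect <= 1,
             "`dm_effect` must lie in [0, 1]")
  check_that(abs(planted_rho) <= 1, "`|planted_rho|` must be at most 1")
  check_that(edge_density >= 0 && edge_density <= 1,
             "`edge_density` must lie in [0, 1]")
  check_that(noise_sd > 0, "`noise_sd` must be positive")
  check_that(planted_triples >= 0 &&
               planted_triples == round(planted_triples),
             "`planted_triples` must be a non-negative integer")
  check_that(planted_triples <= n_genes && planted_triples <= n_lncrnas,
             "`planted_triples` exceeds the available mRNA or lncRNA identifiers")
  check_that(planted_triples * 4 <= n_mirnas,
             "`planted_triples` exceeds the available miRNA identifiers (4 shared miRNAs per triple)")
  structure(cfg, class = "sim_config")
}

# Shared miRNAs per planted mRNA-lncRNA unit. Four gives the
# hypergeometric test a clearly non-null overlap against the sparse
# background without saturating the universe.
SHARED_PER_TRIPLE <- 4L

#' Simulate a two-group methylation/expression ceRNA study
#'
#' Generates everything the pipeline consumes — case/control expression
#' and methylation matrices, a lncRNA expression matrix on the same
#' samples, mRNA-miRNA and miRNA-lncRNA interaction tables, a curated
#' disease-risk miRNA list — together with the planted ground truth
#' needed to score recovery.
#'
#' Expression is Gaussian on a log2-like scale around gene-specific
#' baselines; differential genes get `de_effect` added (up) or
#' subtracted (down) in case samples. Methylation beta values are
#' clamped Gaussians around gene-specific baselines with `+dm_effect`
#' (hyper) or `-dm_effect` (hypo) in cases. Differential methylation is
#' planted so that half of the down-regulated genes are hypermethylated
#' and half of the up-regulated genes are hypomethylated, giving
#' non-empty aberrant intersection classes by construction.
#'
#' Each planted ceRNA unit is an (mRNA, lncRNA) pair sharing 4 miRNAs in
#' the interaction tables; its lncRNA profile is mixed from the
#' standardised mRNA profile, `lnc = rho * z(mRNA) + sqrt(1 - rho^2) *
#' noise`, so the target correlation holds across all samples even when
#' the mRNA also carries a group shift. Planted mRNAs are drawn from the
#' aberrant intersection classes when available. Background interaction
#' edges are uniform at `edge_density`.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"cerna_study"` with elements `expression`,
#'   `methylation`, `lnc_expression` (tibbles, first column the feature
#'   ID, then one column per sample), `groups` (tibble `sample_id`,
#'   `group`), `mrna_mirna`, `mirna_lncrna` (edge tibbles),
#'   `curated_mirnas` (character), `truth` (list of planted-ID sets and
#'   a `true_triples` tibble) and `config`.
#' @export
simulate_cerna_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config

  samples <- c(sprintf("case_%02d", seq_len(cf$n_case)),
               sprintf("ctrl_%02d", seq_len(cf$n_control)))
  is_case <- c(rep(TRUE, cf$n_case), rep(FALSE, cf$n_control))
  groups <- tibble(sample_id = samples,
                   group = ifelse(is_case, "case", "control"))
  ns <- length(samples)

  genes <- sprintf("G%04d", seq_len(cf$n_genes))
  mirnas <- sprintf("hsa-miR-%d", seq_len(cf$n_mirnas))
  lncs <- sprintf("LNC%04d", seq_len(cf$n_lncrnas))

  # -- plant differential and aberrant-class structure ------------------
  n_de <- round(cf$frac_de * cf$n_genes)
  n_up <- n_de %/% 2; n_down <- n_de - n_up
  n_dm <- round(cf$frac_dm * cf$n_genes)
  n_hyper <- n_dm %/% 2 + n_dm %% 2; n_hypo <- n_dm %/% 2
  n_hyperlow <- min(n_down %/% 2, n_hyper)
  n_hypohigh <- min(n_up %/% 2, n_hypo)

  perm <- sample(genes)
  take <- function(k) {
    out <- head(perm, k)
    if (k > 0) perm <<- perm[-seq_len(min(k, length(perm)))]
    out
  }
  hyperlow <- take(n_hyperlow)            # down & hyper
  down_only <- take(n_down - n_hyperlow)
  hypohigh <- take(n_hypohigh)            # up & hypo
  up_only <- take(n_up - n_hypohigh)
  hyper_only <- take(n_hyper - n_hyperlow)
  hypo_only <- take(n_hypo - n_hypohigh)

  true_down <- c(hyperlow, down_only)
  true_up <- c(hypohigh, up_only)
  true_hyper <- c(hyperlow, hyper_only)
  true_hypo <- c(hypohigh, hypo_only)

  # -- expression matrix ------------------------------------------------
  base_expr <- rnorm(cf$n_genes, mean = 8, sd = 1.5)
  expr <- matrix(rnorm(cf$n_genes * ns, sd = cf$noise_sd),
                 nrow = cf$n_genes, dimnames = list(genes, samples))
  expr <- expr + base_expr
  expr[true_up, is_case] <- expr[true_up, is_case] + cf$de_effect
  expr[true_down, is_case] <- expr[true_down, is_case] - cf$de_effect

  # -- methylation matrix (beta values, clamped) ------------------------
  # Within-group beta noise is held at sd 0.05, typical of averaged
  # gene-level 450K betas; `noise_sd` applies to the expression scale.
  base_meth <- runif(cf$n_genes, 0.2, 0.8)
  meth <- matrix(rnorm(cf$n_genes * ns, sd = 0.05),
                 nrow = cf$n_genes, dimnames = list(genes, samples))
  meth <- meth + base_meth
  meth[true_hyper, is_case] <- meth[true_hyper, is_case] + cf$dm_effect
  meth[true_hypo, is_case] <- meth[true_hypo, is_case] - cf$dm_effect
  meth <- pmin(pmax(meth, 0), 1)

  # -- lncRNA expression ------------------------------------------------
  base_lnc <- rnorm(cf$n_lncrnas, mean = 6, sd = 1.5)
  lnc_expr <- matrix(rnorm(cf$n_lncrnas * ns, sd = cf$noise_sd),
                     nrow = cf$n_lncrnas, dimnames = list(lncs, samples))
  lnc_expr <- lnc_expr + base_lnc

  # -- planted ceRNA units ----------------------------------------------
  k <- cf$planted_triples
  # Interleave the two aberrant classes so planted ceRNA units populate
  # both downstream networks.
  nmax <- max(length(hyperlow), length(hypohigh))
  planted_pool <- as.vector(rbind(c(hyperlow, rep(NA, nmax - length(hyperlow))),
                                  c(hypohigh, rep(NA, nmax - length(hypohigh)))))
  planted_pool <- planted_pool[!is.na(planted_pool)]
  if (length(planted_pool) < k) {
    planted_pool <- c(planted_pool,
                      setdiff(genes, planted_pool)[seq_len(k - length(planted_pool))])
  }
  planted_mrna <- head(planted_pool, k)
  planted_lnc <- sample(lncs, k)
  planted_mirna_sets <- if (k > 0) {
    split(sample(mirnas, SHARED_PER_TRIPLE * k),
          rep(seq_len(k), each = SHARED_PER_TRIPLE))
  } else list()

  rho <- cf$planted_rho
  for (i in seq_len(k)) {
    z <- as.numeric(scale(expr[planted_mrna[i], ]))
    eps <- rnorm(ns)
    lnc_expr[planted_lnc[i], ] <- base_lnc[match(planted_lnc[i], lncs)] +
      cf$noise_sd * (rho * z + sqrt(1 - rho^2) * eps)
  }

  # -- interaction tables -----------------------------------------------
  mm_bg <- which(matrix(runif(cf$n_genes * cf$n_mirnas),
                        cf$n_genes) < cf$edge_density, arr.ind = TRUE)
  mrna_mirna <- tibble(mrna = genes[mm_bg[, 1]], mirna = mirnas[mm_bg[, 2]])
  ml_bg <- which(matrix(runif(cf$n_mirnas * cf$n_lncrnas),
                        cf$n_mirnas) < cf$edge_density, arr.ind = TRUE)
  mirna_lncrna <- tibble(mirna = mirnas[ml_bg[, 1]], lncrna = lncs[ml_bg[, 2]])

  if (k > 0) {
    planted_mm <- tibble(
      mrna = rep(planted_mrna, each = SHARED_PER_TRIPLE),
      mirna = unlist(planted_mirna_sets, use.names = FALSE))
    planted_ml <- tibble(
      mirna = unlist(planted_mirna_sets, use.names = FALSE),
      lncrna = rep(planted_lnc, each = SHARED_PER_TRIPLE))
    mrna_mirna <- distinct(bind_rows(mrna_mirna, planted_mm))
    mirna_lncrna <- distinct(bind_rows(mirna_lncrna, planted_ml))
  } else {
    mrna_mirna <- distinct(mrna_mirna)
    mirna_lncrna <- distinct(mirna_lncrna)
  }
  mrna_mirna <- arrange(mrna_mirna, .data$mrna, .data$mirna)
  mirna_lncrna <- arrange(mirna_lncrna, .data$mirna, .data$lncrna)

  # -- curated risk miRNAs ----------------------------------------------
  planted_mir <- unique(unlist(planted_mirna_sets, use.names = FALSE))
  decoys <- sample(setdiff(mirnas, planted_mir),
                   min(30, length(setdiff(mirnas, planted_mir))))
  curated <- sort(unique(c(planted_mir, decoys)))

  true_triples <- if (k > 0) {
    bind_rows(lapply(seq_len(k), function(i) {
      tibble(mrna = planted_mrna[i], mirna = planted_mirna_sets[[i]],
             lncrna = planted_lnc[i])
    }))
  } else tibble(mrna = character(), mirna = character(), lncrna = character())

  truth <- list(
    true_up = sort(true_up), true_down = sort(true_down),
    true_hyper = sort(true_hyper), true_hypo = sort(true_hypo),
    true_hyperlow = sort(hyperlow), true_hypohigh = sort(hypohigh),
    true_triples = true_triples)

  mat_tbl <- function(m, id) {
    out <- as_tibble(m, rownames = id)
    out
  }
  structure(list(
    expression = mat_tbl(expr, "gene_id"),
    methylation = mat_tbl(meth, "gene_id"),
    lnc_expression = mat_tbl(lnc_expr, "lncrna_id"),
    groups = groups,
    mrna_mirna = mrna_mirna,
    mirna_lncrna = mirna_lncrna,
    curated_mirnas = curated,
    truth = truth,
    config = config), class = "cerna_study")
}

#' @export
print.cerna_study <- function(x, ...) {
  cf <- x$config
  cat("Simulated ceRNA study:", cf$n_genes, "genes x",
      cf$n_case + cf$n_control, "samples (",
      cf$n_case, "case /", cf$n_control, "control )\n")
  cat("  planted: ", length(x$truth$true_up), "up,",
      length(x$truth$true_down), "down,",
      length(x$truth$true_hyper), "hyper,",
      length(x$truth$true_hypo), "hypo;",
      cf$planted_triples, "ceRNA units (rho =", cf$planted_rho, ")\n")
  cat("  interactions:", nrow(x$mrna_mirna), "mRNA-miRNA,",
      nrow(x$mirna_lncrna), "miRNA-lncRNA edges\n")
  invisible(x)
}
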