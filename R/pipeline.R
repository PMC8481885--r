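#' Run the full ceRNA biomarker pipeline
#'
#' End-to-end orchestration: differential screens of expression and
#' methylation, intersection into the two aberrant gene classes, ceRNA
#' triple inference run separately per class (each with its own miRNA
#' universe), optional restriction to curated risk miRNAs, tripartite
#' network construction with degree/betweenness, optional PPI hub
#' selection and biomarker matching, and optional gene-set
#' over-representation of each class.
#'
#' @param study A `"cerna_study"` list — from [simulate_cerna_study()] /
#'   [read_cerna_study()], or assembled by hand with the same element
#'   names (`expression`, `methylation`, `lnc_expression`, `groups`,
#'   `mrna_mirna`, `mirna_lncrna`, optional `curated_mirnas`,
#'   `meth_groups` when the methylation cohort differs).
#' @param ppi_edges Optional PPI edge tibble (two columns) for hub
#'   selection.
#' @param gene_sets Optional [read_gmt()] collection for enrichment of
#'   the aberrant classes.
#' @param p_threshold,t_threshold Differential-screen cutoffs (strict);
#'   defaults 0.05 and 2.
#' @param t_method t-statistic flavour, see [two_group_t()].
#' @param hyper_p Hypergeometric p cutoff (strict); default 0.05.
#' @param tail Hypergeometric tail convention; default `"ge"`.
#' @param pcc_threshold,fdr_threshold Co-expression cutoffs (strict);
#'   defaults 0.5 and 0.05.
#' @param hub_degree Strict PPI hub degree cutoff; default 10.
#' @param enrich_p Enrichment p cutoff; default 0.05.
#' @param restrict_curated Apply the curated-miRNA restriction when the
#'   study carries a curated list? Default `TRUE`.
#' @param outdir Optional directory; when given, every stage output plus
#'   a JSON summary is written there.
#' @return A list of class `"cerna_run"`: screen tibbles, the aberrant
#'   sets, per-class pair/triple tibbles, per-class networks and
#'   metrics, hubs, biomarker reports, enrichment tables, and a
#'   `summary` list of all counts.
#' @export
run_cerna_pipeline <- function(study,
                               ppi_edges = NULL, gene_sets = NULL,
                               p_threshold = 0.05, t_threshold = 2,
                               t_method = "student",
                               hyper_p = 0.05, tail = "ge",
                               pcc_threshold = 0.5, fdr_threshold = 0.05,
                               hub_degree = 10, enrich_p = 0.05,
                               restrict_curated = TRUE,
                               outdir = NULL) {
  stage <- function(msg) inform(paste0("[cernet] ", msg))

  stage("differential screen: expression")
  deg <- diff_screen(study$expression, study$groups, method = t_method,
                     p_threshold = p_threshold, t_threshold = t_threshold,
                     mode = "expression")
  stage("differential screen: methylation")
  meth_groups <- study$meth_groups %||% study$groups
  dmg <- diff_screen(study$methylation, meth_groups, method = t_method,
                     p_threshold = p_threshold, t_threshold = t_threshold,
                     mode = "methylation")

  stage("intersecting aberrant gene classes")
  aberrant <- intersect_aberrant(deg, dmg)

  classes <- list(hyper_low = aberrant$hyper_low,
                  hypo_high = aberrant$hypo_high)
  pairs <- list(); triples <- list(); networks <- list()
  metrics <- list(); reports <- list()

  hubs <- if (!is.null(ppi_edges)) select_hubs(ppi_edges, hub_degree) else NULL

  for (cls in names(classes)) {
    stage(paste0("ceRNA inference: ", cls, " (",
                 length(classes[[cls]]), " genes)"))
    dm <- suppressWarnings(match_dmg_mirna(classes[[cls]], study$mrna_mirna))
    pr <- cerna_pairs(dm, study$mirna_lncrna, tail = tail) %>%
      filter(.data$p_hyper < hyper_p)
    pr <- suppressWarnings(
      coexpression_filter(pr, study$expression, study$lnc_expression,
                          pcc_threshold = pcc_threshold,
                          fdr_threshold = fdr_threshold))
    tr <- pr %>%
      mutate(mirna = .data$shared_mirnas) %>%
      tidyr::unnest("mirna") %>%
      mutate(curated = NA) %>%
      select("mrna", "mirna", "lncrna", "N", "n", "m", "x", "p_hyper",
             "pcc", "fdr", "curated")
    if (restrict_curated && length(study$curated_mirnas %||% character()) > 0) {
      tr <- restrict_to_curated(tr, study$curated_mirnas)
    }
    pairs[[cls]] <- pr
    triples[[cls]] <- tr
    if (nrow(tr) > 0) {
      networks[[cls]] <- build_cerna_network(tr)
      metrics[[cls]] <- network_metrics(networks[[cls]])
      if (!is.null(hubs)) {
        reports[[cls]] <- suppressWarnings(
          biomarker_candidates(hubs, networks[[cls]], metrics[[cls]]))
      }
    }
  }

  enrichment <- NULL
  if (!is.null(gene_sets)) {
    stage("over-representation analysis")
    background <- unique(norm_gene_id(deg$feature_id))
    enrichment <- lapply(classes, function(genes) {
      if (length(genes) == 0) return(NULL)
      ora(intersect(genes, background), background, gene_sets,
          p_threshold = enrich_p)
    })
  }

  count_dir <- function(rec, d) sum(rec$direction == d)
  summary <- list(
    n_features_expression = nrow(deg),
    n_features_methylation = nrow(dmg),
    deg_up = count_dir(deg, "up"), deg_down = count_dir(deg, "down"),
    dmg_hyper = count_dir(dmg, "hyper"), dmg_hypo = count_dir(dmg, "hypo"),
    hyper_low = length(aberrant$hyper_low),
    hypo_high = length(aberrant$hypo_high),
    pairs = lapply(pairs, nrow),
    triples = lapply(triples, nrow),
    nodes = lapply(networks, function(nw) as.list(table(nw$nodes$type))),
    hubs = if (is.null(hubs)) NULL else nrow(hubs),
    top_lncrnas = lapply(metrics, function(mt) {
      head(mt$node[mt$type == "lncrna"], 5)
    }))

  run <- structure(list(deg = deg, dmg = dmg, aberrant = aberrant,
                        pairs = pairs, triples = triples,
                        networks = networks, metrics = metrics,
                        hubs = hubs, biomarkers = reports,
                        enrichment = enrichment, summary = summary,
                        params = list(p_threshold = p_threshold,
                                      t_threshold = t_threshold,
                                      t_method = t_method,
                                      hyper_p = hyper_p, tail = tail,
                                      pcc_threshold = pcc_threshold,
                                      fdr_threshold = fdr_threshold,
                                      hub_degree = hub_degree)),
                   class = "cerna_run")
  if (!is.null(outdir)) write_cerna_run(run, outdir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write every stage output of a pipeline run
#'
#' @param run A `"cerna_run"`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, `outdir`.
#' @export
write_cerna_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$deg, file.path(outdir, "differential_expression.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$dmg, file.path(outdir, "differential_methylation.tsv"),
                   progress = FALSE)
  writeLines(run$aberrant$hyper_low, file.path(outdir, "hyper_low_genes.txt"))
  writeLines(run$aberrant$hypo_high, file.path(outdir, "hypo_high_genes.txt"))
  for (cls in names(run$triples)) {
    pr <- run$pairs[[cls]]
    if (!is.null(pr) && nrow(pr) > 0) {
      flat <- mutate(pr, shared_mirnas = vapply(
        .data$shared_mirnas, paste, character(1), collapse = ","))
      readr::write_tsv(flat, file.path(outdir, paste0("pairs_", cls, ".tsv")),
                       progress = FALSE)
    }
    tr <- run$triples[[cls]]
    readr::write_tsv(tr, file.path(outdir, paste0("triples_", cls, ".tsv")),
                     progress = FALSE)
    jsonlite::write_json(as.data.frame(tr),
                         file.path(outdir, paste0("triples_", cls, ".json")),
                         auto_unbox = FALSE, digits = NA)
    if (!is.null(run$networks[[cls]])) {
      write_sif(run$networks[[cls]],
                file.path(outdir, paste0("network_", cls, ".sif")))
      write_network_graphml(run$networks[[cls]],
                            file.path(outdir, paste0("network_", cls,
                                                     ".graphml")))
      readr::write_tsv(run$metrics[[cls]],
                       file.path(outdir, paste0("metrics_", cls, ".tsv")),
                       progress = FALSE)
    }
    rep <- run$biomarkers[[cls]]
    if (!is.null(rep)) {
      readr::write_tsv(rep$table,
                       file.path(outdir, paste0("biomarkers_", cls, ".tsv")),
                       progress = FALSE)
    }
  }
  if (!is.null(run$enrichment)) {
    for (cls in names(run$enrichment)) {
      if (!is.null(run$enrichment[[cls]])) {
        readr::write_tsv(run$enrichment[[cls]],
                         file.path(outdir, paste0("enrichment_", cls, ".tsv")),
                         progress = FALSE)
      }
    }
  }
  jsonlite::write_json(run$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.cerna_run <- function(x, ...) {
  s <- x$summary
  cat("ceRNA pipeline run\n")
  cat("  DEGs:", s$deg_up, "up /", s$deg_down, "down;",
      "DMGs:", s$dmg_hyper, "hyper /", s$dmg_hypo, "hypo\n")
  cat("  aberrant classes:", s$hyper_low, "hyper-low,",
      s$hypo_high, "hypo-high genes\n")
  for (cls in names(x$triples)) {
    cat("  ", cls, ": ", nrow(x$pairs[[cls]]), " pairs, ",
        nrow(x$triples[[cls]]), " triples\n", sep = "")
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#' @param x A `"cerna_run"`.
#' @param ... Unused.
#' @return One-row tibble of headline counts.
#' @export
glance.cerna_run <- function(x, ...) {
  s <- x$summary
  tibble(deg_up = s$deg_up, deg_down = s$deg_down,
         dmg_hyper = s$dmg_hyper, dmg_hypo = s$dmg_hypo,
         hyper_low = s$hyper_low, hypo_high = s$hypo_high,
         triples_hyper_low = s$triples$hyper_low %||% 0L,
         triples_hypo_high = s$triples$hypo_high %||% 0L)
}

#' Tidy the triples of a pipeline run
#' @param x A `"cerna_run"`.
#' @param ... Unused.
#' @return All triples in one tibble with a `class` column.
#' @export
tidy.cerna_run <- function(x, ...) {
  bind_rows(lapply(names(x$triples), function(cls) {
    mutate(x$triples[[cls]], class = cls)
  }))
}
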