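#' Intersect methylation and expression calls into aberrant gene classes
#'
#' The two classes at the heart of the analysis:
#' hypermethylated/low-expression genes (called `hyper` in the
#' methylation screen and `down` in the expression screen) and
#' hypomethylated/high-expression genes (`hypo` and `up`). Membership is
#' by exact symbol match after uppercasing and whitespace stripping;
#' genes present in only one screen are silently non-members.
#'
#' @param expression_calls,methylation_calls Classified record tibbles
#'   from [diff_screen()] (expression and methylation modes
#'   respectively), sharing a gene-symbol namespace.
#' @return A list of class `"aberrant_gene_sets"` with sorted character
#'   vectors `hyper_low` and `hypo_high`.
#' @export
intersect_aberrant <- function(expression_calls, methylation_calls) {
  pick <- function(calls, dir) {
    sort(unique(norm_gene_id(calls$feature_id[calls$direction == dir])))
  }
  hyper_low <- intersect(pick(methylation_calls, "hyper"),
                         pick(expression_calls, "down"))
  hypo_high <- intersect(pick(methylation_calls, "hypo"),
                         pick(expression_calls, "up"))
  # A gene cannot be both up and down in one expression screen, so the
  # classes are disjoint by construction; guard anyway.
  check_that(length(intersect(hyper_low, hypo_high)) == 0,
             "aberrant classes overlap: inconsistent input calls")
  structure(list(hyper_low = hyper_low, hypo_high = hypo_high),
            class = "aberrant_gene_sets")
}

#' @export
print.aberrant_gene_sets <- function(x, ...) {
  cat("Aberrantly methylated-differentially expressed gene classes:\n")
  cat("  hypermethylated / low expression :", length(x$hyper_low), "genes\n")
  cat("  hypomethylated / high expression :", length(x$hypo_high), "genes\n")
  invisible(x)
}
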