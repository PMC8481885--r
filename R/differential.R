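#' Two-group t-statistics per feature
#'
#' Computes a signed t-statistic (positive = higher in cases) and a
#' two-sided p-value for every feature of a feature x sample matrix.
#' Three flavours are available: `"student"` (pooled-variance two-sample
#' t, the self-contained default), `"welch"` (unequal variances,
#' Satterthwaite degrees of freedom), and `"moderated"` (limma's
#' empirical-Bayes moderated t, matching the statistic GEO2R reports for
#' microarray series).
#'
#' Missing cells are allowed: each feature uses its available samples,
#' and features with fewer than 3 observed values in either group are
#' dropped with a warning. A feature with zero variance in both groups
#' and equal means gets `t = 0`, `p = 1` with a warning. Duplicate
#' feature identifiers (e.g. multiple probes per gene symbol) are
#' collapsed to the record with the smallest p-value.
#'
#' @param mat Data frame, first column the feature identifier, remaining
#'   columns numeric sample values; or a numeric matrix with feature
#'   rownames.
#' @param groups Data frame with columns `sample_id` and `group`
#'   (`"case"`/`"control"`) covering every sample column of `mat`.
#' @param method `"student"`, `"welch"` or `"moderated"`.
#' @return Tibble with columns `feature_id`, `t`, `df`, `p`, `direction`
#'   (all `"none"`; see [classify_differential()]).
#' @export
two_group_t <- function(mat, groups,
                        method = c("student", "welch", "moderated")) {
  method <- match.arg(method)
  m <- if (is.matrix(mat)) mat else as_feature_matrix(mat)
  check_that(all(c("sample_id", "group") %in% names(groups)),
             "`groups` needs columns `sample_id` and `group`")
  check_that(all(colnames(m) %in% groups$sample_id),
             "every sample column must have a group label")
  lab <- setNames(groups$group, groups$sample_id)[colnames(m)]
  check_that(all(lab %in% c("case", "control")),
             "group labels must be 'case' or 'control'")
  check_that(sum(lab == "case") >= 3 && sum(lab == "control") >= 3,
             "need at least 3 samples per group")

  x1 <- m[, lab == "case", drop = FALSE]
  x2 <- m[, lab == "control", drop = FALSE]

  if (method == "moderated") {
    res <- moderated_t(m, lab)
  } else {
    n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
    usable <- n1 >= 3 & n2 >= 3
    if (any(!usable)) {
      warn(sprintf("%d feature(s) with < 3 observed values per group skipped",
                   sum(!usable)))
    }
    m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
    v1 <- rowSums((x1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
    v2 <- rowSums((x2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
    if (method == "student") {
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    } else {
      se <- sqrt(v1 / n1 + v2 / n2)
      df <- (v1 / n1 + v2 / n2)^2 /
        (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
    }
    tt <- (m1 - m2) / se
    degenerate <- is.finite(m1) & is.finite(m2) & se == 0 & m1 == m2
    if (any(degenerate & usable)) {
      warn(sprintf("%d feature(s) with zero variance and equal means: t set to 0, p to 1",
                   sum(degenerate & usable)))
      tt[degenerate] <- 0
      df[degenerate] <- n1[degenerate] + n2[degenerate] - 2
    }
    p <- 2 * pt(-abs(tt), df)
    p[degenerate] <- 1
    res <- tibble(feature_id = rownames(m), t = unname(tt),
                  df = unname(df), p = unname(p))[usable, ]
  }

  res %>%
    mutate(direction = "none") %>%
    group_by(.data$feature_id) %>%
    slice_min(.data$p, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    arrange(match(.data$feature_id, rownames(m)))
}

# limma lmFit + eBayes on a case/control design; returns the moderated t
# for the case-minus-control coefficient.
moderated_t <- function(m, lab) {
  if (!requireNamespace("limma", quietly = TRUE)) {
    abort("method = 'moderated' requires the limma package")
  }
  design <- cbind(Intercept = 1, case = as.numeric(lab == "case"))
  fit <- limma::eBayes(limma::lmFit(m, design))
  tibble(feature_id = rownames(m),
         t = fit$t[, "case"],
         df = unname(fit$df.total),
         p = fit$p.value[, "case"])
}

#' Classify features as differential by statistic cutoffs
#'
#' Applies the screening rule `p < p_threshold` and `|t| > t_threshold`
#' (both strict): features with `t` above the threshold are called
#' `"up"` (expression mode) or `"hyper"` (methylation mode), below the
#' negated threshold `"down"`/`"hypo"`, and `"none"` otherwise. The
#' operation is idempotent.
#'
#' @param records Tibble from [two_group_t()].
#' @param p_threshold,t_threshold Strict cutoffs; defaults 0.05 and 2.
#' @param mode `"expression"` or `"methylation"` (names the direction
#'   labels).
#' @return The records with `direction` filled in.
#' @export
classify_differential <- function(records, p_threshold = 0.05,
                                  t_threshold = 2,
                                  mode = c("expression", "methylation")) {
  mode <- match.arg(mode)
  check_that(p_threshold > 0 && t_threshold > 0, "thresholds must be > 0")
  pos <- if (mode == "expression") "up" else "hyper"
  neg <- if (mode == "expression") "down" else "hypo"
  records %>%
    mutate(direction = dplyr::case_when(
      .data$p < p_threshold & .data$t > t_threshold ~ pos,
      .data$p < p_threshold & .data$t < -t_threshold ~ neg,
      TRUE ~ "none"))
}

#' Differential screen in one call
#'
#' Convenience wrapper: [two_group_t()] followed by
#' [classify_differential()].
#'
#' @inheritParams two_group_t
#' @inheritParams classify_differential
#' @return Classified record tibble.
#' @export
diff_screen <- function(mat, groups, method = "student",
                        p_threshold = 0.05, t_threshold = 2,
                        mode = c("expression", "methylation")) {
  two_group_t(mat, groups, method) %>%
    classify_differential(p_threshold, t_threshold, mode)
}
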