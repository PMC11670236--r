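# Plasma-cell gating, dual-percentile malignant/nonmalignant classification,
# compound-score distributions and treated-vs-untreated comparisons.

#' Plasma-cell gate rule
#'
#' Cells are gated in when at least one `required_any` gene exceeds
#' `min_expression` and every `excluded` gene is at or below it. Defaults
#' follow the canonical plasma-cell definition: Sdc1, Xbp1 or Prdm1 positive
#' and Cd19 negative.
#'
#' @param required_any Genes of which at least one must be expressed.
#' @param excluded Genes that must not be expressed.
#' @param min_expression Log-normalized expression threshold.
#' @return A `gate_rule` object.
#' @export
gate_rule <- function(required_any = c("Sdc1", "Xbp1", "Prdm1"),
                      excluded = "Cd19",
                      min_expression = 0) {
  if (length(required_any) == 0) abort("required_any must be nonempty")
  structure(
    list(required_any = required_any, excluded = excluded, min_expression = min_expression),
    class = "gate_rule"
  )
}

#' Gate plasma cells
#'
#' @param x An [expr_matrix()] with `layer = "lognorm"`.
#' @param rule A [gate_rule()]. Rule genes absent from the matrix warn and are
#'   skipped.
#' @return The gated [expr_matrix()] subset; gated barcodes in attribute
#'   `"cells"`. An empty gate warns (downstream steps should be skipped).
#' @export
gate_plasma_cells <- function(x, rule = gate_rule()) {
  stopifnot(inherits(x, "expr_matrix"), inherits(rule, "gate_rule"))
  if (x$layer != "lognorm") abort("gate_plasma_cells expects log-normalized input")
  counts <- x$counts
  genes <- rownames(counts)
  req <- intersect(rule$required_any, genes)
  exc <- intersect(rule$excluded, genes)
  absent <- setdiff(c(rule$required_any, rule$excluded), genes)
  if (length(absent) > 0) {
    warn(paste("gate genes absent from matrix, skipped:", paste(absent, collapse = ", ")))
  }
  if (length(req) == 0) abort("none of the required gate genes are present")
  has_req <- Matrix::colSums(counts[req, , drop = FALSE] > rule$min_expression) > 0
  no_exc <- if (length(exc) > 0) {
    Matrix::colSums(counts[exc, , drop = FALSE] > rule$min_expression) == 0
  } else {
    rep(TRUE, ncol(counts))
  }
  keep <- has_req & no_exc
  if (!any(keep)) {
    warn("gate returned no cells")
  }
  out <- structure(
    list(counts = counts[, keep, drop = FALSE], layer = x$layer),
    class = "expr_matrix"
  )
  attr(out, "cells") <- colnames(counts)[keep]
  out
}

#' Dual-percentile malignancy classification
#'
#' A cell is labeled `malignant` when its malignant score is at or above the
#' upper quantile and its nonmalignant score at or below the lower quantile;
#' `nonmalignant` under the mirrored condition; `unclassified` otherwise.
#' Quantiles are computed over all cells in `scores` (linear interpolation
#' between order statistics, R type 7); comparisons are inclusive.
#'
#' @param scores Score table from [score_cells()] (>= 5 rows).
#' @param upper_quantile,lower_quantile Quantile cutpoints (defaults 0.80 and
#'   0.20: top and bottom 20 percent).
#' @param by_sample If `TRUE`, quantiles are computed within each `sample_id`
#'   instead of pooled over the analysis.
#' @return `scores` with a `label` factor column added.
#' @export
classify_cells <- function(scores, upper_quantile = 0.80, lower_quantile = 0.20,
                           by_sample = FALSE) {
  stopifnot(lower_quantile > 0, upper_quantile < 1, lower_quantile < upper_quantile)
  scores <- as_tibble(scores)
  if (nrow(scores) < 5) abort("need at least 5 cells to classify (quantiles meaningless below)")
  label_block <- function(df) {
    m_hi <- quantile(df$malignant_score, upper_quantile, type = 7, names = FALSE)
    m_lo <- quantile(df$malignant_score, lower_quantile, type = 7, names = FALSE)
    n_hi <- quantile(df$nonmalignant_score, upper_quantile, type = 7, names = FALSE)
    n_lo <- quantile(df$nonmalignant_score, lower_quantile, type = 7, names = FALSE)
    dplyr::mutate(df, label = dplyr::case_when(
      malignant_score >= m_hi & nonmalignant_score <= n_lo ~ "malignant",
      malignant_score <= m_lo & nonmalignant_score >= n_hi ~ "nonmalignant",
      TRUE ~ "unclassified"
    ))
  }
  out <- if (by_sample) {
    if (!("sample_id" %in% names(scores))) abort("by_sample = TRUE requires a sample_id column")
    scores |> dplyr::group_by(.data$sample_id) |> dplyr::group_modify(~ label_block(.x)) |> dplyr::ungroup()
  } else {
    label_block(scores)
  }
  out$label <- factor(out$label, levels = c("malignant", "nonmalignant", "unclassified"))
  out
}

#' Compound-score histogram
#'
#' Bins compound scores into half-open intervals `[k*w, (k+1)*w)` anchored at
#' zero. Frequencies are percentages within each group (summing to 100 per
#' group) when a `group` column is present, else over all cells.
#'
#' @param scores Score table with a `compound_score` column.
#' @param bin_width Histogram bin width (default 0.2).
#' @return Tibble with `group` (if present), `bin_left`, `bin_right`, `n`, `pct`.
#' @export
compound_distribution <- function(scores, bin_width = 0.2) {
  stopifnot(bin_width > 0)
  scores <- as_tibble(scores)
  scores$.bin <- floor(scores$compound_score / bin_width)
  grouping <- if ("group" %in% names(scores)) c("group", ".bin") else ".bin"
  out <- scores |>
    dplyr::count(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::group_by(dplyr::across(dplyr::any_of("group"))) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      bin_left = .data$.bin * bin_width,
      bin_right = (.data$.bin + 1) * bin_width
    ) |>
    dplyr::select(dplyr::any_of("group"), "bin_left", "bin_right", "n", "pct")
  out
}

#' Compare compound scores between treated and untreated groups
#'
#' Two-tailed Mann-Whitney test on per-cell compound scores between the two
#' groups, plus per-sample malignant-cell frequencies (malignant labels over
#' gated cells).
#'
#' @param scores Labeled score table ([classify_cells()]) with `group` and
#'   (optionally) `sample_id` columns; exactly two groups, each with >= 2 cells.
#' @return List with `test` (a [surveil_test][new_surveil_test]) and
#'   `sample_freq` (tibble of per-sample malignant frequencies).
#' @export
compare_groups <- function(scores) {
  scores <- as_tibble(scores)
  if (!("group" %in% names(scores))) abort("scores must have a group column")
  split_scores <- split(scores$compound_score, scores$group)
  if (length(split_scores) != 2) abort("need exactly two groups")
  if (any(lengths(split_scores) < 2)) abort("each group needs at least 2 observations")
  test <- mann_whitney(split_scores[[1]], split_scores[[2]])
  sample_freq <- NULL
  if (all(c("sample_id", "label") %in% names(scores))) {
    sample_freq <- scores |>
      dplyr::group_by(.data$group, .data$sample_id) |>
      dplyr::summarise(
        n_gated = dplyr::n(),
        n_malignant = sum(.data$label == "malignant"),
        malignant_freq = .data$n_malignant / .data$n_gated,
        .groups = "drop"
      )
  }
  list(test = test, sample_freq = sample_freq)
}

#' Per-gene differential expression between two groups
#'
#' Two-tailed rank-sum p per gene (tie-corrected normal approximation),
#' Benjamini-Hochberg adjustment and log2 fold change of group mean
#' normalized expression. Constant genes get p = 1 and are flagged.
#'
#' @param x An [expr_matrix()] with `layer = "lognorm"`.
#' @param groups Factor/character vector of length `n_cells(x)` with two
#'   levels (>= 3 cells each), or a named vector keyed by barcode.
#' @param alpha_levels Adjusted-p thresholds to tally (attribute
#'   `"n_significant"`).
#' @return Tibble with `gene`, `log2_fc`, `p_value`, `p_adjusted`, `constant`.
#'   Positive `log2_fc` means higher in the first group level.
#' @export
differential_expression <- function(x, groups, alpha_levels = c(0.001, 0.05)) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$layer != "lognorm") abort("differential_expression expects log-normalized input")
  counts <- x$counts
  if (!is.null(names(groups))) groups <- groups[colnames(counts)]
  groups <- factor(groups)
  if (nlevels(groups) != 2) abort("need exactly two groups")
  if (any(table(groups) < 3)) abort("each group needs at least 3 cells")
  ga <- groups == levels(groups)[1]
  n1 <- sum(ga); n2 <- sum(!ga); N <- n1 + n2
  dense <- as.matrix(counts)
  ranks <- t(apply(dense, 1, rank))
  w <- rowSums(ranks[, ga, drop = FALSE])
  u <- w - n1 * (n1 + 1) / 2
  tie_term <- apply(ranks, 1, function(r) {
    tt <- table(r)
    sum(tt^3 - tt)
  })
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term / (N * (N - 1)))
  z <- u - n1 * n2 / 2
  z <- ifelse(sigma2 > 0, (z - sign(z) * 0.5) / sqrt(sigma2), 0)
  p <- ifelse(sigma2 > 0, pmin(1, 2 * pnorm(-abs(z))), 1)
  constant <- sigma2 <= 0
  mean_a <- rowMeans(expm1(dense[, ga, drop = FALSE]))
  mean_b <- rowMeans(expm1(dense[, !ga, drop = FALSE]))
  lfc <- log2((mean_a + 1) / (mean_b + 1))
  out <- tibble(
    gene = rownames(counts),
    log2_fc = unname(lfc),
    p_value = unname(p),
    p_adjusted = unname(bh_fdr(p)),
    constant = unname(constant)
  )
  attr(out, "n_significant") <- tibble(
    alpha = alpha_levels,
    n_genes = vapply(alpha_levels, function(a) sum(out$p_adjusted < a), integer(1))
  )
  attr(out, "groups") <- levels(groups)
  out
}
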