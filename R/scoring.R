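# QC filtering, log-normalization and gene-set module scoring with
# expression-binned control genes.

#' Filter cells on counts, detected genes and mitochondrial fraction
#'
#' Keeps cells with total counts >= `min_counts`, detected genes >=
#' `min_genes` and mitochondrial percentage <= `max_pct_mito`. Mitochondrial
#' genes are identified by symbol prefix. The numbers removed per criterion
#' are attached as attribute `"qc_removed"`.
#'
#' @param x An [expr_matrix()] with raw counts.
#' @param min_counts,min_genes,max_pct_mito QC thresholds.
#' @param mito_prefix Gene-symbol prefix marking mitochondrial genes.
#' @return Filtered [expr_matrix()].
#' @export
qc_filter <- function(x, min_counts = 0, min_genes = 0, max_pct_mito = 100,
                      mito_prefix = "mt-") {
  stopifnot(inherits(x, "expr_matrix"), x$layer == "raw")
  counts <- x$counts
  totals <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  mito_rows <- startsWith(rownames(counts), mito_prefix)
  pct_mito <- if (any(mito_rows)) {
    m <- Matrix::colSums(counts[mito_rows, , drop = FALSE])
    ifelse(totals > 0, 100 * m / totals, 0)
  } else {
    rep(0, length(totals))
  }
  pass_counts <- totals >= min_counts
  pass_genes <- detected >= min_genes
  pass_mito <- pct_mito <= max_pct_mito
  keep <- pass_counts & pass_genes & pass_mito
  if (!any(keep)) abort("all cells removed by QC; review thresholds")
  out <- expr_matrix(counts[, keep, drop = FALSE], layer = "raw")
  attr(out, "qc_removed") <- c(
    low_counts = sum(!pass_counts),
    low_genes = sum(!pass_genes),
    high_mito = sum(!pass_mito),
    total_removed = sum(!keep)
  )
  out
}

#' Log-normalize counts
#'
#' Scales each cell to `scale_factor` total counts, then applies `log(1 + x)`.
#' All-zero cells are left all-zero with a warning.
#'
#' @param x An [expr_matrix()] with raw counts.
#' @param scale_factor Target total per cell (default 10,000).
#' @return An [expr_matrix()] with `layer = "lognorm"`.
#' @export
log_normalize <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "expr_matrix"), x$layer == "raw")
  counts <- x$counts
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) warn(sprintf("%d all-zero cell(s) left as zero", sum(totals == 0)))
  scale <- ifelse(totals > 0, scale_factor / totals, 0)
  out <- counts %*% Matrix::Diagonal(x = scale)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  expr_matrix(out, layer = "lognorm")
}

#' Gene-set module score with expression-binned control genes
#'
#' Genes are ranked by mean expression over all cells and cut into `n_bins`
#' equal-size bins (ties broken by gene order). For each set gene, `n_ctrl`
#' control genes are sampled without replacement from its bin, excluding all
#' set genes (with replacement, with a warning, when the bin is too small).
#' The per-cell score is the mean expression of the set genes minus the mean
#' over the full multiset of sampled controls. Sampling is driven by `seed`,
#' so scores are reproducible.
#'
#' With `n_bins = 1` and `n_ctrl` equal to the number of non-set genes, the
#' score reduces exactly to (set mean - non-set mean).
#'
#' @param x An [expr_matrix()] with `layer = "lognorm"`.
#' @param gene_set A [gene_set()] (genes absent from the matrix are ignored;
#'   an error is thrown if none are present).
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Controls sampled per set gene (default 100).
#' @param seed Integer seed for the control-sampling stream.
#' @return Tibble with `cell_id` and `score`.
#' @export
module_score <- function(x, gene_set, n_bins = 24, n_ctrl = 100, seed = 0) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$layer != "lognorm") abort("module_score expects log-normalized input")
  stopifnot(inherits(gene_set, "gene_set"), n_bins >= 1, n_ctrl >= 1)
  counts <- x$counts
  genes <- rownames(counts)
  set_genes <- intersect(gene_set$genes, genes)
  if (length(set_genes) == 0) {
    abort(paste0(
      "no genes of set '", gene_set$name, "' present in the matrix; missing: ",
      paste(head(gene_set$genes, 10), collapse = ", ")
    ))
  }
  avg <- Matrix::rowMeans(counts)
  ord <- order(avg) # stable: ties keep gene-list order
  bin_of_sorted <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  bin <- integer(length(genes))
  bin[ord] <- pmin(bin_of_sorted, n_bins)
  names(bin) <- genes
  ctrl_idx <- withr::with_seed(seed, {
    unlist(lapply(set_genes, function(g) {
      candidates <- which(bin == bin[[g]] & !(genes %in% gene_set$genes))
      if (length(candidates) == 0) {
        warn(sprintf("no control candidates in bin of gene %s; gene skipped in controls", g))
        return(integer(0))
      }
      if (length(candidates) < n_ctrl) {
        warn(sprintf(
          "bin of gene %s has %d candidates < n_ctrl = %d; sampling with replacement",
          g, length(candidates), n_ctrl
        ))
        sample(candidates, n_ctrl, replace = TRUE)
      } else {
        sample(candidates, n_ctrl, replace = FALSE)
      }
    }))
  })
  set_mean <- Matrix::colMeans(counts[set_genes, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(counts[ctrl_idx, , drop = FALSE])
  tibble(cell_id = colnames(counts), score = as.numeric(set_mean - ctrl_mean))
}

#' Score cells with the malignant and nonmalignant signatures
#'
#' Computes both module scores and the compound score in one call. By the
#' package convention the compound score is malignant minus nonmalignant
#' (higher = more malignant); `compound_sign = -1` flips it.
#'
#' @inheritParams module_score
#' @param malignant_set,nonmalignant_set [gene_set()] objects.
#' @param annotation Optional tibble with `cell_id`, `sample_id`, `group`
#'   columns to join onto the result.
#' @param compound_sign `1` for malignant - nonmalignant (default), `-1` for
#'   the reverse subtraction.
#' @return A score table: tibble with `cell_id`, `malignant_score`,
#'   `nonmalignant_score`, `compound_score` (plus annotation columns if given).
#' @export
score_cells <- function(x, malignant_set, nonmalignant_set, annotation = NULL,
                        n_bins = 24, n_ctrl = 100, seed = 0, compound_sign = 1) {
  stopifnot(compound_sign %in% c(1, -1))
  mal <- module_score(x, malignant_set, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  nonmal <- module_score(x, nonmalignant_set, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed + 1)
  out <- tibble(
    cell_id = mal$cell_id,
    malignant_score = mal$score,
    nonmalignant_score = nonmal$score,
    compound_score = compound_sign * (mal$score - nonmal$score)
  )
  if (!is.null(annotation)) {
    out <- dplyr::left_join(out, as_tibble(annotation), by = "cell_id")
  }
  out
}
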