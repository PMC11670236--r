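# End-to-end orchestration: simulate -> QC/normalize -> gate -> score ->
# classify -> repertoire -> statistics -> report, with per-stage file
# interfaces for command-line use.

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full surveillance pipeline on simulated data
#'
#' Executes every stage on data drawn from `cfg` and writes the result bundle
#' to `out_dir`: labeled score CSV, compound-score histogram CSV, differential
#' expression CSV, clone table CSV, isotype / V-family / CDR3-length / V-J /
#' W33L / clone-size tables, logo matrices, and `summary.json` holding every
#' test report, the parameters and the seed. Identical config + seed give an
#' identical bundle.
#'
#' @param cfg A [sim_config()] (or path to its YAML form).
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param qc Named list of QC thresholds
#'   (`min_counts`, `min_genes`, `max_pct_mito`).
#' @param scoring Named list of scoring parameters (`n_bins`, `n_ctrl`).
#' @param classification Named list with `upper_quantile`, `lower_quantile`,
#'   `hist_bin_width`.
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(cfg, out_dir = NULL,
                         qc = list(min_counts = 200, min_genes = 50, max_pct_mito = 20),
                         scoring = list(n_bins = 10, n_ctrl = 30),
                         classification = list(upper_quantile = 0.80,
                                               lower_quantile = 0.20,
                                               hist_bin_width = 0.2)) {
  if (is.character(cfg)) cfg <- read_sim_config(cfg)
  stopifnot(inherits(cfg, "sim_config"))

  sim <- run_stage("simulate_expression", simulate_expression(cfg))
  rep_sim <- run_stage("simulate_repertoire", simulate_repertoire(cfg, sim$annotation))

  filtered <- run_stage("qc_filter", qc_filter(
    sim$expression, min_counts = qc$min_counts,
    min_genes = qc$min_genes, max_pct_mito = qc$max_pct_mito
  ))
  lognorm <- run_stage("log_normalize", log_normalize(filtered))
  gated <- run_stage("gate_plasma_cells", gate_plasma_cells(lognorm))

  scores <- run_stage("score_cells", score_cells(
    gated, sim$gene_sets$malignant, sim$gene_sets$nonmalignant,
    annotation = sim$annotation,
    n_bins = scoring$n_bins, n_ctrl = scoring$n_ctrl, seed = cfg$seed + 404L
  ))
  labeled <- run_stage("classify_cells", classify_cells(
    scores, upper_quantile = classification$upper_quantile,
    lower_quantile = classification$lower_quantile
  ))
  hist_tbl <- run_stage("compound_distribution",
                        compound_distribution(labeled, classification$hist_bin_width))
  comparison <- run_stage("compare_groups", compare_groups(labeled))
  de <- run_stage("differential_expression",
                  differential_expression(lognorm, setNames(
                    sim$annotation$group, sim$annotation$cell_id
                  )))

  rearr <- run_stage("assign_clonotypes",
                     assign_clonotypes(add_mutation_stats(rep_sim$rearrangements)))
  clones <- run_stage("clone_table", clone_table(rearr))
  mutated <- run_stage("mutated_clonotype_frequency", mutated_clonotype_frequency(rearr))
  isotypes <- run_stage("isotype_frequencies", isotype_frequencies(rearr))
  vfam <- run_stage("v_family_frequencies", v_family_frequencies(rearr))
  vj <- run_stage("vj_matrix", vj_matrix(rearr))
  cdr3 <- run_stage("cdr3_length_distribution", cdr3_length_distribution(rearr, by = "group"))
  vh172 <- run_stage("vh1_72_analysis", vh1_72_analysis(rearr))
  csizes <- run_stage("clone_size_stats", clone_size_stats(rearr))
  logos <- run_stage("kl_logo", {
    win <- vh172$records |> dplyr::filter(.data$window_ok)
    lapply(split(win, win$group), function(df) {
      kl_logo(substr(df$sequence_alignment, df$cdr1_start[1], df$cdr1_end[1]))
    })
  })

  result <- list(
    config = cfg, sim = sim, repertoire_sim = rep_sim,
    lognorm = lognorm, scores = labeled, compound_hist = hist_tbl,
    comparison = comparison, de = de,
    rearrangements = rearr, clones = clones,
    mutated_clonotypes = mutated, isotypes = isotypes,
    v_families = vfam, vj = vj, cdr3 = cdr3, vh1_72 = vh172,
    clone_sizes = csizes, logos = logos
  )
  if (!is.null(out_dir)) write_bundle(result, out_dir)
  invisible(result)
}

write_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$scores, file.path(out_dir, "scores.csv"), progress = FALSE)
  readr::write_csv(result$compound_hist, file.path(out_dir, "compound_histogram.csv"), progress = FALSE)
  readr::write_csv(result$de, file.path(out_dir, "differential_expression.csv"), progress = FALSE)
  readr::write_csv(
    dplyr::select(result$clones, -"isotype_counts"),
    file.path(out_dir, "clones.csv"), progress = FALSE
  )
  readr::write_csv(result$mutated_clonotypes, file.path(out_dir, "mutated_clonotypes.csv"), progress = FALSE)
  readr::write_csv(result$isotypes, file.path(out_dir, "isotype_frequencies.csv"), progress = FALSE)
  readr::write_csv(result$v_families, file.path(out_dir, "v_family_frequencies.csv"), progress = FALSE)
  readr::write_csv(result$vj, file.path(out_dir, "vj_pairs.csv"), progress = FALSE)
  readr::write_csv(result$cdr3$distribution, file.path(out_dir, "cdr3_lengths.csv"), progress = FALSE)
  readr::write_csv(result$vh1_72$usage, file.path(out_dir, "vh1_72_usage.csv"), progress = FALSE)
  readr::write_csv(result$clone_sizes$clones, file.path(out_dir, "clone_sizes.csv"), progress = FALSE)
  for (grp in names(result$logos)) {
    readr::write_csv(tidy(result$logos[[grp]]),
                     file.path(out_dir, paste0("logo_", grp, ".csv")), progress = FALSE)
  }
  summary <- list(
    seed = result$config$seed,
    parameters = result$config[setdiff(names(result$config), "seed")],
    scoring_layer = "lognorm",
    tests = list(
      compound_mann_whitney = as.list(tidy(result$comparison$test)),
      w33l_fisher = if (!is.null(result$vh1_72$test)) as.list(tidy(result$vh1_72$test)),
      clone_size_mann_whitney = if (!is.null(result$clone_sizes$test)) {
        as.list(tidy(result$clone_sizes$test))
      }
    ),
    de_significant = attr(result$de, "n_significant"),
    cdr3_summary = result$cdr3$summary,
    vh1_72_group_usage = result$vh1_72$usage |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(mean_usage = mean(.data$usage), .groups = "drop")
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(out_dir)
}

#' File-based pipeline stages
#'
#' Thin wrappers exposing the pipeline stage by stage over files, used by the
#' bundled command-line script: `pipeline_simulate()` writes an MTX directory,
#' annotation CSV, AIRR TSV, gene-set files and truth tables;
#' `pipeline_score()` scores a written MTX directory against gene-set files;
#' `pipeline_classify()` labels a score CSV; `pipeline_repertoire()` analyses
#' an AIRR TSV; `pipeline_stats()` runs the group comparisons on stage
#' outputs; `pipeline_report()` stitches existing stage outputs into
#' `summary.json` without recomputation.
#'
#' @param cfg A [sim_config()] or YAML path.
#' @param out_dir Directory for stage outputs.
#' @return The output directory (invisibly).
#' @export
pipeline_simulate <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- read_sim_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_expression(cfg)
  rep_sim <- simulate_repertoire(cfg, sim$annotation)
  write_mtx_dir(sim$expression, file.path(out_dir, "mtx"))
  readr::write_csv(sim$annotation, file.path(out_dir, "annotation.csv"), progress = FALSE)
  readr::write_csv(sim$truth, file.path(out_dir, "truth_cells.csv"), progress = FALSE)
  write_airr(rep_sim$rearrangements, file.path(out_dir, "rearrangements.tsv"))
  readr::write_csv(rep_sim$truth, file.path(out_dir, "truth_repertoire.csv"), progress = FALSE)
  write_gene_set(sim$gene_sets$malignant, file.path(out_dir, "malignant_set.txt"))
  write_gene_set(sim$gene_sets$nonmalignant, file.path(out_dir, "nonmalignant_set.txt"))
  invisible(out_dir)
}

#' @rdname pipeline_simulate
#' @param mtx_dir MTX directory ([write_mtx_dir()] layout).
#' @param malignant_path,nonmalignant_path Gene-set files.
#' @param annotation_path Optional annotation CSV to join.
#' @param out_csv Output CSV path.
#' @param seed Seed for control-gene sampling.
#' @export
pipeline_score <- function(mtx_dir, malignant_path, nonmalignant_path,
                           out_csv, annotation_path = NULL, seed = 0) {
  x <- log_normalize(read_mtx_dir(mtx_dir))
  gated <- gate_plasma_cells(x)
  ann <- if (!is.null(annotation_path)) readr::read_csv(annotation_path, show_col_types = FALSE)
  scores <- score_cells(
    gated,
    read_gene_set(malignant_path, "malignant"),
    read_gene_set(nonmalignant_path, "nonmalignant"),
    annotation = ann, seed = seed
  )
  write_scores(scores, out_csv)
  invisible(out_csv)
}

#' @rdname pipeline_simulate
#' @param scores_csv Score CSV from `pipeline_score()`.
#' @export
pipeline_classify <- function(scores_csv, out_csv,
                              upper_quantile = 0.80, lower_quantile = 0.20) {
  scores <- readr::read_csv(scores_csv, show_col_types = FALSE)
  write_scores(classify_cells(scores, upper_quantile, lower_quantile), out_csv)
  invisible(out_csv)
}

#' @rdname pipeline_simulate
#' @param airr_path AIRR rearrangement TSV.
#' @export
pipeline_repertoire <- function(airr_path, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  parsed <- read_airr(airr_path)
  rearr <- assign_clonotypes(add_mutation_stats(parsed$rearrangements))
  readr::write_csv(dplyr::select(clone_table(rearr), -"isotype_counts"),
                   file.path(out_dir, "clones.csv"), progress = FALSE)
  readr::write_csv(mutated_clonotype_frequency(rearr),
                   file.path(out_dir, "mutated_clonotypes.csv"), progress = FALSE)
  readr::write_csv(isotype_frequencies(rearr),
                   file.path(out_dir, "isotype_frequencies.csv"), progress = FALSE)
  readr::write_csv(v_family_frequencies(rearr),
                   file.path(out_dir, "v_family_frequencies.csv"), progress = FALSE)
  readr::write_csv(vj_matrix(rearr), file.path(out_dir, "vj_pairs.csv"), progress = FALSE)
  readr::write_csv(cdr3_length_distribution(rearr)$distribution,
                   file.path(out_dir, "cdr3_lengths.csv"), progress = FALSE)
  readr::write_csv(vh1_72_analysis(rearr)$usage,
                   file.path(out_dir, "vh1_72_usage.csv"), progress = FALSE)
  invisible(out_dir)
}

#' @rdname pipeline_simulate
#' @param labeled_csv Labeled score CSV from `pipeline_classify()`.
#' @param out_json Output JSON path.
#' @export
pipeline_stats <- function(labeled_csv, out_json) {
  labeled <- readr::read_csv(labeled_csv, show_col_types = FALSE)
  cmp <- compare_groups(labeled)
  jsonlite::write_json(
    list(compound_mann_whitney = as.list(tidy(cmp$test)), sample_freq = cmp$sample_freq),
    out_json, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_json)
}

#' @rdname pipeline_simulate
#' @param stage_dir Directory holding earlier stage outputs.
#' @export
pipeline_report <- function(stage_dir, out_json = file.path(stage_dir, "summary.json")) {
  files <- list.files(stage_dir, pattern = "\\.csv$", full.names = TRUE)
  summary <- lapply(setNames(files, sub("\\.csv$", "", basename(files))), function(f) {
    df <- readr::read_csv(f, show_col_types = FALSE)
    list(rows = nrow(df), columns = names(df))
  })
  jsonlite::write_json(summary, out_json, auto_unbox = TRUE, pretty = TRUE)
  invisible(out_json)
}
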