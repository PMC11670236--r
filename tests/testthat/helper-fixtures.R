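# Small programmatic fixtures shared across tests.

mk_expr <- function(mat, layer = "raw", genes = NULL, cells = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- genes %||% sprintf("g%d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- cells %||% sprintf("c%d", seq_len(ncol(mat)))
  expr_matrix(mat, layer = layer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small simulation config that runs in well under a second
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(
      n_cells_per_sample = 150, n_genes = 150, n_samples_treated = 2,
      n_samples_untreated = 2, n_sequences_per_sample = 200,
      n_signature_genes = 15
    ),
    list(...)
  )
  do.call(sim_config, args)
}

# a rearrangement tibble with explicit alignments and CDR1 annotation
mk_rearr <- function(v_seq, germline, v_call = "VH1-72", j_call = "JH2",
                     cdr3 = "CARSAYWGQG", isotype = "IgG1",
                     cdr1_start = 26, cdr1_end = 33) {
  n <- length(v_seq)
  tibble::tibble(
    sequence_id = sprintf("q%03d", seq_len(n)),
    cell_id = sprintf("q%03d", seq_len(n)),
    v_call = v_call, j_call = j_call,
    c_call = "IGHG1", isotype = isotype,
    cdr3_aa = cdr3,
    sequence_alignment = v_seq,
    germline_alignment = germline,
    cdr1_start = cdr1_start, cdr1_end = cdr1_end
  )
}

# scored cells used by classification tests
mk_scores <- function(m, n, group = NULL, sample_id = NULL) {
  out <- tibble::tibble(
    cell_id = sprintf("c%04d", seq_along(m)),
    malignant_score = m,
    nonmalignant_score = n,
    compound_score = m - n
  )
  if (!is.null(group)) out$group <- group
  if (!is.null(sample_id)) out$sample_id <- sample_id
  out
}
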