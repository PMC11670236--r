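test_that("simulation config validates proportions, rates and depletion", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(cell_type_proportions = c(plasma = 0.5, b_cell = 0.2,
                                                    t_nk = 0.1, granulocyte = 0.1,
                                                    other = 0.05)), "sum to 1")
  expect_error(sim_config(depletion_factor = 0.5), ">= 1")
  expect_error(sim_config(shm_rate_expanded = 1.5), "rates")
  expect_error(sim_config(isotype_probs_naive = c(IgM = 0.5, IgQ = 0.5)), "unknown")
})

test_that("config round-trips through YAML", {
  cfg <- small_cfg(seed = 4, depletion_factor = 10)
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(unclass(cfg), function(v) if (is.null(names(v))) v else as.list(v)), f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$depletion_factor, 10)
  expect_equal(cfg2$cell_type_proportions, cfg$cell_type_proportions)
})

test_that("expression simulation is deterministic and conserves cell-type counts", {
  cfg <- small_cfg(seed = 11)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(as.matrix(a$expression$counts), as.matrix(b$expression$counts))
  expect_identical(a$annotation, b$annotation)

  counts <- table(a$annotation$cell_type[a$annotation$sample_id == "treated_1"])
  expected <- cfg$n_cells_per_sample * cfg$cell_type_proportions
  expect_true(all(abs(counts[names(expected)] - expected) <= 1))
  expect_equal(sum(counts), cfg$n_cells_per_sample)
})

test_that("planted signature effects raise the planted group's set expression", {
  cfg <- small_cfg(seed = 12, signature_effect = 2,
                   n_cells_per_sample = 400,
                   cell_type_proportions = c(plasma = 0.5, b_cell = 0.2, t_nk = 0.1,
                                             granulocyte = 0.1, other = 0.1))
  sim <- simulate_expression(cfg)
  counts <- sim$expression$counts
  mal_cells <- sim$truth$cell_id[sim$truth$malignant %in% TRUE]
  non_cells <- sim$truth$cell_id[sim$truth$malignant %in% FALSE]
  mal_genes <- sim$gene_sets$malignant$genes
  # direct group-mean oracle on malignant-set expression
  mean_mal <- mean(as.matrix(counts[mal_genes, mal_cells]))
  mean_non <- mean(as.matrix(counts[mal_genes, non_cells]))
  expect_gt(mean_mal, mean_non)

  # zero effect: groups exchangeable in expectation
  sim0 <- simulate_expression(small_cfg(seed = 12, signature_effect = 0))
  c0 <- sim0$expression$counts
  m0 <- mean(as.matrix(c0[sim0$gene_sets$malignant$genes,
                          sim0$truth$cell_id[sim0$truth$malignant %in% TRUE]]))
  n0 <- mean(as.matrix(c0[sim0$gene_sets$malignant$genes,
                          sim0$truth$cell_id[sim0$truth$malignant %in% FALSE]]))
  expect_lt(abs(m0 - n0) / n0, 0.2)
})

test_that("repertoire simulation is deterministic with planted clone structure", {
  cfg <- small_cfg(seed = 13)
  a <- simulate_repertoire(cfg)
  b <- simulate_repertoire(cfg)
  expect_identical(a$rearrangements, b$rearrangements)

  # expanded clone members share V and J by construction
  joined <- dplyr::inner_join(a$rearrangements, a$truth, by = "sequence_id")
  for (cl in unique(joined$sim_clone[joined$compartment == "expanded"])) {
    mem <- joined[joined$sim_clone == cl, ]
    expect_equal(length(unique(mem$v_call)), 1)
    expect_equal(length(unique(mem$j_call)), 1)
  }

  # truth invariant: mutated positions are exactly the mismatch positions
  ms <- vh_mutation_stats(a$rearrangements$sequence_alignment,
                          a$rearrangements$germline_alignment)
  expect_true(all(ms$mutation_count >= 0))
  naive_rows <- joined$compartment == "naive"
  expanded_rows <- joined$compartment == "expanded"
  expect_gt(mean(ms$mutation_freq[expanded_rows]), mean(ms$mutation_freq[naive_rows]))
})

test_that("zero naive SHM reproduces germline sequences exactly", {
  cfg <- small_cfg(seed = 14, shm_rate_naive = 0)
  sim <- simulate_repertoire(cfg)
  joined <- dplyr::inner_join(sim$rearrangements, sim$truth, by = "sequence_id")
  naive <- joined[joined$compartment == "naive", ]
  expect_true(all(naive$sequence_alignment == naive$germline_alignment))
})

test_that("expanded SHM load matches the binomial expectation", {
  # rate 0.05 over a 300-site V region: mean mutations ~ 15 within 3*sqrt(np(1-p))
  gv <- read_germline_fasta(germline_fasta_path("v"))
  long <- gv
  long$seq <- vapply(seq_len(nrow(gv)), function(i) {
    substr(strrep(gv$seq[i], 4), 1, 300)
  }, character(1))
  cfg <- sim_config(n_sequences_per_sample = 250, n_samples_treated = 0,
                    n_samples_untreated = 1, expanded_fraction = 0.8,
                    clone_count = 4, shm_rate_expanded = 0.05, seed = 15)
  sim <- simulate_repertoire(cfg, germline_v = long)
  joined <- dplyr::inner_join(sim$rearrangements, sim$truth, by = "sequence_id")
  exp_rows <- joined[joined$compartment == "expanded", ]
  ms <- vh_mutation_stats(exp_rows$sequence_alignment, exp_rows$germline_alignment)
  n <- 300; p <- 0.05
  # 3 standard errors of the mean, plus slack for the planted W33L residue
  expect_lt(abs(mean(ms$mutation_count) - n * p),
            3 * sqrt(n * p * (1 - p) / nrow(exp_rows)) + 1)
  expect_equal(unique(ms$aligned_length), 300)
})

test_that("treatment depletion divides expanded clone sizes and spares the naive pool", {
  cfg <- sim_config(n_sequences_per_sample = 400, clone_count = 2,
                    expanded_fraction = 0.2, depletion_factor = 10,
                    n_samples_treated = 0, n_samples_untreated = 1, seed = 16)
  sim <- simulate_repertoire(cfg)
  joined <- dplyr::inner_join(sim$rearrangements, sim$truth, by = "sequence_id")
  sizes <- table(joined$sim_clone[joined$compartment == "expanded"])
  treated <- apply_treatment(sim$rearrangements, sim$truth, cfg)
  tr_joined <- dplyr::inner_join(treated, sim$truth, by = "sequence_id")
  tr_sizes <- table(tr_joined$sim_clone[tr_joined$compartment == "expanded"])
  for (cl in names(sizes)) {
    expect_equal(unname(tr_sizes[cl]), floor(unname(sizes[cl]) / 10 + 0.5),
                 info = cl)
  }
  # naive untouched
  expect_equal(sum(tr_joined$compartment == "naive"), sum(joined$compartment == "naive"))

  # depletion factor 1 keeps every record
  cfg1 <- sim_config(depletion_factor = 1, seed = 16)
  expect_equal(nrow(apply_treatment(sim$rearrangements, sim$truth, cfg1)),
               nrow(sim$rearrangements))

  # a 40-member clone at factor 10 keeps exactly 4 members
  toy_truth <- tibble::tibble(sequence_id = sprintf("s%02d", 1:40),
                              sim_clone = "cl1", compartment = "expanded")
  toy_rearr <- tibble::tibble(sequence_id = toy_truth$sequence_id)
  cfg10 <- sim_config(depletion_factor = 10)
  expect_equal(nrow(apply_treatment(toy_rearr, toy_truth, cfg10)), 4)
})

test_that("depleting expanded clones raises the naive IgM fraction in treated samples", {
  cfg <- sim_config(n_sequences_per_sample = 600, n_samples_treated = 2,
                    n_samples_untreated = 2, depletion_factor = 8, seed = 17)
  sim <- simulate_repertoire(cfg)
  iso <- isotype_frequencies(sim$rearrangements)
  igm <- iso[iso$isotype == "IgM", ]
  mean_treated <- mean(igm$freq[igm$group == "treated"])
  mean_untreated <- mean(igm$freq[igm$group == "untreated"])
  expect_gt(mean_treated, mean_untreated)
})
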