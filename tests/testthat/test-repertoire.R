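test_that("clonotype assignment follows the inclusive 80% identity rule", {
  # two CDR3s of length 10 differing at 2 positions: identity exactly 0.80
  r <- tibble::tibble(
    v_call = "VH1-72", j_call = "JH2",
    cdr3_aa = c("AAAAAAAAAA", "AAAAAAAAGG")
  )
  out <- assign_clonotypes(r)
  expect_equal(out$clone_id[1], out$clone_id[2])

  # three differences (identity 0.7) split the clone
  r2 <- tibble::tibble(v_call = "VH1-72", j_call = "JH2",
                       cdr3_aa = c("AAAAAAAAAA", "AAAAAAAGGG"))
  out2 <- assign_clonotypes(r2)
  expect_false(out2$clone_id[1] == out2$clone_id[2])

  # identical records share a clone; different V or J never do
  r3 <- tibble::tibble(v_call = c("VH1-72", "VH1-72", "VH2-2"),
                       j_call = c("JH1", "JH1", "JH1"),
                       cdr3_aa = "CARDY")
  out3 <- assign_clonotypes(r3)
  expect_equal(out3$clone_id[1], out3$clone_id[2])
  expect_false(out3$clone_id[1] == out3$clone_id[3])

  expect_equal(nrow(assign_clonotypes(r3[0, ])), 0)
})

test_that("clonotype partition is order-invariant and matches the graph oracle", {
  skip_if_not_installed("igraph")
  for (s in 1:20) {
    r <- random_repertoire(30, seed = 500 + s)
    mine <- assign_clonotypes(r)
    perm <- withr::with_seed(s, sample(nrow(r)))
    shuffled <- assign_clonotypes(r[perm, ])
    shuffled <- shuffled[order(match(shuffled$sequence_id, r$sequence_id)), ]
    expect_equal(canonical_partition(mine$clone_id),
                 canonical_partition(shuffled$clone_id), info = paste("perm seed", s))
    oracle <- oracle_clonotype_partition(r, 0.80)
    expect_equal(canonical_partition(mine$clone_id), canonical_partition(oracle),
                 info = paste("oracle seed", s))
  }
})

test_that("identity threshold 1.0 reduces to exact (V, J, CDR3) grouping", {
  r <- random_repertoire(40, seed = 900)
  out <- assign_clonotypes(r, identity_threshold = 1.0)
  dict <- paste(r$v_call, r$j_call, r$cdr3_aa)
  expect_equal(canonical_partition(out$clone_id), canonical_partition(dict))
})

test_that("clone sizes are conserved and clone members share V/J", {
  sim <- simulate_repertoire(small_cfg(seed = 61))
  out <- assign_clonotypes(sim$rearrangements)
  clones <- clone_table(add_mutation_stats(out))
  expect_equal(sum(clones$size), nrow(out))
  expect_true(all(!is.na(clones$mean_vh_mutation_freq)))
})

test_that("mutation counting matches the position-wise oracle and flags length mismatch", {
  expect_equal(vh_mutation_stats("ACDEF", "ACDEF")$mutation_count, 0L)
  expect_equal(vh_mutation_stats("ACDEF", "ACDEF")$mutation_freq, 0)

  # 6 substitutions over 300 sites: exactly 2.0% -- the boundary case
  germ <- paste(rep("A", 300), collapse = "")
  seq6 <- paste(c(rep("C", 6), rep("A", 294)), collapse = "")
  ms <- vh_mutation_stats(seq6, germ)
  expect_equal(ms$mutation_count, 6L)
  expect_equal(ms$mutation_freq, 2.0)

  # gaps are excluded from both count and length
  msg <- vh_mutation_stats("AC-EF", "ACD-F")
  expect_equal(msg$aligned_length, 3L)

  for (s in 1:10) {
    withr::with_seed(s, {
      g <- paste(sample(c("A", "C", "G"), 50, replace = TRUE), collapse = "")
      q <- paste(sample(c("A", "C", "G"), 50, replace = TRUE), collapse = "")
    })
    gi <- strsplit(g, "")[[1]]; qi <- strsplit(q, "")[[1]]
    expect_equal(vh_mutation_stats(q, g)$mutation_count, sum(gi != qi))
  }

  expect_error(vh_mutation_stats("ACD", "AC"), "equal length")
})

test_that("the boundary case at exactly 2% is classified not-above", {
  germ <- paste(rep("A", 300), collapse = "")
  mk <- function(nmut, n) {
    vapply(seq_len(n), function(i) {
      paste(c(rep("C", nmut), rep("A", 300 - nmut)), collapse = "")
    }, character(1))
  }
  r <- dplyr::bind_rows(
    mk_rearr(mk(6, 12), germ, cdr3 = "AAAAAAAAAA"),        # 2.0%: not above
    mk_rearr(mk(9, 12), germ, v_call = "VH2-2", cdr3 = "CCCCCCCCCC") # 3%: above
  )
  r <- assign_clonotypes(r)
  out <- mutated_clonotype_frequency(r)
  expect_equal(out$n_qualifying, 2)
  expect_equal(out$n_mutated_qualifying, 1)
  expect_equal(out$prop_mutated_clones, 0.5)
})

test_that("the (>2%, >10 cells) double filter reproduces the hand-computed example", {
  germ <- paste(rep("A", 100), collapse = "")
  mk_seq <- function(nmut) paste(c(rep("G", nmut), rep("A", 100 - nmut)), collapse = "")
  # clones of sizes (12, 11, 5) with mean frequencies (3%, 1%, 9%)
  r <- dplyr::bind_rows(
    mk_rearr(rep(mk_seq(3), 12), germ, v_call = "VH1-72", cdr3 = "AAAAAAAA"),
    mk_rearr(rep(mk_seq(1), 11), germ, v_call = "VH2-2", cdr3 = "CCCCCCCC"),
    mk_rearr(rep(mk_seq(9), 5), germ, v_call = "VH3-6", cdr3 = "DDDDDDDD")
  )
  r <- assign_clonotypes(r)
  out <- mutated_clonotype_frequency(r)
  expect_equal(out$n_qualifying, 2)          # size-5 clone excluded
  expect_equal(out$prop_mutated_clones, 0.5) # 1 of 2 qualifying clones above 2%

  # all clones unmutated: zero
  r0 <- assign_clonotypes(mk_rearr(rep(germ, 12), germ))
  out0 <- mutated_clonotype_frequency(r0)
  expect_equal(out0$prop_mutated_clones, 0)

  # no qualifying clones: missing, not zero
  r5 <- assign_clonotypes(mk_rearr(rep(mk_seq(9), 5), germ))
  expect_true(is.na(mutated_clonotype_frequency(r5)$prop_mutated_clones))
})

test_that("isotype frequencies count correctly and sum to one over known isotypes", {
  r <- tibble::tibble(isotype = rep("IgM", 7))
  out <- isotype_frequencies(r)
  expect_equal(out$freq[out$isotype == "IgM"], 1)
  expect_equal(sum(out$freq, na.rm = TRUE), 1)

  r2 <- tibble::tibble(
    isotype = c("IgM", "IgM", "IgG1", "IgA", "unknown"),
    sample_id = "s1"
  )
  out2 <- isotype_frequencies(r2)
  expect_equal(out2$freq[out2$isotype == "IgM"], 2 / 4)
  expect_equal(out2$freq[out2$isotype == "IgG1"], 1 / 4)
  expect_true(is.na(out2$freq[out2$isotype == "unknown"]))
  expect_equal(out2$n[out2$isotype == "unknown"], 1)
  expect_equal(sum(out2$freq, na.rm = TRUE), 1)
})

test_that("V-family frequencies and the V-J matrix conserve marginals", {
  r <- tibble::tibble(
    v_call = c("VH1-72", "VH1-12", "VH2-2", "VH1-72"),
    j_call = c("JH2", "JH2", "JH1", "JH2"),
    cdr3_aa = c("AAAA", "CCCC", "DDDD", "AAAA")
  )
  fam <- v_family_frequencies(r)
  expect_equal(fam$freq[fam$family == "VH1"], 0.75)
  expect_equal(sum(fam$freq), 1)

  vj <- vj_matrix(r)
  expect_equal(vj$n[vj$v_call == "VH1-72" & vj$j_call == "JH2"], 2)
  expect_equal(sum(vj$n), nrow(r))
  # row/column sums equal per-gene usage
  expect_equal(
    sum(vj$n[vj$j_call == "JH2"]), sum(r$j_call == "JH2")
  )

  rc <- assign_clonotypes(r)
  vjc <- vj_matrix(rc, collapse_clones = TRUE)
  expect_equal(vjc$n[vjc$v_call == "VH1-72" & vjc$j_call == "JH2"], 1)
  expect_equal(sum(vjc$n), dplyr::n_distinct(rc$clone_id))
})

test_that("CDR3 length distribution computes mode, AUC and normalized frequencies", {
  r8 <- tibble::tibble(cdr3_aa = strrep("A", rep(8, 10)))
  d8 <- cdr3_length_distribution(r8)
  expect_equal(d8$summary$modal_length, 8)
  expect_equal(d8$distribution$freq, 1)

  # uniform lengths 7..10 at 0.25: trapezoidal AUC = 0.75
  ru <- tibble::tibble(cdr3_aa = strrep("A", rep(7:10, each = 5)))
  du <- cdr3_length_distribution(ru)
  expect_equal(du$summary$auc, 0.75)
  expect_equal(sum(du$distribution$freq), 1)

  # gaps in the observed range are zero-filled
  rg <- tibble::tibble(cdr3_aa = strrep("A", c(7, 7, 10)))
  dg <- cdr3_length_distribution(rg)
  expect_equal(dg$distribution$length, 7:10)
  expect_equal(dg$distribution$n, c(2L, 0L, 0L, 1L))
})

test_that("VH1-72 analysis reads the W33L residue from the CDR1 window", {
  gv <- read_germline_fasta(germline_fasta_path("v"))
  canon <- gv[gv$segment == "VH1-72", ]
  germline_rec <- mk_rearr(canon$seq, canon$seq)
  out <- vh1_72_analysis(dplyr::bind_rows(
    germline_rec,
    mk_rearr("L" |> (\(l) {s <- canon$seq; substr(s, 33, 33) <- l; s})(), canon$seq),
    mk_rearr(canon$seq, canon$seq, v_call = "VH2-2")
  ))
  expect_equal(out$usage$usage, 2 / 3)
  expect_equal(out$records$w33l, c(FALSE, TRUE))
  expect_equal(out$w33l$n_W, 1)
  expect_equal(out$w33l$n_L, 1)

  # window past the alignment end: flagged and excluded
  short <- mk_rearr(substr(canon$seq, 1, 20), substr(canon$seq, 1, 20))
  out_short <- vh1_72_analysis(short)
  expect_false(out_short$records$window_ok)
  expect_equal(sum(out_short$w33l$n), 0)
})

test_that("clone size statistics report log10 sizes and compare groups", {
  r <- tibble::tibble(
    clone_id = c("a", rep("b", 10), rep("c", 100)),
    group = c("treated", rep("treated", 10), rep("untreated", 100))
  )
  out <- clone_size_stats(r)
  expect_equal(sort(out$clones$log10_size), c(0, 1, 2))
  expect_null(out$test) # fewer than 2 clones per group -> no test

  sim <- simulate_repertoire(small_cfg(seed = 62))
  rc <- assign_clonotypes(sim$rearrangements)
  cs <- clone_size_stats(rc)
  expect_s3_class(cs$test, "surveil_test")
})

test_that("KL logo weights follow the signed enrichment formula", {
  # observed equal to background at every position: all weights zero
  aa <- clonesurveil:::AA_ALPHABET
  unif <- vapply(1:20, function(i) {
    paste(aa[((seq_len(20) + i - 2) %% 20) + 1], collapse = "")
  }, character(1)) # every residue appears exactly once per column
  logo_unif <- kl_logo(unif)
  expect_equal(max(abs(logo_unif$weights)), 0)

  # a single-residue column: positive only for that residue
  logo_a <- kl_logo(rep("A", 30))
  expect_gt(logo_a$weights[1, "A"], 0)
  expect_true(all(logo_a$weights[1, colnames(logo_a$weights) != "A"] <= 0))

  # magnitudes match direct formula evaluation
  wins <- c("AA", "AC", "AC", "AG")
  logo <- kl_logo(wins, pseudocount = 1)
  q <- 1 / 20; n <- 4
  p_c2 <- (2 + 1 * q) / (n + 1)
  expect_equal(logo$weights[2, "C"], p_c2 * log2(p_c2 / q))
  p_a1 <- (4 + q) / (n + 1)
  expect_equal(logo$weights[1, "A"], p_a1 * log2(p_a1 / q))

  expect_error(kl_logo(c("AA", "AAA")), "equal length")
  expect_error(kl_logo("AA", background = c(A = 1)), "strictly positive")

  td <- tidy(logo)
  expect_equal(nrow(td), 2 * 20)
})

test_that("planted W33L depletion flips the L weight sign between arms", {
  cfg <- small_cfg(seed = 63, n_sequences_per_sample = 400,
                   expanded_fraction = 0.3)
  sim <- simulate_repertoire(cfg)
  out <- vh1_72_analysis(sim$rearrangements)
  win <- out$records[out$records$window_ok, ]
  logos <- lapply(split(win, win$group), function(df) {
    kl_logo(substr(df$sequence_alignment, df$cdr1_start[1], df$cdr1_end[1]))
  })
  # untreated arm (56% W33L) is enriched for L at window position 8;
  # the treated arm (10%) is depleted relative to the untreated arm
  expect_gt(logos$untreated$weights[8, "L"], 0)
  expect_gt(logos$untreated$weights[8, "L"], logos$treated$weights[8, "L"])
})
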