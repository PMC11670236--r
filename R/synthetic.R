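# Synthetic bone-marrow expression matrices and paired BCR repertoires with
# planted ground truth: malignant plasma-cell subpopulations separated by two
# signature gene sets, clonal expansions with mutation gradients, a canonical
# VH1-72/W33L clone, and treatment effects that deplete expanded clones.

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: a bone-marrow
#' mixture of five cell types, an untreated malignant plasma-cell fraction of
#' 0.3, a +2 log-scale signature effect, an expanded (clonal) repertoire
#' compartment of 10 percent carrying class-switched isotypes and ~4 percent
#' V-region mutation, a canonical VH1-72 clone with 56 percent W33L carriage
#' untreated versus 10 percent treated, and a sixfold depletion of expanded
#' clones in treated samples. Six treated and five untreated samples mirror a
#' typical paired mouse cohort.
#'
#' @param n_cells_per_sample Cells per sample in the expression simulation.
#' @param n_genes Genes in the expression simulation.
#' @param cell_type_proportions Named proportions over
#'   plasma/b_cell/t_nk/granulocyte/other (sum to 1).
#' @param malignant_fraction_untreated Fraction of plasma cells planted
#'   malignant in untreated samples (divided by `depletion_factor` in treated
#'   samples).
#' @param signature_effect Log-scale mean-expression shift added to
#'   malignant-set genes in malignant cells and to nonmalignant-set genes in
#'   nonmalignant plasma cells.
#' @param n_signature_genes Genes per signature set.
#' @param library_size_mean Expected counts per cell.
#' @param library_size_sdlog Log-sd of the per-cell library size.
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param n_samples_treated,n_samples_untreated Samples per arm.
#' @param n_sequences_per_sample Heavy-chain records per sample in the
#'   repertoire simulation (when no annotation is supplied).
#' @param clone_count Expanded clones per sample.
#' @param clone_size_distribution Power-law exponent for expanded clone sizes.
#' @param expanded_fraction Fraction of a sample's sequences in expanded clones.
#' @param shm_rate_naive,shm_rate_expanded Per-site mutation probabilities.
#' @param isotype_probs_naive,isotype_probs_expanded Named isotype probability
#'   maps (each summing to 1).
#' @param w33l_fraction_untreated,w33l_fraction_treated Fraction of the
#'   canonical VH1-72 clone carrying W33L per arm.
#' @param depletion_factor Multiplicative reduction of expanded-clone sizes
#'   (and of the malignant plasma fraction) in treated samples; >= 1.
#' @param seed Integer seed; all outputs are pure functions of (config, seed).
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_cells_per_sample = 1000,
                       n_genes = 600,
                       cell_type_proportions = c(
                         plasma = 0.30, b_cell = 0.25, t_nk = 0.20,
                         granulocyte = 0.15, other = 0.10
                       ),
                       malignant_fraction_untreated = 0.30,
                       signature_effect = 2,
                       n_signature_genes = 30,
                       library_size_mean = 2500,
                       library_size_sdlog = 0.3,
                       dispersion = 0.5,
                       n_samples_treated = 6,
                       n_samples_untreated = 5,
                       n_sequences_per_sample = 1200,
                       clone_count = 6,
                       clone_size_distribution = 1,
                       expanded_fraction = 0.10,
                       shm_rate_naive = 5e-4,
                       shm_rate_expanded = 0.04,
                       isotype_probs_naive = c(
                         IgM = 0.85, IgD = 0.10, IgG3 = 0.02, IgG1 = 0.01,
                         IgG2b = 0.01, IgG2c = 0.005, IgA = 0.005
                       ),
                       isotype_probs_expanded = c(
                         IgM = 0.05, IgG1 = 0.40, IgG2b = 0.20, IgG2c = 0.15,
                         IgG3 = 0.05, IgA = 0.15
                       ),
                       w33l_fraction_untreated = 0.56,
                       w33l_fraction_treated = 0.10,
                       depletion_factor = 6,
                       seed = 1) {
  cfg <- as.list(environment())
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  props <- cfg$cell_type_proportions
  if (any(props < 0) || any(props > 1) || abs(sum(props) - 1) > 1e-6) {
    abort("cell_type_proportions must lie in [0, 1] and sum to 1")
  }
  for (nm in c("isotype_probs_naive", "isotype_probs_expanded")) {
    p <- cfg[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) abort(paste(nm, "must be nonnegative and sum to 1"))
    if (!all(names(p) %in% KNOWN_ISOTYPES)) abort(paste(nm, "has unknown isotype names"))
  }
  rates <- c(
    cfg$malignant_fraction_untreated, cfg$expanded_fraction,
    cfg$shm_rate_naive, cfg$shm_rate_expanded,
    cfg$w33l_fraction_untreated, cfg$w33l_fraction_treated
  )
  if (any(rates < 0) || any(rates > 1)) abort("fractions and rates must lie in [0, 1]")
  if (cfg$depletion_factor < 1) abort("depletion_factor must be >= 1")
  if (cfg$signature_effect < 0) abort("signature_effect must be nonnegative")
  stopifnot(cfg$n_genes >= 2 * cfg$n_signature_genes + 30)
  cfg
}

#' @rdname sim_config
#' @param path YAML file with fields named as in `sim_config()`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("cell_type_proportions", "isotype_probs_naive", "isotype_probs_expanded")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d+%d samples, %d cells x %d genes, effect %.1f, depletion %.1fx, seed %d\n",
    x$n_samples_treated, x$n_samples_untreated, x$n_cells_per_sample,
    x$n_genes, x$signature_effect, x$depletion_factor, x$seed
  ))
  invisible(x)
}

# deterministic allocation of n into counts proportional to p (largest remainder)
round_proportions <- function(n, p) {
  raw <- n * p / sum(p)
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

round_half_up <- function(x) floor(x + 0.5)

sample_ids_for <- function(cfg) {
  tibble(
    sample_id = c(
      sprintf("treated_%d", seq_len(cfg$n_samples_treated)),
      sprintf("untreated_%d", seq_len(cfg$n_samples_untreated))
    ),
    group = rep(c("treated", "untreated"), c(cfg$n_samples_treated, cfg$n_samples_untreated))
  )
}

MARKER_GENES <- list(
  plasma = c("Sdc1", "Xbp1", "Prdm1", "Ccr10"),
  b_cell = c("Cd19", "Cd79a", "Ms4a1"),
  t_nk = c("Cd3e", "Nkg7"),
  granulocyte = c("S100a8", "S100a9"),
  other = character(0)
)
MITO_GENES <- c("mt-Co1", "mt-Nd1", "mt-Atp6")

#' Simulate a bone-marrow expression matrix with planted malignant plasma cells
#'
#' Counts follow a negative-binomial model with per-cell lognormal library
#' sizes and lognormal per-gene base abundances. Cell-type marker genes
#' (Sdc1/Xbp1/Prdm1 for plasma cells, Cd19/Cd79a/Ms4a1 for B cells, ...) are
#' elevated in their type; planted-malignant plasma cells get
#' `+signature_effect` (log scale) on the malignant signature genes,
#' planted-nonmalignant plasma cells the same on the nonmalignant set.
#' Treated samples carry a malignant fraction reduced by `depletion_factor`.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_expression` with `expression` ([expr_matrix()]),
#'   `annotation` (cell_id/sample_id/group/cell_type), `truth` (planted
#'   labels), `gene_sets` (malignant and nonmalignant [gene_set()]s) and
#'   `config`.
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::local_seed(cfg$seed + 101L)
  nsig <- cfg$n_signature_genes
  mal_genes <- sprintf("Msig%02d", seq_len(nsig))
  nonmal_genes <- sprintf("Nsig%02d", seq_len(nsig))
  markers <- unlist(MARKER_GENES, use.names = FALSE)
  n_filler <- cfg$n_genes - length(markers) - length(MITO_GENES) - 2 * nsig
  genes <- c(markers, MITO_GENES, mal_genes, nonmal_genes,
             sprintf("Gene%04d", seq_len(n_filler)))
  G <- length(genes)
  base <- rlnorm(G, meanlog = 0, sdlog = 1)
  names(base) <- genes
  # mitochondrial content around 3 percent of the library
  base[MITO_GENES] <- sum(base) * 0.03 / length(MITO_GENES)

  med <- median(base)
  all_markers <- unlist(MARKER_GENES, use.names = FALSE)
  type_abundance <- function(cell_type, status = NA) {
    a <- base
    # marker genes are near-silent off-type and strongly expressed in-type
    a[all_markers] <- 0.002 * med
    a[MARKER_GENES[[cell_type]]] <- 10 * med
    if (cell_type == "plasma" && !is.na(status)) {
      if (status == "malignant") a[mal_genes] <- a[mal_genes] * exp(cfg$signature_effect)
      else a[nonmal_genes] <- a[nonmal_genes] * exp(cfg$signature_effect)
    }
    a / sum(a)
  }

  samples <- sample_ids_for(cfg)
  blocks <- vector("list", 0)
  ann <- vector("list", 0)
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    grp <- samples$group[s]
    type_counts <- round_proportions(cfg$n_cells_per_sample, cfg$cell_type_proportions)
    names(type_counts) <- names(cfg$cell_type_proportions)
    mal_frac <- cfg$malignant_fraction_untreated /
      (if (grp == "treated") cfg$depletion_factor else 1)
    cell_no <- 0L
    for (ct in names(type_counts)) {
      n_ct <- type_counts[[ct]]
      if (n_ct == 0) next
      block_sizes <- if (ct == "plasma") {
        n_mal <- round_half_up(mal_frac * n_ct)
        c(malignant = n_mal, nonmalignant = n_ct - n_mal)
      } else {
        setNames(n_ct, NA_character_)
      }
      for (bi in seq_along(block_sizes)) {
        status <- names(block_sizes)[bi]
        if (is.na(status) || status == "NA") status <- NA_character_
        n_blk <- block_sizes[[bi]]
        if (n_blk == 0) next
        p <- type_abundance(ct, status)
        lib <- rlnorm(n_blk, log(cfg$library_size_mean) - cfg$library_size_sdlog^2 / 2,
                      cfg$library_size_sdlog)
        mu <- outer(p, lib)
        counts <- matrix(
          rnbinom(G * n_blk, mu = mu, size = 1 / cfg$dispersion),
          nrow = G
        )
        ids <- sprintf("%s_cell%04d", sid, cell_no + seq_len(n_blk))
        cell_no <- cell_no + n_blk
        dimnames(counts) <- list(genes, ids)
        blocks[[length(blocks) + 1]] <- Matrix::Matrix(counts, sparse = TRUE)
        ann[[length(ann) + 1]] <- tibble(
          cell_id = ids, sample_id = sid, group = grp, cell_type = ct,
          malignant = if (ct == "plasma") status == "malignant" else NA
        )
      }
    }
  }
  counts <- do.call(cbind, blocks)
  annotation <- dplyr::bind_rows(ann)
  structure(
    list(
      expression = expr_matrix(counts, layer = "raw"),
      annotation = annotation[, c("cell_id", "sample_id", "group", "cell_type")],
      truth = annotation[, c("cell_id", "sample_id", "group", "cell_type", "malignant")],
      gene_sets = list(
        malignant = gene_set("malignant", mal_genes),
        nonmalignant = gene_set("nonmalignant", nonmal_genes)
      ),
      config = cfg
    ),
    class = "sim_expression"
  )
}

random_aa <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

mutate_aa <- function(seq, rate, protect = integer(0)) {
  chars <- strsplit(seq, "")[[1]]
  pos <- which(runif(length(chars)) < rate)
  pos <- setdiff(pos, protect)
  for (i in pos) {
    chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

substitute_once <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  i <- sample(length(chars), 1)
  chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1)
  paste(chars, collapse = "")
}

CANONICAL_V <- "VH1-72"
CDR3_LENGTH_PROBS <- c(`7` = 0.08, `8` = 0.42, `9` = 0.20, `10` = 0.14,
                       `11` = 0.10, `12` = 0.06)

# one sample's repertoire at untreated intensity; treated arms are derived by
# apply_treatment() plus re-planting of the treated W33L fraction
generate_sample_repertoire <- function(cfg, sid, grp, n_seq, germ_v, germ_j) {
  canon <- germ_v[germ_v$segment == CANONICAL_V, ]
  others <- germ_v[germ_v$segment != CANONICAL_V, ]
  w33l_site <- canon$cdr1_start + 7L # window position 8
  w33l_frac <- if (grp == "treated") cfg$w33l_fraction_treated else cfg$w33l_fraction_untreated

  n_expanded <- round_half_up(cfg$expanded_fraction * n_seq)
  n_naive <- n_seq - n_expanded
  weights <- seq_len(cfg$clone_count)^(-cfg$clone_size_distribution)
  clone_sizes <- round_proportions(n_expanded, weights)

  recs <- vector("list", cfg$clone_count + 1)
  truths <- vector("list", cfg$clone_count + 1)
  for (ci in seq_len(cfg$clone_count)) {
    size <- clone_sizes[ci]
    if (size == 0) next
    if (ci == 1) {
      vrow <- canon
      anc_len <- 10L
    } else {
      vrow <- others[sample(nrow(others), 1), ]
      anc_len <- as.integer(sample(names(CDR3_LENGTH_PROBS), 1, prob = CDR3_LENGTH_PROBS))
    }
    jseg <- germ_j$segment[sample(nrow(germ_j), 1)]
    ancestor <- random_aa(anc_len)
    cdr3 <- vapply(seq_len(size), function(i) {
      if (runif(1) < 0.3) substitute_once(ancestor) else ancestor
    }, character(1))
    protect <- if (ci == 1) w33l_site else integer(0)
    vseq <- vapply(seq_len(size), function(i) {
      mutate_aa(vrow$seq, cfg$shm_rate_expanded, protect = protect)
    }, character(1))
    w33l <- rep(NA, size)
    if (ci == 1) {
      w33l <- runif(size) < w33l_frac
      substr(vseq[w33l], w33l_site, w33l_site) <- "L"
    }
    iso <- sample(names(cfg$isotype_probs_expanded), size, replace = TRUE,
                  prob = cfg$isotype_probs_expanded)
    recs[[ci]] <- tibble(
      v_call = vrow$segment, j_call = jseg, isotype = iso,
      cdr3_aa = cdr3, sequence_alignment = vseq, germline_alignment = vrow$seq,
      cdr1_start = vrow$cdr1_start, cdr1_end = vrow$cdr1_end
    )
    truths[[ci]] <- tibble(
      sim_clone = sprintf("%s_clone%02d", sid, ci),
      compartment = "expanded", w33l = w33l
    )
  }
  if (n_naive > 0) {
    vrows <- sample(nrow(others), n_naive, replace = TRUE)
    jsegs <- germ_j$segment[sample(nrow(germ_j), n_naive, replace = TRUE)]
    lens <- pmin(pmax(round_half_up(rnorm(n_naive, 11, 1.5)), 7), 16)
    cdr3 <- vapply(lens, random_aa, character(1))
    vseq <- vapply(vrows, function(i) mutate_aa(others$seq[i], cfg$shm_rate_naive),
                   character(1))
    iso <- sample(names(cfg$isotype_probs_naive), n_naive, replace = TRUE,
                  prob = cfg$isotype_probs_naive)
    recs[[cfg$clone_count + 1]] <- tibble(
      v_call = others$segment[vrows], j_call = jsegs, isotype = iso,
      cdr3_aa = cdr3, sequence_alignment = vseq,
      germline_alignment = others$seq[vrows],
      cdr1_start = others$cdr1_start[vrows], cdr1_end = others$cdr1_end[vrows]
    )
    truths[[cfg$clone_count + 1]] <- tibble(
      sim_clone = rep("naive", n_naive),
      compartment = "naive", w33l = NA
    )
  }
  rearr <- dplyr::bind_rows(recs)
  truth <- dplyr::bind_rows(truths)
  rearr$sequence_id <- sprintf("%s_seq%05d", sid, seq_len(nrow(rearr)))
  rearr$cell_id <- rearr$sequence_id
  rearr$sample_id <- sid
  rearr$group <- grp
  rearr$c_call <- c(
    IgM = "IGHM", IgD = "IGHD", IgG1 = "IGHG1", IgG2b = "IGHG2B",
    IgG2c = "IGHG2C", IgG3 = "IGHG3", IgA = "IGHA", IgE = "IGHE"
  )[rearr$isotype]
  truth$sequence_id <- rearr$sequence_id
  truth$sample_id <- sid
  list(rearrangements = rearr, truth = truth)
}

#' Simulate a heavy-chain repertoire with planted clonal structure
#'
#' Naive records draw uniform V/J segments, IgM-dominant isotypes and
#' near-germline V regions; expanded clones share (V, J, ancestor CDR3) with
#' members at most one substitution from the ancestor, class-switched
#' isotypes and `shm_rate_expanded` mutation; clone 1 of every sample is the
#' canonical VH1-72 clone carrying W33L (CDR1 window position 8) in the
#' arm-specific fraction of members. Treated samples are derived from an
#' untreated-intensity draw via [apply_treatment()].
#'
#' @param cfg A [sim_config()].
#' @param annotation Optional cell annotation (e.g. from
#'   [simulate_expression()]); when given, each sample receives one record per
#'   B/plasma cell and reuses those cell ids.
#' @param germline_v,germline_j Germline tables ([read_germline_fasta()]);
#'   the packaged synthetic sets by default.
#' @return List of class `sim_repertoire` with `rearrangements`, `truth`
#'   (per-record clone provenance, W33L carriage, depletion bookkeeping) and
#'   `config`.
#' @export
simulate_repertoire <- function(cfg, annotation = NULL,
                                germline_v = read_germline_fasta(germline_fasta_path("v")),
                                germline_j = read_germline_fasta(germline_fasta_path("j"))) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!(CANONICAL_V %in% germline_v$segment)) {
    abort(paste("germline V set must include the canonical segment", CANONICAL_V))
  }
  withr::local_seed(cfg$seed + 202L)
  samples <- sample_ids_for(cfg)
  out_r <- list(); out_t <- list()
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    grp <- samples$group[s]
    if (!is.null(annotation)) {
      cells <- annotation$cell_id[annotation$sample_id == sid &
                                    annotation$cell_type %in% c("b_cell", "plasma")]
      n_seq <- length(cells)
    } else {
      cells <- NULL
      n_seq <- cfg$n_sequences_per_sample
    }
    if (n_seq == 0) next
    samp <- generate_sample_repertoire(cfg, sid, grp, n_seq, germline_v, germline_j)
    if (grp == "treated") {
      samp <- deplete_sample(samp, cfg, seed = cfg$seed + 303L + s)
    } else {
      samp$truth$depletion_applied <- 1
    }
    if (!is.null(cells)) {
      samp$rearrangements$cell_id <- cells[seq_len(nrow(samp$rearrangements))]
    }
    out_r[[s]] <- samp$rearrangements
    out_t[[s]] <- samp$truth
  }
  rearr <- dplyr::bind_rows(out_r)
  cols <- c(
    "sequence_id", "cell_id", "sample_id", "group", "v_call", "j_call",
    "c_call", "isotype", "cdr3_aa", "sequence_alignment", "germline_alignment",
    "cdr1_start", "cdr1_end"
  )
  structure(
    list(
      rearrangements = rearr[, cols],
      truth = dplyr::bind_rows(out_t),
      config = cfg
    ),
    class = "sim_repertoire"
  )
}

deplete_sample <- function(samp, cfg, seed) {
  keep <- apply_treatment(samp$rearrangements, samp$truth, cfg, seed = seed)
  sel <- samp$rearrangements$sequence_id %in% keep$sequence_id
  samp$rearrangements <- samp$rearrangements[sel, , drop = FALSE]
  samp$truth <- samp$truth[sel, , drop = FALSE]
  samp$truth$depletion_applied <- ifelse(samp$truth$compartment == "expanded",
                                         cfg$depletion_factor, 1)
  samp
}

#' Apply treatment depletion to a repertoire sample
#'
#' Each expanded clone keeps `round(size / depletion_factor)` members (half-up
#' rounding, floor 0), chosen by seeded sampling without replacement; the
#' naive compartment is untouched. With `depletion_factor = 1` the input is
#' returned with identical clone sizes.
#'
#' @param rearrangements Rearrangement tibble with `sequence_id`.
#' @param truth Matching truth tibble with `sequence_id`, `sim_clone`,
#'   `compartment` (from [simulate_repertoire()]).
#' @param cfg A [sim_config()] supplying `depletion_factor`.
#' @param seed Seed for the member resampling (derived from the config seed
#'   by default).
#' @return The surviving subset of `rearrangements`.
#' @export
apply_treatment <- function(rearrangements, truth, cfg, seed = cfg$seed + 303L) {
  stopifnot(inherits(cfg, "sim_config"))
  d <- cfg$depletion_factor
  tr <- as_tibble(truth)
  keep_ids <- withr::with_seed(seed, {
    unlist(lapply(split(tr$sequence_id, tr$sim_clone), function(ids) {
      clone <- tr$compartment[match(ids[1], tr$sequence_id)]
      if (clone != "expanded") return(ids)
      k <- round_half_up(length(ids) / d)
      if (k == 0) return(character(0))
      sample(ids, k)
    }), use.names = FALSE)
  })
  rearrangements[rearrangements$sequence_id %in% keep_ids, , drop = FALSE]
}
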