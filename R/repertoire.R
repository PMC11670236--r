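# Clonotype assignment, somatic-hypermutation quantification, isotype /
# V-family / V-J spectra, CDR3 length distributions, canonical VH1-72 / W33L
# analysis, clone-size statistics, and Kullback-Leibler sequence logos.

# union-find with path compression
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

hamming_identity <- function(a, b) {
  # equal-length character vectors of split residues
  mean(a == b)
}

#' Assign clonotypes by V/J identity and CDR3 similarity
#'
#' Records are partitioned by (v_call, j_call, CDR3 length); within a
#' partition, records are clustered with an edge whenever Hamming identity of
#' the CDR3 amino-acid strings is at or above `identity_threshold` (single
#' linkage by default, the standard clonal-grouping convention; complete
#' linkage available). Records with CDR3s of different length never share a
#' clone. The partition is invariant to input order.
#'
#' @param rearrangements Tibble with `v_call`, `j_call`, `cdr3_aa` columns.
#' @param identity_threshold Inclusive identity threshold (default 0.80).
#' @param linkage `"single"` (default) or `"complete"`.
#' @return The input tibble with a `clone_id` column added.
#' @export
assign_clonotypes <- function(rearrangements, identity_threshold = 0.80,
                              linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  rearr <- as_tibble(rearrangements)
  if (nrow(rearr) == 0) {
    rearr$clone_id <- character(0)
    return(rearr)
  }
  stopifnot(all(c("v_call", "j_call", "cdr3_aa") %in% names(rearr)))
  len <- nchar(rearr$cdr3_aa)
  part_key <- paste(rearr$v_call, rearr$j_call, len, sep = "|")
  clone_id <- character(nrow(rearr))
  for (key in sort(unique(part_key))) {
    rows <- which(part_key == key)
    cdr3 <- rearr$cdr3_aa[rows]
    uniq <- sort(unique(cdr3)) # sorted: cluster labels independent of input order
    k <- length(uniq)
    cluster <- integer(k)
    if (k == 1) {
      cluster[] <- 1L
    } else {
      chars <- do.call(rbind, strsplit(uniq, ""))
      if (linkage == "single") {
        parent <- seq_len(k)
        for (i in seq_len(k - 1)) {
          for (j in seq(i + 1, k)) {
            if (mean(chars[i, ] == chars[j, ]) >= identity_threshold) {
              ri <- uf_find(parent, i); rj <- uf_find(parent, j)
              if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
            }
          }
        }
        roots <- vapply(seq_len(k), function(i) uf_find(parent, i), integer(1))
        cluster <- match(roots, sort(unique(roots)))
      } else {
        d <- stats::as.dist(1 - (tcrossprod(
          matrix(1, k, 1)
        ) * 0 + outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
          mean(chars[i, ] == chars[j, ])
        }))))
        hc <- stats::hclust(d, method = "complete")
        cluster <- stats::cutree(hc, h = (1 - identity_threshold) + 1e-9)
        # renumber by smallest member for order stability
        cluster <- match(cluster, unique(cluster[order(uniq)]))
      }
    }
    clone_id[rows] <- paste0(key, "|c", cluster[match(cdr3, uniq)])
  }
  rearr$clone_id <- clone_id
  rearr
}

#' Per-record V-region mutation statistics
#'
#' Counts positions where the aligned V sequence and its germline both hold a
#' residue (non-gap) and differ; the frequency is that count over the
#' non-gap aligned length, in percent.
#'
#' @param seq,germline Equal-length aligned strings (vectors allowed; gaps are
#'   `"-"` or `"."`).
#' @return Tibble with `mutation_count`, `aligned_length`, `mutation_freq`
#'   (percent).
#' @export
vh_mutation_stats <- function(seq, germline) {
  if (length(seq) != length(germline)) abort("seq and germline must have equal length")
  if (any(nchar(seq) != nchar(germline))) {
    abort("aligned sequence and germline must have equal length in every record")
  }
  stats_one <- function(s, g) {
    a <- strsplit(s, "")[[1]]
    b <- strsplit(g, "")[[1]]
    ok <- !(a %in% c("-", ".")) & !(b %in% c("-", "."))
    n_ok <- sum(ok)
    count <- sum(a[ok] != b[ok])
    c(count, n_ok)
  }
  res <- mapply(stats_one, seq, germline, USE.NAMES = FALSE)
  tibble(
    mutation_count = as.integer(res[1, ]),
    aligned_length = as.integer(res[2, ]),
    mutation_freq = unname(100 * res[1, ] / res[2, ])
  )
}

#' @rdname vh_mutation_stats
#' @param rearrangements Tibble with `sequence_alignment` and
#'   `germline_alignment` columns.
#' @export
add_mutation_stats <- function(rearrangements) {
  rearr <- as_tibble(rearrangements)
  stopifnot(all(c("sequence_alignment", "germline_alignment") %in% names(rearr)))
  dplyr::bind_cols(rearr, vh_mutation_stats(rearr$sequence_alignment, rearr$germline_alignment))
}

#' Summarise clonotypes
#'
#' One row per clone: size, V/J calls, representative (most frequent, ties
#' broken lexicographically) CDR3, mean V mutation frequency with each
#' distinct sequence variant counted once, and isotype counts (list column).
#'
#' @param rearrangements Tibble with `clone_id` (see [assign_clonotypes()]);
#'   mutation columns are added on the fly when alignments are present.
#' @return Tibble of clones.
#' @export
clone_table <- function(rearrangements) {
  rearr <- as_tibble(rearrangements)
  stopifnot("clone_id" %in% names(rearr))
  if (!("mutation_freq" %in% names(rearr)) &&
      all(c("sequence_alignment", "germline_alignment") %in% names(rearr))) {
    rearr <- add_mutation_stats(rearr)
  }
  has_mut <- "mutation_freq" %in% names(rearr)
  has_iso <- "isotype" %in% names(rearr)
  rearr |>
    dplyr::group_by(.data$clone_id) |>
    dplyr::summarise(
      v_call = .data$v_call[1],
      j_call = .data$j_call[1],
      size = dplyr::n(),
      cdr3_length = nchar(.data$cdr3_aa[1]),
      ancestor_cdr3 = {
        tab <- sort(table(.data$cdr3_aa), decreasing = TRUE)
        nm <- names(tab)[tab == max(tab)]
        min(nm)
      },
      mean_vh_mutation_freq = if (has_mut) {
        # each distinct clonotype variant counted once
        mean(.data$mutation_freq[!duplicated(.data$sequence_alignment)])
      } else NA_real_,
      isotype_counts = if (has_iso) list(table(.data$isotype)) else list(NULL),
      .groups = "drop"
    )
}

#' Frequency of highly mutated clonotypes per sample
#'
#' Clone-level mutation frequency is the clone's mean V mutation frequency
#' (distinct variants counted once, computed over all members of the clone).
#' Three per-sample statistics are reported, reflecting the two natural
#' denominators plus a sequence-weighted variant:
#' \describe{
#'   \item{prop_mutated_clones}{mutated clones (> `freq_threshold`) among
#'     clones larger than `min_clone_size` cells in that sample; `NA` (missing,
#'     not 0) when no clone qualifies.}
#'   \item{prop_mutated_all}{mutated qualifying clones over all clones seen in
#'     the sample.}
#'   \item{prop_mutated_seqs}{fraction of the sample's sequences that belong
#'     to clones mutated above `freq_threshold` (no size filter); this variant
#'     varies smoothly under clone-size depletion and is the one used for
#'     planted-effect recovery.}
#' }
#' Both threshold comparisons are strict (`>`), so a clone at exactly 2
#' percent or exactly `min_clone_size` cells does not qualify.
#'
#' @param rearrangements Tibble with `clone_id` and alignment or
#'   `mutation_freq` columns; a `sample_id` column splits samples (one pooled
#'   sample otherwise).
#' @param freq_threshold Mutation-frequency threshold in percent (default 2).
#' @param min_clone_size Clone-size threshold (default 10).
#' @return Tibble with one row per sample.
#' @export
mutated_clonotype_frequency <- function(rearrangements, freq_threshold = 2.0,
                                        min_clone_size = 10) {
  rearr <- as_tibble(rearrangements)
  stopifnot("clone_id" %in% names(rearr))
  if (!("sample_id" %in% names(rearr))) rearr$sample_id <- "all"
  clones <- clone_table(rearr)
  if (all(is.na(clones$mean_vh_mutation_freq))) {
    abort("mutation frequencies unavailable; records need alignment columns")
  }
  mut_of <- setNames(clones$mean_vh_mutation_freq, clones$clone_id)
  rearr |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("group", "sample_id")))) |>
    dplyr::group_modify(function(df, key) {
      sizes <- table(df$clone_id)
      mut <- mut_of[names(sizes)] > freq_threshold
      qual <- as.vector(sizes) > min_clone_size
      seq_in_mut <- sum(sizes[mut])
      tibble(
        n_sequences = nrow(df),
        n_clones = length(sizes),
        n_qualifying = sum(qual),
        n_mutated_qualifying = sum(qual & mut),
        prop_mutated_clones = if (any(qual)) sum(qual & mut) / sum(qual) else NA_real_,
        prop_mutated_all = sum(qual & mut) / length(sizes),
        prop_mutated_seqs = seq_in_mut / nrow(df)
      )
    }) |>
    dplyr::ungroup()
}

#' Isotype frequency table
#'
#' Per-sample fractions over the known isotypes (summing to 1); records with
#' unknown isotype are reported as a separate row with `freq = NA`.
#'
#' @param rearrangements Tibble with an `isotype` column (see [read_airr()]);
#'   optional `sample_id` / `group` columns.
#' @return Tibble with `isotype`, `n`, `freq` per sample.
#' @export
isotype_frequencies <- function(rearrangements) {
  rearr <- as_tibble(rearrangements)
  stopifnot("isotype" %in% names(rearr))
  if (!("sample_id" %in% names(rearr))) rearr$sample_id <- "all"
  rearr |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("group", "sample_id")))) |>
    dplyr::group_modify(function(df, key) {
      n_known <- sum(df$isotype %in% KNOWN_ISOTYPES)
      counts <- table(factor(df$isotype, levels = c(KNOWN_ISOTYPES, "unknown")))
      tibble(
        isotype = names(counts),
        n = as.integer(counts),
        freq = ifelse(names(counts) == "unknown", NA_real_,
                      if (n_known > 0) as.integer(counts) / n_known else NA_real_)
      )
    }) |>
    dplyr::ungroup()
}

#' V-family usage frequencies
#'
#' The family is the prefix of `v_call` before the first hyphen (e.g. `VH1`
#' from `VH1-72`).
#'
#' @inheritParams isotype_frequencies
#' @return Tibble with `family`, `n`, `freq` per sample.
#' @export
v_family_frequencies <- function(rearrangements) {
  rearr <- as_tibble(rearrangements)
  rearr$family <- sub("-.*$", "", rearr$v_call)
  if (!("sample_id" %in% names(rearr))) rearr$sample_id <- "all"
  rearr |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("group", "sample_id")))) |>
    dplyr::group_modify(function(df, key) {
      counts <- table(df$family)
      tibble(family = names(counts), n = as.integer(counts),
             freq = as.integer(counts) / nrow(df))
    }) |>
    dplyr::ungroup()
}

#' V-J pairing matrix (Circos-style long format)
#'
#' Counts records (or clones, when `collapse_clones = TRUE`) per (V, J) pair.
#'
#' @inheritParams isotype_frequencies
#' @param collapse_clones Count each clone once (requires `clone_id`).
#' @return Long tibble with `v_call`, `j_call`, `n`, ordered by decreasing `n`.
#' @export
vj_matrix <- function(rearrangements, collapse_clones = FALSE) {
  rearr <- as_tibble(rearrangements)
  if (collapse_clones) {
    stopifnot("clone_id" %in% names(rearr))
    rearr <- dplyr::distinct(rearr, .data$clone_id, .keep_all = TRUE)
  }
  rearr |>
    dplyr::count(.data$v_call, .data$j_call, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$v_call, .data$j_call)
}

#' CDR3 amino-acid length distribution
#'
#' Integer-length frequency distribution (gaps in the observed range filled
#' with zero), plus modal length and the trapezoidal area under the frequency
#' polygon (AUC), optionally per group.
#'
#' @inheritParams isotype_frequencies
#' @param by Optional grouping column name (e.g. `"group"`).
#' @return List of class `surveil_cdr3_dist` with `distribution` and `summary`
#'   tibbles.
#' @export
cdr3_length_distribution <- function(rearrangements, by = NULL) {
  rearr <- as_tibble(rearrangements)
  stopifnot("cdr3_aa" %in% names(rearr), nrow(rearr) > 0)
  rearr$.len <- nchar(rearr$cdr3_aa)
  rearr$.grp <- if (is.null(by)) "all" else as.character(rearr[[by]])
  dist <- rearr |>
    dplyr::group_by(.data$.grp) |>
    dplyr::group_modify(function(df, key) {
      rng <- seq(min(df$.len), max(df$.len))
      counts <- table(factor(df$.len, levels = rng))
      tibble(length = rng, n = as.integer(counts),
             freq = as.integer(counts) / nrow(df))
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(group = ".grp")
  summary <- dist |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      modal_length = .data$length[which.max(.data$freq)],
      auc = if (dplyr::n() > 1) {
        sum((.data$freq[-dplyr::n()] + .data$freq[-1]) / 2)
      } else 0,
      .groups = "drop"
    )
  structure(list(distribution = dist, summary = summary), class = "surveil_cdr3_dist")
}

#' Canonical V-gene usage and the W33L mutation
#'
#' Per-sample usage frequency of `canonical_v`, residue counts at CDR1 window
#' position `w33l_pos` (1-based within the annotated window) among canonical
#' records, and a Fisher's exact test of W33L carriage by group when two
#' groups are present. Records whose window extends past the alignment are
#' flagged and excluded from the residue counts.
#'
#' @inheritParams isotype_frequencies
#' @param canonical_v Canonical V gene name (default `"VH1-72"`).
#' @param w33l_pos Window position of the W->L hotspot (default 8,
#'   corresponding to residue 33 of the V region).
#' @return List of class `surveil_vh172`: `usage` (per-sample), `w33l`
#'   (per-group residue counts and W33L fraction), `test`
#'   (a [surveil_test][new_surveil_test] or `NULL`), `records` (per-record
#'   W33L calls among canonical records).
#' @export
vh1_72_analysis <- function(rearrangements, canonical_v = "VH1-72", w33l_pos = 8) {
  rearr <- as_tibble(rearrangements)
  if (!("sample_id" %in% names(rearr))) rearr$sample_id <- "all"
  usage <- rearr |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("group", "sample_id")))) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_canonical = sum(.data$v_call == canonical_v),
      usage = .data$n_canonical / .data$n_total,
      .groups = "drop"
    )
  canon <- rearr[rearr$v_call == canonical_v, , drop = FALSE]
  records <- NULL
  w33l_tab <- NULL
  test <- NULL
  if (nrow(canon) > 0 && all(c("cdr1_start", "sequence_alignment") %in% names(canon))) {
    pos <- canon$cdr1_start + w33l_pos - 1
    ok <- !is.na(pos) & pos <= nchar(canon$sequence_alignment)
    residue <- rep(NA_character_, nrow(canon))
    residue[ok] <- substr(canon$sequence_alignment[ok], pos[ok], pos[ok])
    records <- canon |>
      dplyr::mutate(
        w33l_residue = residue,
        w33l = .data$w33l_residue == "L",
        window_ok = ok
      )
    w33l_tab <- records |>
      dplyr::filter(.data$window_ok) |>
      dplyr::group_by(dplyr::across(dplyr::any_of("group"))) |>
      dplyr::summarise(
        n = dplyr::n(),
        n_W = sum(.data$w33l_residue == "W"),
        n_L = sum(.data$w33l_residue == "L"),
        n_other = .data$n - .data$n_W - .data$n_L,
        w33l_fraction = .data$n_L / .data$n,
        .groups = "drop"
      )
    if ("group" %in% names(records) && dplyr::n_distinct(records$group) == 2) {
      ok_rec <- records[records$window_ok, , drop = FALSE]
      tab <- table(factor(ok_rec$w33l, levels = c(TRUE, FALSE)), ok_rec$group)
      test <- fisher_exact(unclass(tab))
    }
  }
  structure(list(usage = usage, w33l = w33l_tab, test = test, records = records),
            class = "surveil_vh172")
}

#' Clone-size statistics
#'
#' Per-clone log10 sizes (per group when a `group` column is present) and a
#' two-tailed Mann-Whitney comparison of the two groups' log10 clone sizes.
#'
#' @param rearrangements Tibble with `clone_id` (and optional `group`).
#' @param min_size Smallest clone size entering the comparison (default 1,
#'   all clones; 2 restricts to multi-member clonotypes, useful when deep
#'   naive sampling floods the comparison with singletons).
#' @return List with `clones` (tibble: clone_id, group, size, log10_size) and
#'   `test` ([surveil_test][new_surveil_test] or `NULL`).
#' @export
clone_size_stats <- function(rearrangements, min_size = 1) {
  rearr <- as_tibble(rearrangements)
  stopifnot("clone_id" %in% names(rearr))
  grouping <- intersect(c("group", "clone_id"), names(rearr))
  clones <- rearr |>
    dplyr::count(dplyr::across(dplyr::all_of(grouping)), name = "size") |>
    dplyr::filter(.data$size >= min_size) |>
    dplyr::mutate(log10_size = log10(.data$size))
  test <- NULL
  if ("group" %in% names(clones) && dplyr::n_distinct(clones$group) == 2) {
    sp <- split(clones$log10_size, clones$group)
    if (all(lengths(sp) >= 2)) test <- mann_whitney(sp[[1]], sp[[2]])
  }
  list(clones = clones, test = test)
}

#' Kullback-Leibler sequence logo
#'
#' For each window position and amino acid, the pseudocount-smoothed observed
#' frequency is `p = (count + pseudocount * q) / (n + pseudocount)` where `q`
#' is the background frequency; the logo weight is `p * log2(p / q)`, signed
#' positive when the residue is enriched over background and negative when
#' depleted (drawn below the axis).
#'
#' @param windows Character vector of equal-length aligned amino-acid windows.
#' @param background Named per-residue background frequencies (strictly
#'   positive, summing to 1); uniform over the 20 canonical residues by
#'   default.
#' @param pseudocount Smoothing mass distributed by background (default 1).
#' @return Object of class `surveil_logo`: list with `weights` (positions x
#'   residues matrix, bits), `background`, `n_sequences`.
#' @export
kl_logo <- function(windows, background = NULL, pseudocount = 1) {
  stopifnot(length(windows) > 0)
  L <- unique(nchar(windows))
  if (length(L) != 1) abort("all windows must have equal length")
  if (is.null(background)) {
    background <- setNames(rep(1 / length(AA_ALPHABET), length(AA_ALPHABET)), AA_ALPHABET)
  }
  background <- background[AA_ALPHABET]
  if (any(is.na(background)) || any(background <= 0)) {
    abort("background must be strictly positive over the 20 canonical residues")
  }
  if (abs(sum(background) - 1) > 1e-8) abort("background frequencies must sum to 1")
  n <- length(windows)
  chars <- do.call(rbind, strsplit(windows, ""))
  weights <- t(vapply(seq_len(L), function(i) {
    counts <- table(factor(chars[, i], levels = AA_ALPHABET))
    p <- (as.numeric(counts) + pseudocount * background) / (n + pseudocount)
    as.numeric(p * log2(p / background))
  }, numeric(length(AA_ALPHABET))))
  dimnames(weights) <- list(position = seq_len(L), residue = AA_ALPHABET)
  structure(
    list(weights = weights, background = background, n_sequences = n),
    class = "surveil_logo"
  )
}

#' @export
print.surveil_logo <- function(x, ...) {
  cat(sprintf("<surveil_logo> %d positions, %d sequences\n",
              nrow(x$weights), x$n_sequences))
  invisible(x)
}

#' @rdname kl_logo
#' @param x A `surveil_logo`.
#' @param ... Unused.
#' @export
tidy.surveil_logo <- function(x, ...) {
  as_tibble(as.data.frame.table(x$weights, responseName = "weight")) |>
    dplyr::mutate(position = as.integer(as.character(.data$position)),
                  residue = as.character(.data$residue))
}
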