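# ggplot2 views of the main result types.

#' Plot the compound-score histogram
#'
#' Column chart of per-group percentages per compound-score bin
#' (see [compound_distribution()]).
#'
#' @param dist Tibble from [compound_distribution()].
#' @return A ggplot object.
#' @export
plot_compound_histogram <- function(dist) {
  p <- ggplot(dist, aes(x = (.data$bin_left + .data$bin_right) / 2, y = .data$pct))
  if ("group" %in% names(dist)) {
    p <- p + geom_col(aes(fill = .data$group), position = "dodge")
  } else {
    p <- p + geom_col()
  }
  p + labs(x = "compound score (malignant - nonmalignant)", y = "% of cells") +
    theme_minimal()
}

#' Plot CDR3 length distributions
#'
#' @param x A `surveil_cdr3_dist` from [cdr3_length_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surveil_cdr3_dist <- function(x, ...) {
  ggplot(x$distribution, aes(x = .data$length, y = .data$freq, colour = .data$group)) +
    geom_line() + geom_point() +
    labs(x = "CDR3 length (AA)", y = "frequency") +
    theme_minimal()
}

#' Plot a Kullback-Leibler sequence logo
#'
#' Letters above zero are enriched over background, letters below are
#' depleted; letter placement is a stacked text rendering of the signed
#' per-residue weights.
#'
#' @param x A `surveil_logo` from [kl_logo()].
#' @param min_abs_weight Residues with |weight| below this are hidden.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surveil_logo <- function(x, min_abs_weight = 0.01, ...) {
  df <- tidy(x) |> dplyr::filter(abs(.data$weight) >= min_abs_weight)
  pos <- df |>
    dplyr::group_by(.data$position, up = .data$weight > 0) |>
    dplyr::arrange(dplyr::desc(abs(.data$weight)), .by_group = TRUE) |>
    dplyr::mutate(
      top = ifelse(.data$up, cumsum(.data$weight), -cumsum(abs(.data$weight))),
      mid = .data$top - .data$weight / 2
    ) |>
    dplyr::ungroup()
  ggplot(pos, aes(x = .data$position, y = .data$mid, label = .data$residue)) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    geom_text(aes(size = abs(.data$weight), colour = .data$weight > 0),
              show.legend = FALSE) +
    scale_size_continuous(range = c(2, 8)) +
    scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b")) +
    labs(x = "window position", y = "KL weight (bits)") +
    theme_minimal()
}

#' Plot per-clone log10 sizes by group
#'
#' @param clone_sizes `clones` tibble from [clone_size_stats()].
#' @return A ggplot object.
#' @export
plot_clone_sizes <- function(clone_sizes) {
  ggplot(clone_sizes, aes(x = .data$group, y = .data$log10_size)) +
    geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    labs(x = NULL, y = "log10 clone size") +
    theme_minimal()
}

#' Heatmap of V-J pairing counts
#'
#' @param vj Long tibble from [vj_matrix()].
#' @return A ggplot object.
#' @export
plot_vj_pairs <- function(vj) {
  ggplot(vj, aes(x = .data$j_call, y = .data$v_call, fill = .data$n)) +
    geom_tile() +
    labs(x = "J segment", y = "V segment", fill = "records") +
    theme_minimal()
}
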