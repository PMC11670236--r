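# Independent brute-force oracles used to verify the package implementations.
# These deliberately take the naive enumeration route rather than the dynamic
# programs used inside the package.

# exact two-tailed Mann-Whitney p by enumerating every assignment of n ranks
# out of n + m (midranks handle ties)
oracle_mw_p <- function(x, y) {
  n <- length(x)
  r <- rank(c(x, y))
  subs <- utils::combn(length(r), n)
  W <- colSums(matrix(r[subs], nrow = n))
  w <- sum(r[seq_len(n)])
  min(1, 2 * min(mean(W <= w + 1e-9), mean(W >= w - 1e-9)))
}

# exact two-tailed signed-rank p by enumerating all 2^n sign patterns
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)
  w <- sum(r[d > 0])
  min(1, 2 * min(mean(W <= w + 1e-9), mean(W >= w - 1e-9)))
}

# two-tailed Fisher p from explicit binomial coefficients over all tables
# with the observed margins
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; N <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  prob <- exp(lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(N, c1))
  p_obs <- exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(N, c1))
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# single-linkage clonal partition via igraph connected components
oracle_clonotype_partition <- function(rearr, threshold) {
  n <- nrow(rearr)
  len <- nchar(rearr$cdr3_aa)
  edges <- matrix(0L, nrow = 0, ncol = 2)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (rearr$v_call[i] != rearr$v_call[j]) next
      if (rearr$j_call[i] != rearr$j_call[j]) next
      if (len[i] != len[j]) next
      a <- strsplit(rearr$cdr3_aa[i], "")[[1]]
      b <- strsplit(rearr$cdr3_aa[j], "")[[1]]
      if (mean(a == b) >= threshold) edges <- rbind(edges, c(i, j))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

# canonical form of a partition: list of member index sets
canonical_partition <- function(labels) {
  blocks <- lapply(split(seq_along(labels), labels), sort)
  unname(blocks[order(vapply(blocks, min, numeric(1)))])
}

# manual linear-interpolation quantile (independent of stats::quantile)
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  if (lo + 1 >= length(s)) return(s[length(s)])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

random_repertoire <- function(n, seed) {
  withr::with_seed(seed, {
    lens <- sample(6:8, n, replace = TRUE)
    tibble::tibble(
      sequence_id = sprintf("s%03d", seq_len(n)),
      v_call = sample(c("VH1-72", "VH2-2", "VH3-6"), n, replace = TRUE),
      j_call = sample(c("JH1", "JH2"), n, replace = TRUE),
      cdr3_aa = vapply(lens, function(L) {
        paste(sample(c("A", "G", "S"), L, replace = TRUE), collapse = "")
      }, character(1))
    )
  })
}
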