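# Brute-force reference implementations, kept deliberately independent of
# the package code paths they check.

oracle_percentile <- function(values, q) {
  x <- sort(unname(values))
  n <- length(x)
  p <- 1 + (q / 100) * (n - 1)
  lo <- floor(p)
  fr <- p - lo
  if (lo >= n) x[n] else x[lo] + fr * (x[lo + 1] - x[lo])
}

oracle_median <- function(values) {
  x <- sort(unname(values))
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# average (mid) ranks by counting, no call to rank()
oracle_midrank <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (1 + sum(v == v[i])) / 2
  }, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x)
  ry <- oracle_midrank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

oracle_kw_H <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- oracle_midrank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  rank_sums <- vapply(seq_along(groups), function(j) sum(r[idx == j]),
                      numeric(1))
  H <- 12 / (N * (N + 1)) * sum(rank_sums^2 / lengths(groups)) - 3 * (N + 1)
  tie_sizes <- as.numeric(table(x))
  H / (1 - sum(tie_sizes^3 - tie_sizes) / (N^3 - N))
}

# triple-loop reimplementation of the whole screen on a normalized matrix
oracle_screen <- function(nm, ann, target, median_min, q_max, q) {
  hits <- character(0)
  subtypes <- unique(ann$subtype)
  for (gene in rownames(nm)) {
    tvals <- nm[gene, ann$sample_id[ann$subtype == target]]
    ok <- oracle_median(tvals) > median_min
    for (bg in setdiff(subtypes, target)) {
      bvals <- nm[gene, ann$sample_id[ann$subtype == bg]]
      if (!(oracle_percentile(bvals, q) < q_max)) ok <- FALSE
    }
    if (ok) hits <- c(hits, gene)
  }
  hits
}

# small cohort configuration used throughout the unit tests (the full-size
# default cohort is exercised by the acceptance suite)
small_sim_config <- function(seed, ...) {
  sim_config(seed,
             subtypes = c(alpha = 12, beta = 30, gamma = 20),
             n_genes = 200, n_markers = 3, ...)
}
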