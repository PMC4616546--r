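test_that("linear-interpolation percentile matches its defining formula", {
  expect_equal(expr_percentile(1:100, 95), 95.05)
  expect_equal(expr_percentile(c(42), 95), 42)
  expect_equal(expr_percentile(c(42), 3), 42)
  expect_equal(expr_percentile(c(0, 0, 0, 10), 50), 0)
  expect_error(expr_percentile(numeric(0), 95), "empty")

  set.seed(101)
  for (i in 1:25) {
    v <- round(rexp(sample(1:50, 1)) * 10, sample(0:2, 1))
    q <- runif(1, 0.5, 100)
    expect_equal(expr_percentile(v, q), oracle_percentile(v, q),
                 tolerance = 1e-12)
  }
})

test_that("nearest-rank percentile returns an order statistic", {
  expect_equal(expr_percentile(1:100, 95, "nearest-rank"), 95)
  expect_equal(expr_percentile(c(3, 1, 2), 50, "nearest-rank"), 2)
  expect_equal(expr_percentile(c(3, 1, 2), 1, "nearest-rank"), 1)
  expect_equal(expr_percentile(c(3, 1, 2), 100, "nearest-rank"), 3)
})

make_toy_summary <- function() {
  nm <- rbind(A1 = c(1, 2, 3, 0.1, 0.2, 0.05, 0.3, 0.1, 0.2),
              A2 = rep(5, 9))
  colnames(nm) <- sprintf("s%d", 1:9)
  ann <- data.frame(sample_id = sprintf("s%d", 1:9),
                    subtype = rep(c("A", "B", "C"), each = 3),
                    stringsAsFactors = FALSE)
  list(nm = nm, ann = ann)
}

test_that("summarize_by_subtype computes per-group median and percentile", {
  toy <- make_toy_summary()
  s <- summarize_by_subtype(toy$nm, toy$ann, q = 95)
  # subtype A holds values (1,2,3): median 2, linear q95 at p = 2.9
  expect_equal(s$medians["A1", "A"], 2)
  expect_equal(s$percentiles["A1", "A"], 2.9)
  # constant gene: median = q95 = c everywhere
  expect_true(all(s$medians["A2", ] == 5))
  expect_true(all(s$percentiles["A2", ] == 5))
  expect_identical(unname(s$n_samples), c(3L, 3L, 3L))
})

test_that("summaries match a brute-force group-by on a seeded cohort", {
  sim <- simulate_expression(small_sim_config(5))
  nm <- suppressMessages(normalize_by_reference(sim$expression))
  s <- summarize_by_subtype(nm, sim$annotation, q = 95)
  for (st in unique(sim$annotation$subtype)) {
    ss <- sim$annotation$sample_id[sim$annotation$subtype == st]
    for (gene in sample(rownames(nm), 20)) {
      expect_equal(s$medians[gene, st], oracle_median(nm[gene, ss]),
                   tolerance = 1e-12)
      expect_equal(s$percentiles[gene, st],
                   oracle_percentile(nm[gene, ss], 95), tolerance = 1e-12)
    }
  }
})

test_that("subtypes below min_samples and unannotated samples are handled", {
  toy <- make_toy_summary()
  ann <- toy$ann
  ann <- ann[-(1:2), ]  # subtype A down to one sample
  expect_error(suppressMessages(summarize_by_subtype(toy$nm, ann)),
               "min_samples.*A")
  # samples in the matrix but not the annotation are simply excluded
  extra <- cbind(toy$nm, s10 = c(99, 99))
  expect_message(s <- summarize_by_subtype(extra, toy$ann, q = 95),
                 "excluding 1")
  expect_equal(s$medians["A1", "A"], 2)
})

test_that("both screen thresholds are strict", {
  medians <- cbind(target = c(8, 8 + 1e-9, 10),
                   bg = c(0.01, 0.01, 0.01))
  percentiles <- cbind(target = c(8, 8 + 1e-9, 10),
                       bg = c(0.15, 0.15 - 1e-9, 0.149))
  rownames(medians) <- rownames(percentiles) <- c("at8", "above8", "clear")
  s <- subtype_summary(medians, percentiles,
                       c(target = 10L, bg = 10L), q = 95)
  hits <- apply_screen(s, screen_criteria("target"))
  expect_identical(hits$hit[match(c("at8", "above8", "clear"),
                                  hits$gene_id)],
                   c(FALSE, TRUE, TRUE))
})

test_that("apply_screen equals a brute-force triple loop on random inputs", {
  set.seed(202)
  for (i in 1:10) {
    n_genes <- sample(10:50, 1)
    n_samples <- sample(9:30, 1)
    nm <- matrix(rexp(n_genes * n_samples) * sample(c(0.01, 1, 20), 1),
                 nrow = n_genes,
                 dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                 sprintf("s%02d", seq_len(n_samples))))
    ann <- data.frame(sample_id = colnames(nm),
                      subtype = sample(c("X", "Y", "Z"), n_samples,
                                       replace = TRUE),
                      stringsAsFactors = FALSE)
    if (min(table(ann$subtype)) < 3 || length(unique(ann$subtype)) < 2) next
    crit <- screen_criteria("X", median_min = runif(1, 0.1, 5),
                            background_q_max = runif(1, 0.05, 2))
    s <- summarize_by_subtype(nm, ann, q = 95)
    hits <- apply_screen(s, crit)
    expect_setequal(hits$gene_id[hits$hit],
                    oracle_screen(nm, ann, "X", crit$median_min,
                                  crit$background_q_max, 95))
  }
})

test_that("tightening either threshold never adds a hit", {
  sim <- simulate_expression(small_sim_config(9))
  nm <- suppressMessages(normalize_by_reference(sim$expression))
  s <- summarize_by_subtype(nm, sim$annotation)
  base <- apply_screen(s, screen_criteria("alpha", median_min = 2,
                                          background_q_max = 0.5))
  for (mm in c(4, 8, 16)) {
    h <- apply_screen(s, screen_criteria("alpha", median_min = mm,
                                         background_q_max = 0.5))
    expect_true(all(h$gene_id[h$hit] %in% base$gene_id[base$hit]))
  }
  for (qm in c(0.25, 0.1, 0.02)) {
    h <- apply_screen(s, screen_criteria("alpha", median_min = 2,
                                         background_q_max = qm))
    expect_true(all(h$gene_id[h$hit] %in% base$gene_id[base$hit]))
  }
})

test_that("summaries and hits are invariant to sample order", {
  sim <- simulate_expression(small_sim_config(13))
  nm <- suppressMessages(normalize_by_reference(sim$expression))
  crit <- screen_criteria("alpha")
  s1 <- summarize_by_subtype(nm, sim$annotation)
  set.seed(1)
  perm <- sample(ncol(nm))
  s2 <- summarize_by_subtype(nm[, perm], sim$annotation[rev(seq_len(nrow(sim$annotation))), ])
  expect_equal(s1$medians, s2$medians)
  expect_equal(s1$percentiles, s2$percentiles)
  expect_identical(apply_screen(s1, crit), apply_screen(s2, crit))
})

test_that("condition_counts reports counts and half-up percentages", {
  medians <- cbind(t = c(10, 9, 0.1, 0.2), b = c(0.05, 0.1, 0.05, 0.05))
  percentiles <- cbind(t = c(10, 9, 0.1, 0.2), b = c(0.1, 0.2, 0.1, 0.1))
  rownames(medians) <- rownames(percentiles) <- sprintf("g%d", 1:4)
  s <- subtype_summary(medians, percentiles, c(t = 5L, b = 5L), q = 95)
  cc <- condition_counts(s, screen_criteria("t"))
  expect_equal(cc$count[cc$condition == "cond1_median"], 2)
  expect_equal(cc$percent[cc$condition == "cond1_median"], 50.0)
  expect_equal(cc$count[cc$subtype == "b"], 3)
  expect_equal(cc$percent[cc$subtype == "b"], 75.0)
  # all genes / no genes passing
  s2 <- subtype_summary(cbind(t = rep(20, 4), b = rep(0.001, 4)),
                        cbind(t = rep(25, 4), b = rep(0.01, 4)),
                        c(t = 5L, b = 5L), q = 95)
  cc2 <- condition_counts(s2, screen_criteria("t"))
  expect_true(all(cc2$percent == 100.0))
  s3 <- subtype_summary(medians * 0 + 1, percentiles * 0 + 1,
                        c(t = 5L, b = 5L), q = 95)
  cc3 <- condition_counts(s3, screen_criteria("t"))
  expect_true(all(cc3$count == 0) && all(cc3$percent == 0.0))
})

test_that("a summary computed at another percentile is refused", {
  toy <- make_toy_summary()
  s <- summarize_by_subtype(toy$nm, toy$ann, q = 90)
  expect_error(apply_screen(s, screen_criteria("A")), "90th")
})
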