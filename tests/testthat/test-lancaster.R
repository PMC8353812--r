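test_that("gamma upper quantile has its closed forms and limits", {
  expect_equal(gamma_upper_quantile(0.05, 2), -2 * log(0.05),
               tolerance = 1e-10)
  expect_equal(gamma_upper_quantile(0.05, 2), 5.9915, tolerance = 1e-4)
  expect_equal(gamma_upper_quantile(1, 2), 0)
  for (p in c(0.9, 0.5, 0.1, 0.01))
    expect_equal(gamma_upper_quantile(p, 4),
                 qchisq(p, df = 4, lower.tail = FALSE), tolerance = 1e-10)
  # continuous and decreasing in p
  ps <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(gamma_upper_quantile(ps, 3)) < 0))
  expect_error(gamma_upper_quantile(0, 2), "0, 1")
  expect_error(gamma_upper_quantile(0.5, -1), "positive")
})

test_that("lancaster_pvalue: identity, hand example, degenerate weights", {
  expect_equal(lancaster_pvalue(0.123, 2)$p_agg, 0.123, tolerance = 1e-12)

  r <- lancaster_pvalue(c(0.05, 0.05), c(2, 2))
  expect_equal(r$statistic, -4 * log(0.05), tolerance = 1e-10)
  expect_equal(r$df, 4)
  # chi-squared(4) survival closed form (1 + T/2) exp(-T/2)
  expect_equal(r$p_agg, (1 + r$statistic / 2) * exp(-r$statistic / 2),
               tolerance = 1e-12)
  expect_lt(abs(r$p_agg - 0.0174), 1e-3)

  und <- lancaster_pvalue(c(0.5, 0.5), c(0, 0))
  expect_false(und$defined)
  expect_true(is.na(und$p_agg))

  # zero-weight and missing pairs are dropped, not imputed
  mix <- lancaster_pvalue(c(0.02, NA, 0.9), c(2, 5, 0))
  expect_equal(mix$k_used, 1L)
  expect_equal(mix$p_agg, 0.02, tolerance = 1e-12)
})

test_that("lancaster with unit weights w = 2 is exactly Fisher", {
  set.seed(31)
  for (rep in 1:300) {
    k <- sample(1:6, 1)
    p <- runif(k)
    expect_lt(abs(lancaster_pvalue(p, rep(2, k))$p_agg - bf_fisher(p)),
              1e-10)
  }
})

test_that("weight dominance: a huge weight pins the aggregate to its p", {
  p <- c(0.3, 0.8)
  last <- sapply(c(2, 20, 200, 2000, 2e4), function(w)
    lancaster_pvalue(p, c(w, 2))$p_agg)
  expect_true(all(diff(abs(last - 0.3)) < 0))
  expect_lt(abs(last[length(last)] - 0.3), 0.01)
})

test_that("aggregation is invariant to transcript order within a gene", {
  p <- c(0.01, 0.2, 0.7); w <- c(10, 3, 1)
  o <- c(3, 1, 2)
  expect_equal(lancaster_pvalue(p, w)$p_agg,
               lancaster_pvalue(p[o], w[o])$p_agg, tolerance = 1e-14)
})

test_that("aggregate_genes reproduces manual per-gene aggregation", {
  tx <- data.frame(
    transcript_id = paste0("t", 1:5),
    base_mean = c(10, 5, 0, 8, 2),
    p_interaction = c(0.5, 0.2, 0.9, 0.01, 0.6),
    p_type = c(0.03, 0.5, 0.1, 0.2, 0.4),
    p_parity = c(0.7, 0.8, 0.2, 0.9, 0.3))
  gm <- data.frame(transcript_id = paste0("t", 1:5),
                   gene_id = c("gA", "gA", "gA", "gB", "gB"))
  res <- aggregate_genes(tx, gm)
  # gA: t3 has weight 0 and is dropped
  manual <- lancaster_pvalue(c(0.03, 0.5), c(10, 5))$p_agg
  expect_equal(res$p_agg_type[res$gene_id == "gA"], manual,
               tolerance = 1e-12)
  # gB is a two-transcript gene
  manual_b <- lancaster_pvalue(c(0.2, 0.4), c(8, 2))$p_agg
  expect_equal(res$p_agg_type[res$gene_id == "gB"], manual_b,
               tolerance = 1e-12)
  expect_equal(res$fdr_type, bf_bh(res$p_agg_type))
  expect_error(aggregate_genes(tx, gm[-1, ]), "missing")
})

test_that("single-transcript genes inherit the transcript p exactly", {
  tx <- data.frame(transcript_id = "t1", base_mean = 7,
                   p_interaction = 0.4, p_type = 0.02, p_parity = 0.9)
  gm <- data.frame(transcript_id = "t1", gene_id = "g1")
  res <- aggregate_genes(tx, gm)
  expect_equal(res$p_agg_type, 0.02, tolerance = 1e-12)
  expect_equal(res$p_agg_interaction, 0.4, tolerance = 1e-12)
  expect_equal(res$p_agg_parity, 0.9, tolerance = 1e-12)
})

test_that("genes with all-zero weights are flagged undefined", {
  tx <- data.frame(transcript_id = c("t1", "t2"), base_mean = c(0, 0),
                   p_interaction = c(0.1, 0.2), p_type = c(0.1, 0.2),
                   p_parity = c(0.1, 0.2))
  gm <- data.frame(transcript_id = c("t1", "t2"), gene_id = c("g1", "g1"))
  res <- aggregate_genes(tx, gm)
  expect_false(res$defined)
  expect_true(is.na(res$p_agg_type))
})

test_that("gene log2fc matches the transcript for singleton genes and sums isoforms", {
  sheet <- make_sheet(c(2, 2, 2, 2))
  ns <- nrow(sheet)
  set.seed(33)
  mu <- ifelse(sheet$milk_type == "milk", 100 * 2^1.5, 100)
  cm <- rbind(
    t1 = rnbinom(ns, mu = mu, size = 1 / 0.05),
    t2 = rnbinom(ns, mu = mu, size = 1 / 0.05),
    t3 = rnbinom(ns, mu = 150, size = 1 / 0.05))
  colnames(cm) <- sheet$sample_id
  storage.mode(cm) <- "integer"
  gm <- data.frame(transcript_id = c("t1", "t2", "t3"),
                   gene_id = c("gA", "gA", "gB"))
  sf <- setNames(rep(1, ns), sheet$sample_id)
  lfc <- gene_log2fc(cm, gm, sheet, sf)
  r1 <- nb_glm_test(cm["t3", ], sheet, sf,
                    estimate_dispersion(cm, sf, sheet)[["t3"]])
  expect_equal(unname(lfc["gB"]), r1$log2fc_type, tolerance = 0.2)
  expect_lt(abs(lfc["gA"] - 1.5), 0.5)
})

test_that("deg_partition removes interaction genes and low fold changes", {
  gr <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    fdr_interaction = c(0.004, 0.5, 0.5, 0.5),
    fdr_type = c(0.001, 0.004, 0.004, 0.004))
  lfc <- c(g1 = 3, g2 = 1.5, g3 = 1.8, g4 = -2.4)
  deg <- deg_partition(gr, lfc)
  expect_equal(deg$interaction, "g1")
  expect_setequal(deg$type, c("g3", "g4"))  # g2 excluded at |lfc| = 1.5
})
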