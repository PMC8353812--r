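test_that("size factors reproduce the median-of-ratios definition", {
  cm <- matrix(c(10L, 30L, 20L, 60L), 2, 2,
               dimnames = list(c("t1", "t2"), c("s1", "s2")))
  expect_equal(unname(size_factors(cm)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-10)

  ident <- matrix(rep(c(5L, 9L, 40L), 3), 3, 3,
                  dimnames = list(paste0("t", 1:3), paste0("s", 1:3)))
  expect_equal(unname(size_factors(ident)), c(1, 1, 1))

  # scale equivariance: multiplying one column by c multiplies its factor
  # relative to every other column by c (the global geometric-mean
  # constant rescales all factors together)
  set.seed(1)
  cm2 <- matrix(rpois(40, 50) + 1L, 8, 5,
                dimnames = list(paste0("t", 1:8), paste0("s", 1:5)))
  sf <- size_factors(cm2)
  cm3 <- cm2; cm3[, 2] <- cm3[, 2] * 5L
  sf3 <- size_factors(cm3)
  expect_equal(unname(sf3[2] / sf3[1]), unname(5 * sf[2] / sf[1]),
               tolerance = 1e-12)

  # row-permutation invariance
  expect_equal(size_factors(cm2[sample(8), ]), sf)

  allz <- matrix(c(0L, 3L, 4L, 0L), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(allz), "pseudo")
  expect_length(size_factors(allz, allow_pseudo_reference = TRUE), 2)
})

test_that("size factors and base means agree with DESeq2", {
  skip_if_not_installed("DESeq2")
  set.seed(11)
  cm <- matrix(rnbinom(300, mu = 80, size = 2) + 1L, 30, 10,
               dimnames = list(paste0("t", 1:30), paste0("s", 1:10)))
  sheet <- make_sheet(c(2, 1, 1, 1))
  colnames(cm) <- sheet$sample_id
  dds <- DESeq2::DESeqDataSetFromMatrix(
    cm, data.frame(row.names = sheet$sample_id,
                   type = factor(sheet$milk_type)), ~type)
  dds <- DESeq2::estimateSizeFactors(dds)
  expect_equal(unname(size_factors(cm)),
               unname(DESeq2::sizeFactors(dds)), tolerance = 1e-8)
  expect_equal(unname(base_mean(cm, size_factors(cm))),
               unname(rowMeans(DESeq2::counts(dds, normalized = TRUE))),
               tolerance = 1e-8)
})

test_that("base_mean is the mean of normalized counts", {
  cm <- matrix(c(0L, 0L, 4L, 8L), 2, 2, byrow = TRUE,
               dimnames = list(c("z", "t"), c("s1", "s2")))
  sf <- c(s1 = 1, s2 = 2)
  expect_equal(unname(base_mean(cm, sf)), c(0, 4))
  set.seed(2)
  cm2 <- matrix(rpois(20, 30), 5, 4,
                dimnames = list(paste0("t", 1:5), paste0("s", 1:4)))
  sf2 <- setNames(runif(4, 0.5, 2), colnames(cm2))
  bm <- base_mean(cm2, sf2)
  for (i in 1:5)
    expect_equal(unname(bm[i]), mean(cm2[i, ] / sf2))
})

test_that("moment dispersion recovers truth and degenerates sensibly", {
  sheet <- make_sheet(c(4, 4, 4, 4))  # 32 samples
  ns <- nrow(sheet)
  set.seed(3)
  pois <- matrix(rpois(200 * ns, 500), 200, ns,
                 dimnames = list(paste0("t", 1:200), sheet$sample_id))
  sf1 <- setNames(rep(1, ns), sheet$sample_id)
  d_pois <- estimate_dispersion(pois, sf1, sheet)
  expect_lt(median(d_pois), 0.05)

  nb <- matrix(rnbinom(500 * ns, mu = 300, size = 2), 500, ns,
               dimnames = list(paste0("t", 1:500), sheet$sample_id))
  d_nb <- estimate_dispersion(nb, sf1, sheet)
  expect_gt(median(d_nb), 0.35)
  expect_lt(median(d_nb), 0.65)

  const <- matrix(7L, 2, ns,
                  dimnames = list(c("a", "b"), sheet$sample_id))
  expect_equal(unname(estimate_dispersion(const, sf1, sheet)),
               c(1e-8, 1e-8))
})

test_that("nb_glm_test recovers a planted milk-type effect", {
  sheet <- make_sheet(c(3, 3, 2, 2))  # 10 dams, 10 samples per group
  set.seed(4)
  mu <- ifelse(sheet$milk_type == "milk", 200 * 2^3, 200)
  sf <- setNames(rep(1, nrow(sheet)), sheet$sample_id)
  y <- rnbinom(nrow(sheet), mu = mu, size = 1 / 0.05)
  r <- nb_glm_test(y, sheet, sf, dispersion = 0.05)
  expect_lt(r$p_type, 1e-4)
  expect_lt(abs(r$log2fc_type - 3), 0.5)
  expect_true(r$converged)
})

test_that("plug-in LRT p_type is uniform under the null at known dispersion", {
  sheet <- make_sheet(c(3, 4, 3, 2))
  ns <- nrow(sheet)
  set.seed(5)
  n_tx <- 2000
  cm <- matrix(rnbinom(n_tx * ns, mu = 300, size = 1 / 0.05), n_tx, ns,
               dimnames = list(paste0("t", 1:n_tx), sheet$sample_id))
  res <- de_test(cm, sheet, sf = setNames(rep(1, ns), sheet$sample_id),
                 dispersions = setNames(rep(0.05, n_tx), rownames(cm)),
                 method = "lrt")
  rate <- mean(res$p_type <= 0.05)
  expect_lt(abs(rate - 0.05), 0.01)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(6)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), bf_bh(p))
    expect_true(all(bh_adjust(p) >= p))
  }
  # NA passthrough with m = number of tested entries
  p <- c(0.01, NA, 0.02)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], bf_bh(c(0.01, 0.02)))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("det_partition applies the published rule hierarchy", {
  res <- data.frame(
    transcript_id = paste0("t", 1:4),
    log2fc_type = c(0.5, 1.5, 2.5, 2.5),
    fdr_interaction = c(0.005, 0.5, 0.5, 0.5),
    fdr_type = c(0.001, 0.005, 0.005, 0.5),
    fdr_parity = c(0.001, 0.5, 0.02, 0.001))
  det <- det_partition(res)
  expect_equal(det$interaction, "t1")   # interaction wins, removed elsewhere
  expect_equal(det$type, "t3")          # t2 fails |lfc| >= 2
  expect_setequal(det$parity, "t4")     # no lfc filter for parity
  expect_length(intersect(det$interaction, det$type), 0)
})

test_that("expression summary means, ranks, and tie-breaking", {
  cm <- matrix(c(10L, 10L, 30L, 30L, 10L, 10L), 3, 2, byrow = TRUE,
               dimnames = list(c("gB", "gA", "gC"), c("s1", "s2")))
  sf <- c(s1 = 1, s2 = 1)
  sm <- expression_summary(cm, sf, c(s1 = "col", s2 = "milk"))
  expect_equal(sm$rank_col[sm$id == "gA"], 1L)
  # equal means: adjacent ranks, broken by id
  expect_equal(sm$rank_col[sm$id == "gB"], 2L)
  expect_equal(sm$rank_col[sm$id == "gC"], 3L)
  set.seed(7)
  cm2 <- matrix(rpois(40, 100), 10, 4,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  sf2 <- setNames(runif(4, .5, 2), colnames(cm2))
  g <- setNames(c("a", "a", "b", "b"), colnames(cm2))
  sm2 <- expression_summary(cm2, sf2, g)
  y <- sweep(cm2, 2, sf2, "/")
  expect_equal(sm2$mean_a, unname(rowMeans(y[, 1:2])))
  expect_equal(sm2$mean_b, unname(rowMeans(y[, 3:4])))
})

test_that("de_test results are invariant to row and sample order", {
  cfg <- sim_config(seed = 21, n_queries = 60, dams_per_parity = c(2, 2, 2, 2))
  truth <- simulate_de_truth(sprintf("T%02d", 1:60), cfg)
  sim <- simulate_counts(cfg, truth)
  r1 <- de_test(sim$counts, sim$sheet)
  set.seed(8)
  r2 <- de_test(sim$counts[sample(60), sample(nrow(sim$sheet))],
                sim$sheet[sample(nrow(sim$sheet)), ])
  m <- match(r1$transcript_id, r2$transcript_id)
  expect_equal(r1$p_type, r2$p_type[m])
  expect_equal(r1$p_interaction, r2$p_interaction[m])
  expect_equal(r1$base_mean, r2$base_mean[m])
})
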