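cm_fixture <- function() {
  m <- matrix(c(0, 0, 0,
                5, 0, 0,
                3, 4, 0,
                9, 9, 9), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:3)))
  storage.mode(m) <- "integer"
  m
}

test_that("presence filter keeps transcripts seen in >= 2 libraries", {
  keep <- presence_filter(cm_fixture())
  expect_setequal(keep, c("t3", "t4"))
})

test_that("FPKM matches its defining formula", {
  cm <- matrix(c(0L, 100L), 1, 2,
               dimnames = list("t1", c("s1", "s2")))
  f <- compute_fpkm(cm, c(t1 = 2000), totals = c(s1 = 1e6, s2 = 1e6))
  expect_equal(unname(f["t1", ]), c(0, 50))

  set.seed(7)
  cm2 <- matrix(rpois(20, 30), 4, 5,
                dimnames = list(paste0("t", 1:4), paste0("s", 1:5)))
  len <- setNames(sample(300:3000, 4), rownames(cm2))
  tot <- setNames(runif(5, 5e5, 5e6), colnames(cm2))
  f2 <- compute_fpkm(cm2, len, tot)
  for (i in 1:4) for (j in 1:5)
    expect_equal(f2[i, j],
                 cm2[i, j] / ((len[[i]] / 1000) * (tot[[j]] / 1e6)))
  expect_error(compute_fpkm(cm2, setNames(rep(0, 4), rownames(cm2)), tot),
               "positive")
})

test_that("abundance filter removes rows below tau everywhere, boundary kept", {
  f <- matrix(c(0.2, 0.2,
                0.3, 0.1,
                0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(abundance_filter(f, 0.3), "b")
})

test_that("structural filter needs >= 200 bp and >= 2 exons", {
  short2 <- transcript_model("t", "g", "chr1", "+", c(1, 150), c(99, 249))
  expect_equal(spliced_length(short2), 199L)
  expect_false(structural_filter(short2)$pass)
  expect_equal(structural_filter(short2)$reason, "short")

  long1 <- transcript_model("t", "g", "chr1", "+", 1, 5000)
  expect_false(structural_filter(long1)$pass)
  expect_equal(structural_filter(long1)$reason, "single_exon")

  ok <- transcript_model("t", "g", "chr1", "+", c(1, 201), c(125, 325))
  expect_true(structural_filter(ok)$pass)
})

test_that("longest ORF matches definition and brute-force enumeration", {
  expect_true(is.na(find_longest_orf("CCGGTTCCGGTT")))
  expect_equal(find_longest_orf(paste0("ATG", strrep("GCT", 119), "TAA")),
               120L)
  expect_error(find_longest_orf(""), "non-empty")

  set.seed(42)
  for (rep in 1:200) {
    s <- paste0(sample(c("A", "C", "G", "T"), sample(30:120, 1),
                       replace = TRUE), collapse = "")
    expect_identical(find_longest_orf(s), bf_longest_orf(s))
  }
})

test_that("six-frame scan also looks at the reverse complement", {
  fwd <- paste0("ATG", strrep("GCT", 30), "TAA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  expect_true(is.na(find_longest_orf(rc)))
  expect_equal(find_longest_orf(rc, both_strands = TRUE), 31L)
})

test_that("consensus coding call applies ORF, Pfam, then the vote", {
  ev <- data.frame(
    transcript_id = paste0("t", 1:6),
    orf_len_aa = c(130L, 50L, 50L, 50L, 119L, 50L),
    cpc2_label = c("noncoding", "noncoding", "coding", "coding",
                   "coding", "noncoding"),
    plek_score = c(-1, -1, -1, 0.6, 0.2, -0.2),
    cnit_score = c(-1, -0.5, 0.4, 0.9, 0.1, 0),
    pfam_min_evalue = c(NA, NA, NA, NA, NA, 0.5))
  cc <- consensus_coding_call(ev)
  expect_equal(cc$call,
               c("coding", "noncoding", "ambiguous", "coding", "coding",
                 "coding"))
  expect_equal(cc$basis[1], "orf_length")
  expect_equal(cc$basis[4], "vote_coding")
  expect_equal(cc$basis[6], "pfam_hit")
  # scores exactly zero satisfy neither side of the vote
  ev0 <- ev[2, ]; ev0$plek_score <- 0
  expect_equal(consensus_coding_call(ev0)$call, "ambiguous")
  # an insignificant Pfam hit falls through to the vote
  ev7 <- data.frame(transcript_id = "t7", orf_len_aa = 50L,
                    cpc2_label = "noncoding", plek_score = -1,
                    cnit_score = -1, pfam_min_evalue = 50)
  expect_equal(consensus_coding_call(ev7)$call, "noncoding")
  expect_error(consensus_coding_call(transform(ev, orf_len_aa = NA)),
               "missing")
})

small_bundle <- function(seed = 5, n = 150) {
  cfg <- sim_config(seed = seed, n_queries = n, dams_per_parity = c(2, 2, 2, 2))
  simulate_bundle(cfg)
}

test_that("discovery pipeline reproduces the planted truth end to end", {
  b <- small_bundle()
  v <- discovery_pipeline(b$queries, b$ref, b$counts, b$evidence,
                          totals = b$totals)
  m <- match(b$truth$transcript_id, v$transcript_id)
  expect_equal(v$class[m], b$truth$verdict)
  expect_equal(v$reason[m], b$truth$reason)
  expect_equal(v$lnc_subclass[m], b$truth$lnc_subclass)
  # verdict classes partition the input
  expect_equal(sort(v$transcript_id), sort(names(b$queries)))
  expect_true(all(v$class %in%
                    c("known", "novel_coding", "novel_lncRNA", "discarded")))
})

test_that("'=' transcripts bypass the novelty filters", {
  # an '='-matching single-exon query would fail structural_filter
  r <- transcript_model("r1", "g1", "chr1", "+", 1000, 1099)
  q <- transcript_model("q1", "g1", "chr1", "+", 1000, 1099)
  cm <- matrix(c(500L, 700L), 1, 2, dimnames = list("q1", c("s1", "s2")))
  ev <- data.frame(transcript_id = "q1", orf_len_aa = NA_integer_,
                   cpc2_label = "noncoding", plek_score = -1,
                   cnit_score = -1, pfam_min_evalue = NA_real_)
  v <- discovery_pipeline(list(q), reference_annotation(list(r)), cm, ev,
                          totals = c(s1 = 1e6, s2 = 1e6))
  expect_equal(v$class, "known")
})

test_that("single-library transcripts are discarded with reason presence", {
  q <- transcript_model("q1", "g1", "chr1", "+", c(1, 301), c(200, 500))
  cm <- matrix(c(50L, 0L, 0L), 1, 3,
               dimnames = list("q1", paste0("s", 1:3)))
  ev <- data.frame(transcript_id = "q1", orf_len_aa = 150L,
                   cpc2_label = "coding", plek_score = 1, cnit_score = 1,
                   pfam_min_evalue = NA_real_)
  v <- discovery_pipeline(list(q), reference_annotation(list()), cm, ev)
  expect_equal(v$class, "discarded")
  expect_equal(v$reason, "presence")
})

test_that("pipeline is monotone in thresholds and scale invariant", {
  b <- small_bundle(seed = 9)
  v0 <- discovery_pipeline(b$queries, b$ref, b$counts, b$evidence,
                           totals = b$totals)
  kept0 <- v0$transcript_id[v0$class != "discarded"]
  for (th in list(discovery_thresholds(min_fpkm = 1.0),
                  discovery_thresholds(min_length = 500))) {
    v1 <- discovery_pipeline(b$queries, b$ref, b$counts, b$evidence,
                             totals = b$totals, thresholds = th)
    kept1 <- v1$transcript_id[v1$class != "discarded"]
    expect_true(all(kept1 %in% kept0))
  }
  # scaling counts and totals together leaves the verdicts unchanged
  v2 <- discovery_pipeline(b$queries, b$ref, b$counts * 3L, b$evidence,
                           totals = b$totals * 3)
  expect_equal(v2$class, v0$class)
})

test_that("pipeline reports missing ids", {
  b <- small_bundle(seed = 3, n = 20)
  expect_error(
    discovery_pipeline(b$queries, b$ref,
                       b$counts[-1, , drop = FALSE], b$evidence,
                       totals = b$totals),
    "missing query ids")
})
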