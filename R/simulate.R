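`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator.  The defaults
#' emulate the study design the pipeline targets: 65 dams sampled at
#' farrowing (colostrum) and day 10 (mature milk) across parities 1-4
#' (16/25/15/9 dams), negative-binomial counts with dispersion 0.5 (the
#' maximum plausible value used in the power analysis), log-normal baseline
#' abundances wide enough to exercise the expression filters, and a class
#' -code mixture dominated by exact matches and intergenic novelties.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param n_queries Number of assembled query transcripts.
#' @param class_mixture Named proportions over codes
#'   `=`, `j`, `x`, `i`, `u`, `other` (must sum to 1).
#' @param p_structural_fail Probability that a novel-code query is planted
#'   with a failing structure (single exon or < 200 bp).
#' @param p_presence_fail,p_abundance_fail Probabilities that a query is
#'   planted to fail the presence (single library) or abundance
#'   (all-FPKM-below-threshold) filter; only applied to transcripts with no
#'   planted expression effect.
#' @param p_no_orf Probability that a structurally sound novel candidate
#'   carries no open reading frame.
#' @param coding_mixture Named proportions over the planted coding truth of
#'   novel candidates with an ORF: `coding`, `noncoding`, `ambiguous`.
#' @param p_orf_long Probability that a planted-coding transcript is decided
#'   by ORF length (>= 120 aa) rather than by Pfam/vote evidence.
#' @param orf_long_range,orf_short_range Amino-acid ranges for long and
#'   short planted ORFs.
#' @param evidence_agreement Probability `a` that the external evidence
#'   fields are jointly consistent with the planted truth.
#' @param dams_per_parity Dams in parities 1-4; each dam contributes one
#'   colostrum and one mature-milk sample.
#' @param dispersion NB dispersion `phi` (`Var = mu + phi mu^2`).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline expected counts.
#' @param lib_size_range Range of per-library total mapped fragments (the
#'   FPKM denominator).
#' @param de_frac Named fractions of retained transcripts planted with
#'   `type`, `parity`, and `interaction` effects.
#' @param lfc_type_range,lfc_parity_range,lfc_interaction_range Ranges of
#'   absolute planted log2 fold changes per effect.
#' @param enforce_filter_truth Deterministically nudge counts so the planted
#'   presence/abundance outcomes are guaranteed (default `TRUE`).
#' @param chrom_names Chromosome names over which gene windows are laid out.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_queries = 2000L,
                       class_mixture = c("=" = 0.30, j = 0.15, x = 0.10,
                                         i = 0.10, u = 0.25, other = 0.10),
                       p_structural_fail = 0.06,
                       p_presence_fail = 0.04,
                       p_abundance_fail = 0.05,
                       p_no_orf = 0.05,
                       coding_mixture = c(coding = 0.55, noncoding = 0.30,
                                          ambiguous = 0.15),
                       p_orf_long = 0.6,
                       orf_long_range = c(120L, 190L),
                       orf_short_range = c(20L, 100L),
                       evidence_agreement = 1,
                       dams_per_parity = c(16L, 25L, 15L, 9L),
                       dispersion = 0.5,
                       baseline_meanlog = log(150),
                       baseline_sdlog = 1.2,
                       lib_size_range = c(40e6, 55e6),
                       de_frac = c(type = 0.10, parity = 0.05,
                                   interaction = 0.025),
                       lfc_type_range = c(2, 4),
                       lfc_parity_range = c(1, 2.5),
                       lfc_interaction_range = c(2, 4),
                       enforce_filter_truth = TRUE,
                       chrom_names = c("chr1", "chr2", "chr3")) {
  stopifnot(abs(sum(class_mixture) - 1) < 1e-8,
            abs(sum(coding_mixture) - 1) < 1e-8,
            all(names(class_mixture) == c("=", "j", "x", "i", "u", "other")),
            evidence_agreement >= 0, evidence_agreement <= 1,
            length(dams_per_parity) == 4L, all(dams_per_parity > 0),
            dispersion >= 0, n_queries >= 1, sum(de_frac) <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# --- constructive gene-window geometry ------------------------------------
# Each query lives in its own 20-kb window holding one 4-exon reference
# transcript (300-bp exons, 1500-bp introns); the query's exon chain is
# derived from the reference so its class code is guaranteed by construction.
.win_width <- 20000L
.ref_exon_starts <- c(0L, 1800L, 3600L, 5400L)
.ref_exon_len <- 300L
.ref_offset <- 1000L

sim_ref_exons <- function(base) {
  s <- base + .ref_exon_starts
  data.frame(start = s, end = s + .ref_exon_len - 1L)
}

# query exon chains per planted code; `fail` = planted structural failure
sim_query_exons <- function(code, base, fail) {
  re <- sim_ref_exons(base)
  switch(code,
    "=" = re,
    "j" = if (fail)
      data.frame(start = c(re$end[1L] - 89L, re$start[2L]),
                 end = c(re$end[1L], re$start[2L] + 89L))
    else re[1:3, ],
    "x" = if (fail) re[2L, ] else re[2:3, ],
    "i" = if (fail)
      data.frame(start = re$end[2L] + 101L, end = re$end[2L] + 350L)
    else
      data.frame(start = re$end[2L] + c(101L, 651L),
                 end = re$end[2L] + c(450L, 1000L)),
    "u" = if (fail)
      data.frame(start = base + 11000L, end = base + 11999L)
    else
      data.frame(start = base + c(11000L, 11650L),
                 end = base + c(11449L, 12099L)),
    "other" = data.frame(start = re$start[1L] + 100L,
                         end = re$start[1L] + 399L))
}

#' Simulate a reference annotation and queries with planted class codes
#'
#' Lays one reference gene per 20-kb window and derives each query's exon
#' chain from its window's reference so that the planted class code is
#' guaranteed by construction: `=` copies the chain, `j` drops the terminal
#' exon (keeping shared introns), `x` mirrors two exons onto the opposite
#' strand, `i` drops a two-exon transcript into an intron, `u` sits in the
#' intergenic margin, and `other` is a same-strand single-exon fragment
#' overlapping an exon (a discard-path distractor).  A fraction of novel
#' -code queries is planted with failing structure (single exon / < 200 bp).
#'
#' The returned truth table also carries the planted coding status,
#' ORF length, evidence basis, filter outcomes, expression effects, and the
#' verdict the discovery cascade should reach.
#'
#' @param config A [sim_config()].
#' @return A list with `ref` ([reference_annotation()]), `queries` (named
#'   list of [transcript_model()]), and `truth` (data frame).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_queries
  codes <- names(config$class_mixture)
  n_per <- round(config$class_mixture * n)
  n_per[which.max(n_per)] <- n_per[which.max(n_per)] + (n - sum(n_per))
  code <- sample(rep(codes, times = n_per))

  novel <- code %in% c("j", "x", "i", "u")
  fail <- novel & stats::runif(n) < config$p_structural_fail

  n_chr <- length(config$chrom_names)
  chrom <- config$chrom_names[((seq_len(n) - 1L) %% n_chr) + 1L]
  win <- (seq_len(n) - 1L) %/% n_chr  # window index within chromosome
  base <- win * .win_width + .ref_offset
  strand <- sample(c("+", "-"), n, replace = TRUE)

  refs <- vector("list", n)
  queries <- vector("list", n)
  gene_id <- character(n)
  for (i in seq_len(n)) {
    re <- sim_ref_exons(base[i])
    refs[[i]] <- transcript_model(sprintf("REF.%d.1", i), sprintf("G%d", i),
                                  chrom[i], strand[i], re$start, re$end,
                                  biotype = "mRNA")
    qs <- strand[i]
    if (code[i] == "x") qs <- if (strand[i] == "+") "-" else "+"
    qe <- sim_query_exons(code[i], base[i], fail[i])
    gene_id[i] <- if (code[i] %in% c("=", "j")) sprintf("G%d", i)
      else sprintf("MSTRG.%d", i)
    queries[[i]] <- transcript_model(sprintf("Q.%d", i), gene_id[i],
                                     chrom[i], qs, qe$start, qe$end)
  }
  names(queries) <- vapply(queries, `[[`, character(1), "transcript_id")
  ref <- reference_annotation(refs)

  truth <- data.frame(
    transcript_id = names(queries),
    gene_id = gene_id,
    code = code,
    structural_ok = !fail & code != "other",
    length_bp = vapply(queries, spliced_length, integer(1)),
    row.names = NULL)

  # ---- planted coding truth -----------------------------------------------
  truth$orf_len <- NA_integer_
  truth$coding_status <- NA_character_
  truth$evidence_basis <- NA_character_
  cand <- which(novel & truth$structural_ok)
  no_orf <- cand[stats::runif(length(cand)) < config$p_no_orf]
  with_orf <- setdiff(cand, no_orf)
  status <- sample(names(config$coding_mixture), length(with_orf),
                   replace = TRUE, prob = config$coding_mixture)
  truth$coding_status[with_orf] <- status
  for (k in seq_along(with_orf)) {
    i <- with_orf[k]
    max_aa <- truth$length_bp[i] %/% 3L - 1L
    if (status[k] == "coding" && stats::runif(1) < config$p_orf_long) {
      rng <- config$orf_long_range
      truth$orf_len[i] <- min(sample(rng[1L]:rng[2L], 1L), max_aa)
      truth$evidence_basis[i] <- "orf_length"
    } else {
      rng <- config$orf_short_range
      truth$orf_len[i] <- min(sample(rng[1L]:rng[2L], 1L), max_aa)
      truth$evidence_basis[i] <-
        if (status[k] == "coding") {
          if (stats::runif(1) < 0.5) "pfam_hit" else "vote_coding"
        } else if (status[k] == "noncoding") "vote_noncoding" else "ambiguous"
    }
  }
  # known and discarded-path queries still get a plausible short ORF
  rest <- setdiff(seq_len(n), cand)
  max_aa <- pmax(truth$length_bp[rest] %/% 3L - 1L, 2L)
  rng <- config$orf_short_range
  truth$orf_len[rest] <- pmin(sample(rng[1L]:rng[2L], length(rest),
                                     replace = TRUE), max_aa)
  eq <- truth$code == "="
  truth$orf_len[eq] <- pmin(sample(150:350, sum(eq), replace = TRUE),
                            truth$length_bp[eq] %/% 3L - 1L)
  truth$orf_len[no_orf] <- NA_integer_

  # ---- planted filter outcomes -------------------------------------------
  u01 <- stats::runif(n)
  truth$presence_ok <- u01 >= config$p_presence_fail
  truth$abundance_ok <- !(u01 >= config$p_presence_fail &
                            u01 < config$p_presence_fail +
                              config$p_abundance_fail)

  # ---- constructive verdict ----------------------------------------------
  truth$lnc_subclass <- NA_character_
  truth$verdict <- "discarded"
  truth$reason <- NA_character_
  for (i in seq_len(n)) {
    if (!truth$presence_ok[i]) { truth$reason[i] <- "presence"; next }
    if (!truth$abundance_ok[i]) { truth$reason[i] <- "abundance"; next }
    if (truth$code[i] == "other") { truth$reason[i] <- "class_code"; next }
    if (truth$code[i] == "=") {
      truth$verdict[i] <- "known"; truth$reason[i] <- "class_code_equal"; next
    }
    if (!truth$structural_ok[i]) { truth$reason[i] <- "structural"; next }
    if (is.na(truth$orf_len[i])) { truth$reason[i] <- "no_orf"; next }
    st <- truth$coding_status[i]
    if (st == "coding") {
      truth$verdict[i] <- "novel_coding"
      truth$reason[i] <- truth$evidence_basis[i]
    } else if (st == "noncoding") {
      truth$verdict[i] <- "novel_lncRNA"
      truth$reason[i] <- "vote_noncoding"
      truth$lnc_subclass[i] <- classify_lnc_position(truth$code[i])
    } else {
      truth$reason[i] <- "ambiguous_coding"
    }
  }

  # ---- planted expression effects ----------------------------------------
  truth <- plant_de_truth(truth, config,
                          eligible = truth$verdict != "discarded")
  list(ref = ref, queries = queries, truth = truth)
}

# draw per-transcript expression effects; eligible rows only (others null)
plant_de_truth <- function(truth, config, eligible = rep(TRUE, nrow(truth))) {
  n <- nrow(truth)
  truth$de_class <- "null"
  truth$lfc_type <- 0; truth$lfc_parity <- 0; truth$lfc_interaction <- 0
  fr <- config$de_frac
  u <- stats::runif(n)
  cls <- rep("null", n)
  cls[u < fr["type"]] <- "type"
  cls[u >= fr["type"] & u < fr["type"] + fr["parity"]] <- "parity"
  cls[u >= fr["type"] + fr["parity"] & u < sum(fr)] <- "interaction"
  cls[!eligible] <- "null"
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  truth$de_class <- cls
  i <- cls == "type"
  truth$lfc_type[i] <- sgn[i] *
    stats::runif(sum(i), config$lfc_type_range[1L], config$lfc_type_range[2L])
  i <- cls == "parity"
  truth$lfc_parity[i] <- sgn[i] *
    stats::runif(sum(i), config$lfc_parity_range[1L],
                 config$lfc_parity_range[2L])
  i <- cls == "interaction"
  truth$lfc_interaction[i] <- sgn[i] *
    stats::runif(sum(i), config$lfc_interaction_range[1L],
                 config$lfc_interaction_range[2L])
  truth
}

#' Simulate a ground-truth table for expression-only experiments
#'
#' Convenience generator for studies of the differential-expression stages
#' alone: every transcript passes the discovery filters and only the
#' expression effects are planted.
#'
#' @param ids Transcript ids.
#' @param config A [sim_config()].
#' @return A truth data frame accepted by [simulate_counts()].
#' @export
simulate_de_truth <- function(ids, config) {
  set.seed(config$seed)
  truth <- data.frame(transcript_id = ids,
                      gene_id = paste0("G_", ids),
                      presence_ok = TRUE, abundance_ok = TRUE,
                      row.names = NULL)
  plant_de_truth(truth, config)
}

#' Simulate transcript sequences with planted open reading frames
#'
#' Builds each transcript's spliced sequence from an ATG-free, stop-free
#' background alphabet (`C`, `G`, `T`) and splices in one designed
#' ATG..stop ORF of the planted amino-acid length, so the longest ORF of the
#' sequence is exactly the planted one; transcripts planted without an ORF
#' contain none.  Every sequence is verified with [find_longest_orf()] at
#' generation time.
#'
#' @param queries Named list of `transcript_model` objects.
#' @param truth Truth table from [simulate_annotation()].
#' @param config A [sim_config()].
#' @return A named character vector of sequences.
#' @export
simulate_sequences <- function(queries, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  bg <- c("C", "G", "T")
  codons <- apply(expand.grid(bg, bg, bg), 1L, paste0, collapse = "")
  out <- stats::setNames(character(nrow(truth)), truth$transcript_id)
  for (i in seq_len(nrow(truth))) {
    id <- truth$transcript_id[i]
    n <- spliced_length(queries[[id]])
    aa <- truth$orf_len[i]
    if (is.na(aa)) {
      out[id] <- paste0(sample(bg, n, replace = TRUE), collapse = "")
    } else {
      orf_nt <- 3L * (aa + 1L)
      if (orf_nt > n)
        stop("planted ORF (", orf_nt, " nt) longer than transcript ", id)
      orf <- paste0("ATG",
                    paste0(sample(codons, aa - 1L, replace = TRUE),
                           collapse = ""),
                    sample(c("TAA", "TAG", "TGA"), 1L))
      pos <- sample.int(n - orf_nt + 1L, 1L)
      left <- paste0(sample(bg, pos - 1L, replace = TRUE), collapse = "")
      right <- paste0(sample(bg, n - orf_nt - (pos - 1L), replace = TRUE),
                      collapse = "")
      out[id] <- paste0(left, orf, right)
    }
    got <- find_longest_orf(out[id])
    if (!identical(got, as.integer(aa)) && !(is.na(aa) && is.na(got)))
      stop("planted ORF verification failed for ", id)
  }
  out
}

#' Simulate the external coding-evidence table
#'
#' With probability `a` (the evidence agreement) a transcript's CPC2, PLEK,
#' CNIT and Pfam fields are jointly consistent with its planted coding
#' truth; with probability `1 - a` exactly one of the three vote fields
#' (CPC2 label, PLEK sign, CNIT sign), chosen uniformly, is flipped.
#' Transcripts decided by ORF length or by a Pfam hit are immune to vote
#' flips by construction of the consensus rules.
#'
#' @param truth Truth table from [simulate_annotation()].
#' @param a Evidence agreement probability in `[0, 1]`; defaults to the
#'   config value.
#' @param config A [sim_config()].
#' @return An evidence data frame (columns as in [read_evidence_tsv()]).
#' @export
simulate_evidence <- function(truth, config, a = config$evidence_agreement) {
  stopifnot(a >= 0, a <= 1)
  set.seed(config$seed + 2000L)
  n <- nrow(truth)
  cpc2 <- character(n); plek <- numeric(n); cnit <- numeric(n)
  pfam <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    st <- truth$coding_status[i]
    basis <- truth$evidence_basis[i]
    if (!is.na(st) && st == "coding") {
      cpc2[i] <- "coding"
      plek[i] <- stats::runif(1, 0.5, 2)
      cnit[i] <- stats::runif(1, 0.5, 2)
      if (!is.na(basis) && basis == "pfam_hit")
        pfam[i] <- 10^-stats::runif(1, 0.3, 8)
      else if (!is.na(basis) && basis == "orf_length" && stats::runif(1) < 0.3)
        pfam[i] <- 10^-stats::runif(1, 0.3, 8)
    } else if (!is.na(st) && st == "ambiguous") {
      cpc2[i] <- "coding"
      plek[i] <- -stats::runif(1, 0.5, 2)
      cnit[i] <- stats::runif(1, 0.5, 2)
    } else {  # noncoding truth, plus known/discard-path rows
      cpc2[i] <- "noncoding"
      plek[i] <- -stats::runif(1, 0.5, 2)
      cnit[i] <- -stats::runif(1, 0.5, 2)
    }
  }
  flip <- stats::runif(n) >= a
  which_field <- sample(3L, n, replace = TRUE)
  for (i in which(flip)) {
    switch(which_field[i],
           cpc2[i] <- if (cpc2[i] == "coding") "noncoding" else "coding",
           plek[i] <- -plek[i],
           cnit[i] <- -cnit[i])
  }
  data.frame(transcript_id = truth$transcript_id,
             orf_len_aa = truth$orf_len,
             cpc2_label = cpc2, plek_score = plek, cnit_score = cnit,
             pfam_min_evalue = pfam, row.names = NULL)
}

# paired sample sheet implied by the config's dams-per-parity vector
sim_sample_sheet <- function(config) {
  dams <- sprintf("D%03d", seq_len(sum(config$dams_per_parity)))
  parity <- rep(1:4, times = config$dams_per_parity)
  data.frame(
    sample_id = c(paste0(dams, "_C"), paste0(dams, "_M")),
    dam_id = rep(dams, 2L),
    milk_type = rep(c("colostrum", "milk"), each = length(dams)),
    parity = rep(parity, 2L),
    row.names = NULL)
}

#' Simulate negative-binomial fragment counts under the study design
#'
#' Counts follow `NB(mean = L_s * q_t * 2^(x_s' beta_t), dispersion phi)`:
#' `L_s` is the relative library factor, `q_t` a log-normal baseline,
#' `x_s` the design row (milk type, parity, and their interaction), and
#' `beta_t` the planted log2 fold changes (the parity effect is applied to
#' parities 2-4; the interaction effect enters with alternating sign so it
#' is not absorbed by the main effect).  Paired samples share a `dam_id`.
#'
#' When `config$enforce_filter_truth` is set and spliced `lengths` are
#' supplied, counts are nudged deterministically so the planted presence
#' and abundance outcomes hold exactly: presence-fail rows keep one nonzero
#' library, abundance-fail rows are capped below the FPKM threshold, and
#' passing rows are floored to reach it in at least one library.
#'
#' @param config A [sim_config()].
#' @param truth Truth table ([simulate_annotation()] or
#'   [simulate_de_truth()]).
#' @param lengths Optional named spliced lengths (bp) for the FPKM
#'   guarantees.
#' @param min_fpkm Abundance threshold used for the guarantees (default 0.3).
#' @return A list with `counts` (matrix), `sheet` (sample sheet), and
#'   `totals` (named per-library total mapped fragments).
#' @export
simulate_counts <- function(config, truth, lengths = NULL, min_fpkm = 0.3) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3000L)
  sheet <- sim_sample_sheet(config)
  ns <- nrow(sheet)
  nt <- nrow(truth)
  totals <- stats::setNames(
    stats::runif(ns, config$lib_size_range[1L], config$lib_size_range[2L]),
    sheet$sample_id)
  L <- totals / mean(totals)

  type <- as.numeric(sheet$milk_type == "milk")
  par2 <- as.numeric(sheet$parity >= 2)          # parity effect: P2-P4
  int_sign <- c(0, 1, -1, 1)[sheet$parity] * type  # alternating interaction
  q <- stats::rlnorm(nt, config$baseline_meanlog, config$baseline_sdlog)
  log2mu <- outer(truth$lfc_type, type) +
    outer(truth$lfc_parity, par2) +
    outer(truth$lfc_interaction, int_sign)
  mu <- sweep(2^log2mu * q, 2L, L, `*`)
  counts <- matrix(
    if (config$dispersion < 1e-12) stats::rpois(nt * ns, mu)
    else stats::rnbinom(nt * ns, mu = mu, size = 1 / config$dispersion),
    nrow = nt,
    dimnames = list(truth$transcript_id, sheet$sample_id))

  if (isTRUE(config$enforce_filter_truth)) {
    pres_fail <- which(!truth$presence_ok)
    for (i in pres_fail) {
      keep <- sample.int(ns, 1L)
      counts[i, -keep] <- 0L
      counts[i, keep] <- max(counts[i, keep], 1L)
    }
    if (!is.null(lengths)) {
      len_kb <- as.numeric(lengths[truth$transcript_id]) / 1000
      need <- ceiling(min_fpkm * len_kb %o% (totals / 1e6))  # count at tau
      ab_fail <- which(truth$presence_ok & !truth$abundance_ok)
      for (i in ab_fail) {
        cap <- pmax(need[i, ] - 1L, 0L)
        counts[i, ] <- pmin(counts[i, ], cap)
        nz <- sum(counts[i, ] > 0)
        if (nz < 2L) {
          ok <- which(cap >= 1L)
          pick <- sample(ok, min(2L, length(ok)))
          counts[i, pick] <- pmax(counts[i, pick], 1L)
        }
      }
      ab_pass <- which(truth$presence_ok & truth$abundance_ok)
      for (i in ab_pass) {
        fpkm <- counts[i, ] / (len_kb[i] * totals / 1e6)
        if (max(fpkm) < min_fpkm) {
          j <- which.max(fpkm)
          counts[i, j] <- need[i, j]
        }
      }
    }
    pres_pass <- which(truth$presence_ok)
    few <- pres_pass[rowSums(counts[pres_pass, , drop = FALSE] > 0) < 2L]
    for (i in few) {
      pick <- sample.int(ns, 2L)
      counts[i, pick] <- pmax(counts[i, pick], 1L)
    }
  }
  storage.mode(counts) <- "integer"
  list(counts = counts, sheet = sheet, totals = totals)
}

#' Simulate a complete fixture bundle in memory
#'
#' Runs [simulate_annotation()], [simulate_sequences()],
#' [simulate_evidence()] and [simulate_counts()] in order under the
#' config's seed.
#'
#' @param config A [sim_config()].
#' @return A list: `ref`, `queries`, `truth`, `sequences`, `evidence`,
#'   `counts`, `sheet`, `totals`, `gene_map`, `lengths`, `config`.
#' @export
simulate_bundle <- function(config) {
  ann <- simulate_annotation(config)
  seqs <- simulate_sequences(ann$queries, ann$truth, config)
  ev <- simulate_evidence(ann$truth, config)
  lengths <- vapply(ann$queries, spliced_length, integer(1))
  cnt <- simulate_counts(config, ann$truth, lengths = lengths)
  list(ref = ann$ref, queries = ann$queries, truth = ann$truth,
       sequences = seqs, evidence = ev, counts = cnt$counts,
       sheet = cnt$sheet, totals = cnt$totals,
       gene_map = ann$truth[, c("transcript_id", "gene_id")],
       lengths = lengths, config = config)
}

#' Write a fixture bundle to disk
#'
#' Emits reference and query GTFs, a FASTA of transcript sequences, count,
#' evidence, sample-sheet, library-total, gene-map and truth TSVs, plus a
#' YAML echo of the configuration.  All files round-trip losslessly through
#' the package readers.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `paths` and the in-memory `bundle`.
#' @export
write_fixture_bundle <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  b <- simulate_bundle(config)
  p <- list(
    reference_gtf = file.path(outdir, "reference.gtf"),
    queries_gtf = file.path(outdir, "queries.gtf"),
    fasta = file.path(outdir, "transcripts.fasta"),
    counts = file.path(outdir, "counts.tsv"),
    evidence = file.path(outdir, "evidence.tsv"),
    samples = file.path(outdir, "samples.tsv"),
    totals = file.path(outdir, "totals.tsv"),
    gene_map = file.path(outdir, "gene_map.tsv"),
    truth = file.path(outdir, "truth.tsv"),
    config = file.path(outdir, "config.yaml"))
  write_transcripts_gtf(b$ref$transcripts, p$reference_gtf)
  write_transcripts_gtf(b$queries, p$queries_gtf)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(b$sequences), p$fasta)
  write_counts_tsv(b$counts, p$counts)
  write_tsv(b$evidence, p$evidence)
  write_tsv(b$sheet, p$samples)
  write_tsv(data.frame(sample_id = names(b$totals),
                       total_fragments = unname(b$totals)), p$totals)
  write_tsv(b$gene_map, p$gene_map)
  write_tsv(b$truth, p$truth)
  cfg <- b$config; class(cfg) <- NULL
  yaml::write_yaml(cfg, p$config)
  invisible(list(paths = p, bundle = b))
}
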