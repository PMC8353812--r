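#' Presence filter: expressed in at least two libraries
#'
#' A transcript counts as "identified" in a library when its fragment count
#' is positive there.  Transcripts identified in at most one library are
#' treated as assembly noise and removed.
#'
#' @param cm Transcript-by-sample count matrix.
#' @return Character vector of transcript ids kept.
#' @export
presence_filter <- function(cm) {
  validate_count_matrix(cm)
  rownames(cm)[rowSums(cm > 0) >= 2L]
}

#' FPKM from fragment counts
#'
#' Fragments per kilobase of exon per million mapped fragments:
#' `count / ((length/1000) * (total/1e6))`.  Totals default to the column
#' sums of the supplied matrix; pass per-library total mapped fragments when
#' the matrix covers only a subset of the transcriptome.
#'
#' @param cm Count matrix.
#' @param lengths Named vector of spliced transcript lengths (bp); must cover
#'   all rows and be positive.
#' @param totals Named vector of per-sample total fragments (default column
#'   sums); must be positive.
#' @return Numeric matrix of FPKM values, same dimnames as `cm`.
#' @export
compute_fpkm <- function(cm, lengths, totals = colSums(cm)) {
  validate_count_matrix(cm)
  if (!all(rownames(cm) %in% names(lengths)))
    stop("lengths missing for: ",
         paste(utils::head(setdiff(rownames(cm), names(lengths))), collapse = ", "))
  len <- as.numeric(lengths[rownames(cm)])
  if (any(!is.finite(len)) || any(len <= 0))
    stop("all spliced lengths must be positive")
  if (is.null(names(totals))) names(totals) <- colnames(cm)
  tot <- as.numeric(totals[colnames(cm)])
  if (anyNA(tot) || any(tot <= 0)) stop("all library totals must be positive")
  fpkm <- cm / (len / 1000)
  fpkm <- sweep(fpkm, 2L, tot / 1e6, "/")
  fpkm
}

#' Abundance filter on FPKM
#'
#' Removes transcripts whose FPKM is below `tau` in every library; a
#' transcript reaching `tau` in at least one library is kept (the boundary
#' value itself passes).
#'
#' @param fpkm FPKM matrix.
#' @param tau Threshold (default 0.3).
#' @return Character vector of transcript ids kept.
#' @export
abundance_filter <- function(fpkm, tau = 0.3) {
  mx <- apply(fpkm, 1L, max)
  rownames(fpkm)[mx >= tau]
}

#' Structural filter for novel-transcript candidates
#'
#' A candidate passes when its spliced (exonic) length is at least
#' `min_length` base pairs and it has at least two exons.
#'
#' @param t A `transcript_model`.
#' @param min_length Minimum spliced length in bp (default 200).
#' @return A list with `pass` (logical) and `reason` (`NA` when passing,
#'   otherwise `"short"` or `"single_exon"`; single-exon is reported first).
#' @export
structural_filter <- function(t, min_length = 200) {
  stopifnot(inherits(t, "transcript_model"))
  if (nrow(t$exons) < 2L) return(list(pass = FALSE, reason = "single_exon"))
  if (spliced_length(t) < min_length)
    return(list(pass = FALSE, reason = "short"))
  list(pass = TRUE, reason = NA_character_)
}

#' Longest open reading frame in a transcript sequence
#'
#' Scans the three forward reading frames (the library preparation is
#' stranded, so the supplied sequence is the transcript strand) for the
#' longest ATG-to-stop open reading frame.  Length is reported in amino
#' acids, counting codons from the ATG inclusive to the stop exclusive.
#' Set `both_strands = TRUE` to also scan the reverse complement for
#' unstranded inputs.
#'
#' @param seq A single nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param both_strands Also scan the reverse complement (default `FALSE`).
#' @return Integer ORF length in amino acids, or `NA_integer_` when no
#'   complete ORF exists.
#' @export
#' @examples
#' find_longest_orf(paste0("ATG", strrep("GCT", 119), "TAA"))  # 120
find_longest_orf <- function(seq, both_strands = FALSE) {
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    stop("seq must be a single non-empty nucleotide string")
  s <- toupper(seq)
  best <- orf_scan_forward(s)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    best <- max(best, orf_scan_forward(rc))
  }
  if (!is.finite(best)) NA_integer_ else as.integer(best)
}

orf_scan_forward <- function(s) {
  n <- nchar(s)
  best <- -Inf
  for (f in 0:2) {
    m <- (n - f) %/% 3L
    if (m < 2L) next
    pos <- f + seq(1L, by = 3L, length.out = m)
    codons <- substring(s, pos, pos + 2L)
    starts <- which(codons == "ATG")
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (!length(starts) || !length(stops)) next
    idx <- findInterval(starts, stops) + 1L  # first stop strictly after start
    ok <- idx <= length(stops)
    if (!any(ok)) next
    best <- max(best, max(stops[idx[ok]] - starts[ok]))
  }
  best
}

#' Consensus protein-coding classification
#'
#' Combines ORF length with external coding-potential evidence:
#'
#' 1. ORF length >= `min_orf_aa` amino acids: protein-coding.
#' 2. Otherwise a significant Pfam domain hit (E-value < `pfam_evalue`):
#'    protein-coding.
#' 3. Otherwise, with no significant Pfam hit: CPC2 "coding" with PLEK and
#'    CNIT scores both positive is coding; CPC2 "noncoding" with both scores
#'    negative is noncoding; everything else (including scores exactly zero)
#'    is ambiguous and will be discarded downstream.
#'
#' All transcripts reaching this call already have a predicted ORF; a missing
#' `orf_len_aa` is an error.
#'
#' @param ev Data frame with columns `transcript_id`, `orf_len_aa`,
#'   `cpc2_label`, `plek_score`, `cnit_score`, `pfam_min_evalue` (`NA` = no
#'   Pfam hit).
#' @param min_orf_aa ORF threshold in amino acids (default 120).
#' @param pfam_evalue Pfam significance threshold (default 10.0).
#' @return A data frame with `transcript_id`, `call` in
#'   `coding`/`noncoding`/`ambiguous`, and `basis`, the decisive rule
#'   (`orf_length`, `pfam_hit`, `vote_coding`, `vote_noncoding`,
#'   `ambiguous`).
#' @export
consensus_coding_call <- function(ev, min_orf_aa = 120, pfam_evalue = 10.0) {
  need <- c("transcript_id", "orf_len_aa", "cpc2_label", "plek_score",
            "cnit_score", "pfam_min_evalue")
  if (!all(need %in% names(ev)))
    stop("evidence needs columns: ", paste(need, collapse = ", "))
  if (anyNA(ev$orf_len_aa))
    stop("orf_len_aa missing for: ",
         paste(utils::head(ev$transcript_id[is.na(ev$orf_len_aa)]), collapse = ", "))
  if (anyNA(ev$cpc2_label) || anyNA(ev$plek_score) || anyNA(ev$cnit_score))
    stop("cpc2_label, plek_score and cnit_score must be complete")
  if (!all(ev$cpc2_label %in% c("coding", "noncoding")))
    stop("cpc2_label must be 'coding' or 'noncoding'")

  n <- nrow(ev)
  call <- rep("ambiguous", n)
  basis <- rep("ambiguous", n)

  pfam_sig <- !is.na(ev$pfam_min_evalue) & ev$pfam_min_evalue < pfam_evalue
  vote_cod <- !pfam_sig & ev$cpc2_label == "coding" &
    ev$plek_score > 0 & ev$cnit_score > 0
  vote_non <- !pfam_sig & ev$cpc2_label == "noncoding" &
    ev$plek_score < 0 & ev$cnit_score < 0
  orf_long <- ev$orf_len_aa >= min_orf_aa

  call[vote_non] <- "noncoding"; basis[vote_non] <- "vote_noncoding"
  call[vote_cod] <- "coding"; basis[vote_cod] <- "vote_coding"
  call[pfam_sig] <- "coding"; basis[pfam_sig] <- "pfam_hit"
  call[orf_long] <- "coding"; basis[orf_long] <- "orf_length"

  data.frame(transcript_id = ev$transcript_id, call = call, basis = basis,
             row.names = NULL)
}

#' Default thresholds for the discovery cascade
#'
#' @param min_fpkm Abundance threshold in FPKM (default 0.3).
#' @param min_length Minimum spliced length in bp (default 200).
#' @param min_orf_aa Protein-coding ORF threshold in amino acids (default 120).
#' @param pfam_evalue Pfam E-value significance threshold (default 10.0).
#' @return A named list of thresholds.
#' @export
discovery_thresholds <- function(min_fpkm = 0.3, min_length = 200,
                                 min_orf_aa = 120, pfam_evalue = 10.0) {
  stopifnot(min_fpkm > 0, min_length > 0, min_orf_aa > 0, pfam_evalue > 0)
  list(min_fpkm = min_fpkm, min_length = min_length,
       min_orf_aa = min_orf_aa, pfam_evalue = pfam_evalue)
}

#' Run the staged novel-transcript discovery cascade
#'
#' Applies, in order: the presence filter (>= 2 libraries), the abundance
#' filter (FPKM), class-code assignment (codes outside `=`, `j`, `x`, `i`,
#' `u` are discarded; `=` transcripts are known and bypass the novelty
#' filters), the structural filter (length and exon count), the ORF
#' requirement, and the consensus coding-potential call.  Noncoding
#' survivors are assigned their positional lncRNA subclass.
#'
#' @param queries Named list of `transcript_model` objects (the assembled
#'   transcripts under scrutiny).
#' @param ref A [reference_annotation()].
#' @param cm Count matrix covering every query id.
#' @param evidence Coding-evidence data frame (see [read_evidence_tsv()]);
#'   must cover every candidate reaching the coding step, with `NA`
#'   `orf_len_aa` meaning no predicted ORF.
#' @param lengths Named spliced lengths in bp; default derived from `queries`.
#' @param totals Per-library total mapped fragments for FPKM; default column
#'   sums of `cm`.
#' @param thresholds See [discovery_thresholds()].
#' @return A data frame (one row per query) with columns `transcript_id`,
#'   `class` (`known`, `novel_coding`, `novel_lncRNA`, `discarded`), `code`,
#'   `matched_ref_id`, `lnc_subclass`, `reason`.  The funnel of per-stage
#'   survivor counts is attached as attribute `"funnel"`.
#' @export
discovery_pipeline <- function(queries, ref, cm, evidence,
                               lengths = NULL, totals = colSums(cm),
                               thresholds = discovery_thresholds()) {
  stopifnot(is.list(queries), inherits(ref, "reference_annotation"))
  ids <- vapply(queries, function(t) t$transcript_id, character(1))
  names(queries) <- ids
  missing_counts <- setdiff(ids, rownames(cm))
  if (length(missing_counts))
    stop("count matrix missing query ids: ",
         paste(utils::head(missing_counts, 10), collapse = ", "))
  if (is.null(lengths))
    lengths <- vapply(queries, spliced_length, integer(1))

  verdict <- data.frame(
    transcript_id = ids,
    class = rep("discarded", length(ids)),
    code = NA_character_, matched_ref_id = NA_character_,
    lnc_subclass = NA_character_, reason = NA_character_,
    row.names = ids)

  # stage 1: presence
  kept1 <- intersect(presence_filter(cm[ids, , drop = FALSE]), ids)
  verdict[setdiff(ids, kept1), "reason"] <- "presence"

  # stage 2: abundance
  if (length(kept1)) {
    fpkm <- compute_fpkm(cm[kept1, , drop = FALSE], lengths, totals)
    kept2 <- abundance_filter(fpkm, thresholds$min_fpkm)
  } else kept2 <- character(0)
  verdict[setdiff(kept1, kept2), "reason"] <- "abundance"

  # stage 3: class codes
  if (length(kept2)) {
    codes <- assign_class_codes(queries[kept2], ref)
    verdict[codes$query_id, "code"] <- codes$code
    verdict[codes$query_id, "matched_ref_id"] <- codes$matched_ref_id
    known <- codes$query_id[codes$code == "="]
    novel <- codes$query_id[codes$code %in% c("j", "x", "i", "u")]
    bad_code <- setdiff(kept2, c(known, novel))
    verdict[bad_code, "reason"] <- "class_code"
    verdict[known, "class"] <- "known"
    verdict[known, "reason"] <- "class_code_equal"
  } else {
    known <- novel <- character(0)
  }

  # stage 4: structural (novel candidates only)
  if (length(novel)) {
    st <- lapply(queries[novel], structural_filter,
                 min_length = thresholds$min_length)
    pass <- vapply(st, `[[`, TRUE, "pass")
    fail <- novel[!pass]
    verdict[fail, "reason"] <- "structural"
    kept4 <- novel[pass]
  } else kept4 <- character(0)

  # stage 5: ORF presence, stage 6: consensus coding call
  if (length(kept4)) {
    ev <- evidence[match(kept4, evidence$transcript_id), , drop = FALSE]
    if (anyNA(ev$transcript_id))
      stop("evidence table missing ids: ",
           paste(utils::head(kept4[is.na(ev$transcript_id)], 10), collapse = ", "))
    no_orf <- kept4[is.na(ev$orf_len_aa)]
    verdict[no_orf, "reason"] <- "no_orf"
    kept5 <- setdiff(kept4, no_orf)
    if (length(kept5)) {
      ev5 <- ev[match(kept5, ev$transcript_id), , drop = FALSE]
      cc <- consensus_coding_call(ev5, min_orf_aa = thresholds$min_orf_aa,
                                  pfam_evalue = thresholds$pfam_evalue)
      cod <- kept5[cc$call == "coding"]
      non <- kept5[cc$call == "noncoding"]
      amb <- kept5[cc$call == "ambiguous"]
      verdict[cod, "class"] <- "novel_coding"
      verdict[cod, "reason"] <- cc$basis[cc$call == "coding"]
      verdict[non, "class"] <- "novel_lncRNA"
      verdict[non, "reason"] <- "vote_noncoding"
      verdict[non, "lnc_subclass"] <- classify_lnc_position(verdict[non, "code"])
      verdict[amb, "reason"] <- "ambiguous_coding"
    }
  } else kept5 <- character(0)

  funnel <- c(input = length(ids), presence = length(kept1),
              abundance = length(kept2),
              class_code = length(known) + length(novel),
              known = length(known), novel_candidates = length(novel),
              structural = length(kept4), with_orf = length(kept5),
              retained = sum(verdict$class != "discarded"))
  attr(verdict, "funnel") <- funnel
  rownames(verdict) <- NULL
  verdict
}
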