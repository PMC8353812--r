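#' Construct a transcript model
#'
#' A transcript model is the exon-chain representation of one transcript on a
#' genome: an ordered set of disjoint exons sharing a chromosome and strand.
#' It is the substrate for class-code assignment and for the positional
#' classification of long non-coding RNAs.
#'
#' Coordinates are 1-based and inclusive at both ends (GTF convention).
#' Exons are sorted by start position on construction, so the exon order in
#' the input does not matter.
#'
#' @param transcript_id Character scalar, unique transcript identifier.
#' @param gene_id Character scalar, identifier of the parent gene locus.
#' @param chrom Character scalar, chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of equal length (>= 1) giving
#'   exon boundaries; exons must be pairwise disjoint with a gap of at least
#'   one base between consecutive exons.
#' @param biotype One of `"mRNA"`, `"ncRNA"`, `"pseudogene"`, `"miscRNA"`,
#'   `"unknown"`.
#' @return An object of class `transcript_model`.
#' @export
#' @examples
#' tx <- transcript_model("t1", "g1", "chr1", "+", c(1, 201), c(100, 300))
#' spliced_length(tx)
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exon_starts, exon_ends, biotype = "unknown") {
  if (length(transcript_id) != 1L || is.na(transcript_id))
    stop("transcript_id must be a single non-missing value")
  if (length(strand) != 1L || !strand %in% c("+", "-"))
    stop("strand must be '+' or '-'")
  if (length(exon_starts) != length(exon_ends) || length(exon_starts) < 1L)
    stop("need >= 1 exon with matching starts and ends")
  o <- order(exon_starts)
  s <- as.integer(exon_starts[o])
  e <- as.integer(exon_ends[o])
  if (anyNA(s) || anyNA(e)) stop("exon coordinates must be non-missing")
  if (any(s < 1L)) stop("exon starts must be >= 1")
  if (any(e < s)) stop("each exon must satisfy start <= end")
  n <- length(s)
  if (n > 1L && any(s[-1L] - e[-n] < 2L))
    stop("exons must be pairwise disjoint with gap >= 1")
  biotype <- match.arg(biotype,
                       c("mRNA", "ncRNA", "pseudogene", "miscRNA", "unknown"))
  structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         chrom = as.character(chrom),
         strand = strand,
         exons = data.frame(start = s, end = e),
         biotype = biotype),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%d-%d(%s), %d exon(s), %d bp spliced\n",
              x$transcript_id, x$gene_id, x$chrom,
              x$exons$start[1L], x$exons$end[nrow(x$exons)],
              x$strand, nrow(x$exons), spliced_length(x)))
  invisible(x)
}

#' Spliced (exonic) length of a transcript
#'
#' @param t A `transcript_model`.
#' @return Integer, the sum of exon lengths in base pairs.
#' @export
spliced_length <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  sum(t$exons$end - t$exons$start + 1L)
}

tx_span <- function(t) {
  c(start = t$exons$start[1L], end = t$exons$end[nrow(t$exons)])
}

#' Intron chain of a transcript
#'
#' Returns the maximal gaps between consecutive exons, i.e. the introns, as a
#' data frame of 1-based inclusive intervals.  Single-exon transcripts have an
#' empty chain.
#'
#' @param t A `transcript_model`.
#' @return A data frame with columns `start`, `end` (possibly zero rows).
#' @export
#' @examples
#' tx <- transcript_model("t1", "g1", "chr1", "+", c(1, 201), c(100, 300))
#' intron_chain(tx)  # 101-200
intron_chain <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  ex <- t$exons
  n <- nrow(ex)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-n] + 1L, end = ex$start[-1L] - 1L)
}

#' Build a reference annotation with an overlap index
#'
#' Bundles a collection of [transcript_model()] objects with a gene index and
#' a per-chromosome interval index (a [GenomicRanges::GRanges] of transcript
#' spans) so that overlap queries are fast.
#'
#' @param transcripts A list of `transcript_model` objects (possibly empty).
#' @return An object of class `reference_annotation`.
#' @export
reference_annotation <- function(transcripts) {
  stopifnot(is.list(transcripts))
  if (length(transcripts) &&
      !all(vapply(transcripts, inherits, TRUE, "transcript_model")))
    stop("all elements must be transcript_model objects")
  ids <- vapply(transcripts, function(t) t$transcript_id, character(1))
  if (anyDuplicated(ids)) stop("transcript ids must be unique")
  names(transcripts) <- ids
  if (length(transcripts)) {
    spans <- do.call(rbind, lapply(transcripts, tx_span))
    gr <- GenomicRanges::GRanges(
      seqnames = vapply(transcripts, function(t) t$chrom, character(1)),
      ranges = IRanges::IRanges(start = spans[, "start"], end = spans[, "end"]),
      strand = vapply(transcripts, function(t) t$strand, character(1)))
    names(gr) <- ids
  } else {
    gr <- GenomicRanges::GRanges()
  }
  gene_ids <- vapply(transcripts, function(t) t$gene_id, character(1))
  structure(
    list(transcripts = transcripts,
         spans = gr,
         genes = split(ids, gene_ids)),
    class = "reference_annotation")
}

#' @export
print.reference_annotation <- function(x, ...) {
  cat(sprintf("<reference_annotation> %d transcript(s), %d gene(s)\n",
              length(x$transcripts), length(x$genes)))
  invisible(x)
}

# ids of reference transcripts whose genomic span intersects [start, end] on
# chrom (any strand)
overlapping_ref_ids <- function(ref, chrom, start, end) {
  if (!length(ref$transcripts)) return(character(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, ref$spans, ignore.strand = TRUE))
  names(ref$spans)[S4Vectors::subjectHits(hits)]
}

same_intron_chain <- function(a, b) {
  nrow(a) == nrow(b) && all(a$start == b$start) && all(a$end == b$end)
}

intervals_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

any_exon_overlap <- function(q, r) {
  for (i in seq_len(nrow(q$exons))) {
    if (any(intervals_overlap(q$exons$start[i], q$exons$end[i],
                              r$exons$start, r$exons$end)))
      return(TRUE)
  }
  FALSE
}

#' Assign a gffcompare-style class code to an assembled transcript
#'
#' Compares a query transcript against a reference annotation and assigns one
#' of the five codes used for milk-transcriptome discovery plus a catch-all:
#'
#' * `=`: exact intron-chain match with a same-strand reference transcript
#'   (single-exon queries match a single-exon, same-strand reference with
#'   overlapping exons);
#' * `j`: multi-exon query sharing at least one identical intron (both
#'   boundaries) with a same-strand reference transcript;
#' * `x`: at least one query exon overlaps an exon of an opposite-strand
#'   reference transcript;
#' * `i`: query fully contained within a single intron of a same-strand
#'   reference transcript;
#' * `u`: the query span overlaps no reference transcript span (intergenic);
#' * `other`: overlaps the annotation but matches none of the above.
#'
#' Rules are applied in the fixed priority order `=` > `j` > `x` > `i` > `u`,
#' so every query receives exactly one code.  When several reference
#' transcripts satisfy the decisive rule, for `j` the one sharing the most
#' introns is reported (ties broken by lexicographic id); otherwise the
#' lexicographically smallest id is reported.
#'
#' @param q A `transcript_model` query.
#' @param ref A [reference_annotation()]; may be empty (every query is `u`).
#' @return A list with `query_id`, `code`, and `matched_ref_id`
#'   (`NA_character_` for codes `u` and `other`).
#' @export
assign_class_code <- function(q, ref) {
  stopifnot(inherits(q, "transcript_model"), inherits(ref, "reference_annotation"))
  sp <- tx_span(q)
  cand <- overlapping_ref_ids(ref, q$chrom, sp["start"], sp["end"])
  if (!length(cand))
    return(list(query_id = q$transcript_id, code = "u",
                matched_ref_id = NA_character_))
  cand <- sort(cand)
  refs <- ref$transcripts[cand]
  same <- refs[vapply(refs, function(r) r$strand == q$strand, TRUE)]
  opp <- refs[vapply(refs, function(r) r$strand != q$strand, TRUE)]
  qi <- intron_chain(q)

  # '=': identical intron chain, same strand; empty chains need exon overlap
  for (r in same) {
    ri <- intron_chain(r)
    if (same_intron_chain(qi, ri) &&
        (nrow(qi) > 0L || any_exon_overlap(q, r)))
      return(list(query_id = q$transcript_id, code = "=",
                  matched_ref_id = r$transcript_id))
  }

  # 'j': multi-exon query sharing >= 1 identical intron with same-strand ref
  if (nrow(qi) > 0L && length(same)) {
    shared <- vapply(same, function(r) {
      ri <- intron_chain(r)
      if (!nrow(ri)) return(0L)
      m <- match(qi$start, ri$start)
      sum(!is.na(m) & qi$end == ri$end[m])
    }, integer(1))
    if (any(shared > 0L)) {
      best <- names(same)[which.max(shared)]  # ids sorted; first max wins ties
      return(list(query_id = q$transcript_id, code = "j",
                  matched_ref_id = best))
    }
  }

  # 'x': exonic overlap with an opposite-strand reference transcript
  for (r in opp) {
    if (any_exon_overlap(q, r))
      return(list(query_id = q$transcript_id, code = "x",
                  matched_ref_id = r$transcript_id))
  }

  # 'i': fully contained within one intron of a same-strand reference
  for (r in same) {
    ri <- intron_chain(r)
    if (nrow(ri) &&
        any(ri$start <= sp["start"] & sp["end"] <= ri$end))
      return(list(query_id = q$transcript_id, code = "i",
                  matched_ref_id = r$transcript_id))
  }

  list(query_id = q$transcript_id, code = "other",
       matched_ref_id = NA_character_)
}

#' Assign class codes to many queries
#'
#' Vectorized driver over [assign_class_code()].
#'
#' @param queries A list of `transcript_model` objects.
#' @param ref A [reference_annotation()].
#' @return A data frame with columns `query_id`, `code`, `matched_ref_id`.
#' @export
assign_class_codes <- function(queries, ref) {
  res <- lapply(queries, assign_class_code, ref = ref)
  data.frame(
    query_id = vapply(res, `[[`, character(1), "query_id"),
    code = vapply(res, `[[`, character(1), "code"),
    matched_ref_id = vapply(res, `[[`, character(1), "matched_ref_id"),
    row.names = NULL)
}

#' Positional subclass of a novel long non-coding RNA
#'
#' Maps the class code of a transcript already established as non-coding to
#' its positional lncRNA subclass: intergenic (`u` -> `lincRNA`), intronic
#' (`i` -> `ilncRNA`), antisense (`x` -> `lncNAT`), and novel isoform
#' (`j` -> `isolncRNA`).
#'
#' @param code Character vector of class codes, each in `u`, `i`, `x`, `j`.
#' @return Character vector of subclasses.
#' @export
classify_lnc_position <- function(code) {
  map <- c(u = "lincRNA", i = "ilncRNA", x = "lncNAT", j = "isolncRNA")
  bad <- !code %in% names(map)
  if (any(bad))
    stop("class code(s) not valid for lncRNA subclassification: ",
         paste(unique(code[bad]), collapse = ", "))
  unname(map[code])
}
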