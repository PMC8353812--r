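#' Read transcript models from a GTF file
#'
#' Imports exon features via [rtracklayer::import()] and assembles one
#' [transcript_model()] per `transcript_id`.  The `gene_id` and
#' `transcript_id` attributes are mandatory; `gene_biotype` is honoured when
#' present.
#'
#' @param path Path to a GTF file.
#' @return A named list of `transcript_model` objects (names = transcript ids).
#' @export
read_transcripts_gtf <- function(path) {
  if (!file.exists(path)) stop("no such GTF file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(grep("^[^#[:space:]]", lines))) return(list())
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) return(list())
  if (is.null(gr$transcript_id) || is.null(gr$gene_id))
    stop("GTF must carry gene_id and transcript_id attributes: ", path)
  biot <- if (!is.null(gr$gene_biotype)) gr$gene_biotype else
    rep(NA_character_, length(gr))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    biotype = biot)
  out <- lapply(split(df, df$transcript_id), function(d) {
    bt <- d$biotype[1L]
    if (is.na(bt) || !bt %in% c("mRNA", "ncRNA", "pseudogene", "miscRNA"))
      bt <- "unknown"
    transcript_model(d$transcript_id[1L], d$gene_id[1L], d$chrom[1L],
                     d$strand[1L], d$start, d$end, biotype = bt)
  })
  out[order(names(out))]
}

#' Write transcript models to a GTF file
#'
#' Emits one `exon` feature per exon with `gene_id` and `transcript_id`
#' attributes, via [rtracklayer::export()].
#'
#' @param transcripts A list of `transcript_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_gtf <- function(transcripts, path) {
  if (!length(transcripts)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  parts <- lapply(transcripts, function(t) {
    n <- nrow(t$exons)
    data.frame(chrom = rep(t$chrom, n), start = t$exons$start,
               end = t$exons$end, strand = rep(t$strand, n),
               gene_id = rep(t$gene_id, n),
               transcript_id = rep(t$transcript_id, n),
               gene_biotype = rep(t$biotype, n))
  })
  df <- do.call(rbind, parts)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  gr$source <- "lacteome"
  gr$type <- "exon"
  gr$gene_id <- df$gene_id
  gr$transcript_id <- df$transcript_id
  gr$gene_biotype <- df$gene_biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a transcript-by-sample count matrix from TSV
#'
#' First column must be the transcript (or gene) id; remaining columns are
#' sample counts.
#'
#' @param path Path to a tab-separated file.
#' @return An integer matrix with row and column names.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  validate_count_matrix(m)
  m
}

#' Write a count matrix to TSV
#'
#' @param cm Count matrix with row and column names.
#' @param path Output path.
#' @param id_col Name for the id column (default `"transcript_id"`).
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(cm, path, id_col = "transcript_id") {
  df <- data.frame(rownames(cm), cm, check.names = FALSE,
                   row.names = NULL)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a coding-evidence table from TSV
#'
#' Expected columns (exactly): `transcript_id`, `orf_len_aa`, `cpc2_label`,
#' `plek_score`, `cnit_score`, `pfam_min_evalue`.  Empty fields are read as
#' missing (`NA`), meaning the quantity is absent (e.g. no predicted ORF, no
#' Pfam hit).
#'
#' @param path Path to a tab-separated file.
#' @return A data frame.
#' @export
read_evidence_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("transcript_id", "orf_len_aa", "cpc2_label", "plek_score",
            "cnit_score", "pfam_min_evalue")
  if (!identical(names(df), need))
    stop("evidence TSV must have columns exactly: ",
         paste(need, collapse = ", "))
  df$orf_len_aa <- as.integer(df$orf_len_aa)
  df
}

#' Read a sample sheet from TSV
#'
#' Columns `sample_id`, `dam_id`, `milk_type` (`colostrum`/`milk`) and
#' `parity` (1-4) are required.
#'
#' @param path Path to a tab-separated file.
#' @return A data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_count_matrix <- function(cm) {
  if (is.null(rownames(cm)) || is.null(colnames(cm)))
    stop("count matrix must have row (transcript) and column (sample) names")
  if (anyDuplicated(rownames(cm))) stop("duplicate transcript ids in counts")
  if (anyNA(cm) || any(cm < 0)) stop("counts must be non-negative and complete")
  invisible(cm)
}

validate_sample_sheet <- function(sheet, cm = NULL) {
  need <- c("sample_id", "dam_id", "milk_type", "parity")
  if (!all(need %in% names(sheet)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  if (!all(sheet$milk_type %in% c("colostrum", "milk")))
    stop("milk_type must be 'colostrum' or 'milk'")
  if (!all(sheet$parity %in% 1:4)) stop("parity must be in 1..4")
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample ids")
  if (!is.null(cm) && !all(sheet$sample_id %in% colnames(cm)))
    stop("every sample in the sheet must have a column in the count matrix")
  invisible(sheet)
}
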