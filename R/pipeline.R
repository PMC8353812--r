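#' Pipeline configuration
#'
#' Input paths and thresholds for the end-to-end analysis.  Threshold
#' defaults are the canonical values of the discovery and
#' differential-expression cascades: FPKM 0.3, spliced length 200 bp, ORF
#' 120 aa, Pfam E-value 10, FDR 0.01, transcript |log2FC| 2, gene |log2FC|
#' 1.5, enrichment FDR 0.05.
#'
#' @param reference_gtf,queries_gtf,counts,evidence,samples Paths to the
#'   reference annotation, assembled transcripts, count matrix, coding
#'   evidence and sample sheet.
#' @param totals Optional TSV (`sample_id`, `total_fragments`) of
#'   per-library total mapped fragments for FPKM; column sums are used when
#'   absent.
#' @param gene_map Optional TSV (`transcript_id`, `gene_id`); defaults to
#'   the gene ids carried by the query GTF.
#' @param term_map Optional term-to-gene map for over-representation
#'   testing (TSV or GMT).
#' @param outdir Output directory.
#' @param min_fpkm,min_length,min_orf_aa,pfam_evalue,fdr,lfc_transcript,lfc_gene,enrich_fdr
#'   Thresholds (see above).
#' @param seed Seed recorded in the run report (the analysis itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_gtf, queries_gtf, counts, evidence,
                            samples, totals = NULL, gene_map = NULL,
                            term_map = NULL, outdir = "lacteome_out",
                            min_fpkm = 0.3, min_length = 200,
                            min_orf_aa = 120, pfam_evalue = 10.0,
                            fdr = 0.01, lfc_transcript = 2, lfc_gene = 1.5,
                            enrich_fdr = 0.05, seed = 1L) {
  stopifnot(min_fpkm > 0, min_length > 0, min_orf_aa > 0, pfam_evalue > 0,
            fdr > 0, lfc_transcript > 0, lfc_gene > 0, enrich_fdr > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

stage_fail <- function(stage, msg) {
  stop(sprintf("[stage %s] %s", stage, msg), call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: novel-transcript discovery ([discovery_pipeline()]),
#' transcript-level differential expression ([de_test()] on the retained
#' transcripts), gene-level aggregation ([aggregate_genes()],
#' [gene_log2fc()], [deg_partition()]), marker-based cell composition
#' ([marker_proportions()]), and, when a term map is supplied,
#' over-representation testing of the milk-type DEG ([hypergeom_ora()]).
#' Result tables are written as TSVs under `config$outdir` together with a
#' YAML run report of thresholds, input checksums and per-stage counts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `verdicts`, `det` (transcript results +
#'   sets), `deg` (gene results + sets), `composition`, `enrichment`
#'   (or `NULL`), and `report`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  queries <- read_transcripts_gtf(config$queries_gtf)
  if (!length(queries)) stage_fail("input", "query GTF holds no transcripts")
  ref <- reference_annotation(read_transcripts_gtf(config$reference_gtf))
  cm <- read_counts_tsv(config$counts)
  evidence <- read_evidence_tsv(config$evidence)
  sheet <- read_sample_sheet(config$samples)
  validate_sample_sheet(sheet, cm)
  totals <- if (!is.null(config$totals)) {
    tt <- utils::read.delim(config$totals, stringsAsFactors = FALSE)
    stats::setNames(tt$total_fragments, tt$sample_id)
  } else colSums(cm)
  gene_map <- if (!is.null(config$gene_map)) {
    utils::read.delim(config$gene_map, stringsAsFactors = FALSE)
  } else {
    data.frame(transcript_id = names(queries),
               gene_id = vapply(queries, `[[`, character(1), "gene_id"))
  }

  th <- discovery_thresholds(config$min_fpkm, config$min_length,
                             config$min_orf_aa, config$pfam_evalue)
  verdicts <- discovery_pipeline(queries, ref, cm, evidence,
                                 totals = totals, thresholds = th)
  retained <- verdicts$transcript_id[verdicts$class != "discarded"]
  if (!length(retained)) stage_fail("discovery", "no transcript retained")

  cm_ret <- cm[retained, sheet$sample_id, drop = FALSE]
  tx_res <- de_test(cm_ret, sheet, allow_pseudo_reference = TRUE)
  det <- det_partition(tx_res, fdr = config$fdr,
                       lfc_transcript = config$lfc_transcript)

  gm_ret <- gene_map[gene_map$transcript_id %in% retained, , drop = FALSE]
  miss <- setdiff(retained, gm_ret$transcript_id)
  if (length(miss))
    stage_fail("aggregate", paste("gene map missing:",
                                  paste(utils::head(miss, 10), collapse = ", ")))
  gene_res <- aggregate_genes(tx_res, gm_ret)
  lfc_gene <- gene_log2fc(cm_ret, gm_ret, sheet)
  deg <- deg_partition(gene_res, lfc_gene, fdr = config$fdr,
                       lfc_gene = config$lfc_gene)
  gene_res$log2fc_type <- unname(lfc_gene[gene_res$gene_id])
  gene_res$deg_set <- ifelse(
    gene_res$gene_id %in% deg$interaction, "interaction",
    ifelse(gene_res$gene_id %in% deg$type, "type", "none"))

  gcm <- rowsum(cm_ret, gm_ret$gene_id[match(retained, gm_ret$transcript_id)])
  storage.mode(gcm) <- "integer"
  comp <- suppressWarnings(marker_proportions(gcm))
  comp_groups <- suppressWarnings(group_summary(comp, sheet))

  enr <- NULL
  if (!is.null(config$term_map)) {
    tm <- read_term_map(config$term_map)
    enr <- hypergeom_ora(deg$type, tm, background = unique(gm_ret$gene_id))
  }

  tx_res$det_set <- ifelse(
    tx_res$transcript_id %in% det$interaction, "interaction",
    ifelse(tx_res$transcript_id %in% det$type, "type",
           ifelse(tx_res$transcript_id %in% det$parity, "parity", "none")))

  report <- list(
    inputs = lapply(
      Filter(Negate(is.null),
             config[c("reference_gtf", "queries_gtf", "counts", "evidence",
                      "samples", "totals", "gene_map", "term_map")]),
      function(p) unname(tools::md5sum(p))),
    thresholds = config[c("min_fpkm", "min_length", "min_orf_aa",
                          "pfam_evalue", "fdr", "lfc_transcript", "lfc_gene",
                          "enrich_fdr")],
    seed = config$seed,
    funnel = as.list(attr(verdicts, "funnel")),
    det_sizes = lapply(det, length),
    deg_sizes = lapply(deg, length))

  write_tsv(verdicts, file.path(config$outdir, "verdicts.tsv"))
  write_tsv(tx_res, file.path(config$outdir, "transcript_de.tsv"))
  write_tsv(gene_res, file.path(config$outdir, "gene_de.tsv"))
  write_tsv(comp, file.path(config$outdir, "composition.tsv"))
  if (!is.null(enr))
    write_tsv(enr, file.path(config$outdir, "enrichment.tsv"))
  yaml::write_yaml(report, file.path(config$outdir, "run_report.yaml"))

  invisible(list(verdicts = verdicts,
                 det = list(results = tx_res, sets = det),
                 deg = list(results = gene_res, sets = deg,
                            log2fc = lfc_gene),
                 composition = list(profiles = comp, groups = comp_groups),
                 enrichment = enr,
                 report = report))
}
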