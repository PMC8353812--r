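#' Upper-tail gamma quantile transform
#'
#' The per-transcript transform of the weighted Lancaster combination: the
#' value whose upper-tail probability under a Gamma distribution with shape
#' `w/2` and scale 2 equals `p`.  With `w = 2` this is exactly Fisher's
#' `-2 log(p)`, and for any `w` it equals the chi-squared upper quantile
#' with `w` degrees of freedom.
#'
#' @param p P-value(s) in `(0, 1]`.
#' @param w Positive weight(s); recycled against `p`.
#' @return Numeric vector of transformed values (0 at `p = 1`).
#' @export
gamma_upper_quantile <- function(p, w) {
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p must lie in (0, 1]")
  stats::qgamma(p, shape = w / 2, scale = 2, lower.tail = FALSE)
}

#' Weighted Lancaster combination of P-values
#'
#' Combines the P-values of a gene's member transcripts into one gene-level
#' P-value.  Each `p_i` is transformed by the upper-tail quantile of a
#' Gamma(shape `w_i/2`, scale 2) distribution; the sum of the transforms is
#' referred to a chi-squared distribution with `sum(w_i)` degrees of
#' freedom.  With all weights equal to 2 this reduces exactly to Fisher's
#' method.  Pairs with zero weight or missing P-value are dropped before
#' summation; P-values are clipped to `[1e-300, 1]` for numerical safety.
#'
#' @param p Numeric vector of transcript P-values.
#' @param w Non-negative weights, same length as `p` (e.g. mean normalized
#'   expression).
#' @return A list with `statistic` (the chi-squared statistic `T`), `df`
#'   (sum of retained weights), `p_agg`, `k_used` (pairs retained), and
#'   `defined` (`FALSE` when nothing was retained, in which case `p_agg` is
#'   `NA` rather than silently 1).
#' @export
#' @examples
#' lancaster_pvalue(c(0.05, 0.05), c(2, 2))$p_agg  # ~0.0174 (Fisher)
lancaster_pvalue <- function(p, w) {
  if (length(p) != length(w)) stop("p and w must have equal length")
  if (any(!is.na(w) & w < 0)) stop("weights must be non-negative")
  keep <- !is.na(p) & !is.na(w) & w > 0
  if (!any(keep))
    return(list(statistic = NA_real_, df = NA_real_, p_agg = NA_real_,
                k_used = 0L, defined = FALSE))
  pk <- pmin(pmax(p[keep], 1e-300), 1)
  wk <- w[keep]
  stat <- sum(gamma_upper_quantile(pk, wk))
  df <- sum(wk)
  list(statistic = stat, df = df,
       p_agg = stats::pchisq(stat, df = df, lower.tail = FALSE),
       k_used = sum(keep), defined = TRUE)
}

#' Aggregate transcript-level tests to gene level
#'
#' For each gene and each effect (interaction, milk type, parity) combines
#' the member transcripts' P-values with [lancaster_pvalue()], weighting
#' each transcript by its mean normalized expression (`base_mean`), then
#' applies Benjamini-Hochberg adjustment across the defined genes of each
#' effect.  Genes whose transcripts all have zero weight (or missing
#' P-values) are reported with `defined = FALSE` and excluded from the
#' adjustment.
#'
#' @param tx_results Transcript-level table from [de_test()].
#' @param gene_map Data frame with columns `transcript_id`, `gene_id`
#'   covering every transcript in `tx_results`.
#' @return A data frame with one row per gene: `gene_id`, `n_transcripts`,
#'   `p_agg_*`, `fdr_*` for the three effects, and `defined`.
#' @export
aggregate_genes <- function(tx_results, gene_map) {
  miss <- setdiff(tx_results$transcript_id, gene_map$transcript_id)
  if (length(miss))
    stop("gene map missing transcripts: ",
         paste(utils::head(miss, 10), collapse = ", "))
  gid <- gene_map$gene_id[match(tx_results$transcript_id,
                                gene_map$transcript_id)]
  genes <- sort(unique(gid))
  idx <- split(seq_len(nrow(tx_results)), gid)
  effects <- c(interaction = "p_interaction", type = "p_type",
               parity = "p_parity")
  out <- data.frame(gene_id = genes,
                    n_transcripts = unname(lengths(idx)[genes]),
                    row.names = NULL)
  defined <- rep(TRUE, length(genes))
  for (eff in names(effects)) {
    pcol <- effects[[eff]]
    agg <- vapply(genes, function(g) {
      i <- idx[[g]]
      lancaster_pvalue(tx_results[[pcol]][i],
                       tx_results$base_mean[i])$p_agg
    }, numeric(1))
    defined <- defined & !is.na(agg)
    out[[paste0("p_agg_", eff)]] <- agg
    out[[paste0("fdr_", eff)]] <- bh_adjust(agg)
  }
  out$defined <- defined
  out
}

#' Gene-level log2 fold change (milk vs colostrum)
#'
#' Transcript counts are summed within each gene and the milk-type
#' coefficient of the additive negative-binomial model (with the gene's own
#' method-of-moments dispersion) is converted to a log2 fold change.
#'
#' @param cm Transcript-level count matrix.
#' @param gene_map Data frame `transcript_id`, `gene_id` covering every row
#'   of `cm`.
#' @param sheet Sample sheet.
#' @param sf Size factors (default computed from the transcript matrix).
#' @return Named numeric vector of gene log2 fold changes (`NA` for
#'   all-zero genes).
#' @export
gene_log2fc <- function(cm, gene_map, sheet, sf = NULL) {
  validate_count_matrix(cm)
  miss <- setdiff(rownames(cm), gene_map$transcript_id)
  if (length(miss))
    stop("gene map missing transcripts: ",
         paste(utils::head(miss, 10), collapse = ", "))
  if (is.null(sf)) sf <- size_factors(cm, allow_pseudo_reference = TRUE)
  gid <- gene_map$gene_id[match(rownames(cm), gene_map$transcript_id)]
  gcm <- rowsum(cm, gid)
  disp <- estimate_dispersion(gcm, sf, sheet)
  X <- design_matrices(sheet)
  sfv <- sf[sheet$sample_id]
  lfc <- vapply(seq_len(nrow(gcm)), function(i) {
    y <- gcm[i, sheet$sample_id]
    if (all(y == 0)) return(NA_real_)
    nb_glm_test_raw(y, X, sfv, disp[i])$log2fc_type
  }, numeric(1))
  stats::setNames(lfc, rownames(gcm))
}

#' Partition genes into differential-expression sets
#'
#' Interaction DEG: interaction FDR at or below `fdr`.  Milk-type DEG:
#' milk-type FDR at or below `fdr`, not already an interaction DEG, and
#' absolute gene log2 fold change strictly greater than `lfc_gene` (genes
#' with `|log2FC| <= lfc_gene` are filtered out).
#'
#' @param gene_results Table from [aggregate_genes()].
#' @param log2fc Named vector from [gene_log2fc()].
#' @param fdr FDR threshold (default 0.01).
#' @param lfc_gene Gene-level fold-change threshold (default 1.5).
#' @return A list of character vectors `interaction`, `type`.
#' @export
deg_partition <- function(gene_results, log2fc, fdr = 0.01, lfc_gene = 1.5) {
  isTrue <- function(x) !is.na(x) & x
  lfc <- log2fc[gene_results$gene_id]
  int <- isTrue(gene_results$fdr_interaction <= fdr)
  typ <- !int & isTrue(gene_results$fdr_type <= fdr) &
    isTrue(abs(lfc) > lfc_gene)
  list(interaction = gene_results$gene_id[int],
       type = gene_results$gene_id[typ])
}
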