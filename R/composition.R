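#' Default cell-type marker panel for whole milk
#'
#' Fifteen cell-specific marker genes used to gauge the relative cell-type
#' composition of whole-milk samples: pan-immune and lymphocyte markers
#' (PTPRC, CD8A, NCAM1, CD19, CD4, CD3E, CD3D, CD3G), stromal markers
#' (FABP4, SL100A4, DLK1), epithelial markers (LAMP1, EPCAM, KRT8), and the
#' hemopoietic stem-cell marker CD34.  The stromal symbol is shipped as
#' `SL100A4` for fidelity with the source table; set
#' `alias_s100a4 = TRUE` to use the conventional `S100A4` symbol instead.
#'
#' @param alias_s100a4 Replace `SL100A4` with `S100A4` (default `FALSE`).
#' @return A data frame with columns `symbol`, `cell_type`.
#' @export
default_marker_panel <- function(alias_s100a4 = FALSE) {
  panel <- data.frame(
    symbol = c("PTPRC", "CD8A", "NCAM1", "CD19", "CD4", "CD3E", "CD3D",
               "CD3G", "FABP4", "SL100A4", "DLK1", "LAMP1", "EPCAM",
               "KRT8", "CD34"),
    cell_type = c(rep("immune", 8), rep("stromal", 3), rep("epithelial", 3),
                  "stem"))
  if (alias_s100a4) panel$symbol[panel$symbol == "SL100A4"] <- "S100A4"
  panel
}

validate_panel <- function(panel) {
  if (!all(c("symbol", "cell_type") %in% names(panel)))
    stop("panel needs columns symbol, cell_type")
  if (anyDuplicated(panel$symbol)) stop("panel symbols must be unique")
  invisible(panel)
}

#' Per-sample marker proportions
#'
#' For each sample, the number of reads mapped to each cell-specific marker
#' divided by the sum of reads mapped to all markers of the panel.  Raw
#' counts are used without length correction.  Samples with zero reads on
#' every marker yield an undefined profile (`NA` proportions).  Panel
#' symbols absent from the matrix are treated as zero with a warning.
#'
#' @param cm Gene-level count matrix (genes x samples).
#' @param panel Marker panel data frame (see [default_marker_panel()]).
#' @return A long-format data frame with columns `sample_id`, `symbol`,
#'   `cell_type`, `proportion`, `defined`.
#' @export
marker_proportions <- function(cm, panel = default_marker_panel()) {
  validate_count_matrix(cm)
  validate_panel(panel)
  missing <- setdiff(panel$symbol, rownames(cm))
  if (length(missing))
    warning("marker(s) absent from counts, treated as zero: ",
            paste(missing, collapse = ", "))
  sub <- matrix(0, nrow = nrow(panel), ncol = ncol(cm),
                dimnames = list(panel$symbol, colnames(cm)))
  present <- intersect(panel$symbol, rownames(cm))
  sub[present, ] <- cm[present, , drop = FALSE]
  tot <- colSums(sub)
  prop <- sweep(sub, 2L, ifelse(tot > 0, tot, NA_real_), "/")
  data.frame(
    sample_id = rep(colnames(cm), each = nrow(panel)),
    symbol = rep(panel$symbol, ncol(cm)),
    cell_type = rep(panel$cell_type, ncol(cm)),
    proportion = as.vector(prop),
    defined = rep(tot > 0, each = nrow(panel)),
    row.names = NULL)
}

#' Mean marker proportions per milk-type by parity group
#'
#' Averages the defined per-sample profiles within each milk-type by parity
#' cell, and additionally totals the markers of each cell type.  Samples
#' with undefined profiles are excluded from the means (not imputed as
#' zero); empty groups are dropped with a warning.
#'
#' @param profiles Output of [marker_proportions()].
#' @param sheet Sample sheet covering every profiled sample.
#' @return A list with two data frames: `marker` (`milk_type`, `parity`,
#'   `symbol`, `cell_type`, `mean_proportion`) and `cell_type`
#'   (`milk_type`, `parity`, `cell_type`, `mean_proportion`).
#' @export
group_summary <- function(profiles, sheet) {
  validate_sample_sheet(sheet)
  miss <- setdiff(unique(profiles$sample_id), sheet$sample_id)
  if (length(miss))
    stop("sample sheet missing: ", paste(miss, collapse = ", "))
  pr <- profiles[profiles$defined, , drop = FALSE]
  if (!nrow(pr)) {
    warning("no defined composition profile; returning empty summaries")
    empty_m <- data.frame(milk_type = character(0), parity = integer(0),
                          symbol = character(0), cell_type = character(0),
                          mean_proportion = numeric(0))
    empty_c <- empty_m[, c("milk_type", "parity", "cell_type",
                           "mean_proportion")]
    return(list(marker = empty_m, cell_type = empty_c))
  }
  i <- match(pr$sample_id, sheet$sample_id)
  pr$milk_type <- sheet$milk_type[i]
  pr$parity <- sheet$parity[i]
  empty <- setdiff(
    unique(paste(sheet$milk_type, sheet$parity)),
    unique(paste(pr$milk_type, pr$parity)))
  if (length(empty))
    warning("group(s) with no defined profile dropped: ",
            paste(empty, collapse = "; "))
  marker <- stats::aggregate(
    proportion ~ milk_type + parity + symbol + cell_type, data = pr,
    FUN = mean)
  names(marker)[names(marker) == "proportion"] <- "mean_proportion"
  ct <- stats::aggregate(
    mean_proportion ~ milk_type + parity + cell_type, data = marker,
    FUN = sum)
  marker <- marker[order(marker$milk_type, marker$parity, marker$symbol), ]
  ct <- ct[order(ct$milk_type, ct$parity, ct$cell_type), ]
  rownames(marker) <- rownames(ct) <- NULL
  list(marker = marker, cell_type = ct)
}
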