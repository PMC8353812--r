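#' Hypergeometric over-representation test
#'
#' For each term, tests whether the differential-expression set contains
#' more of the term's genes than expected by chance, using the upper-tail
#' hypergeometric probability `P(X >= k)` (the observed overlap included).
#' With background size `N`, term size `K`, DE-set size `n` and overlap
#' `k`, the P-value is `phyper(k - 1, K, N - K, n, lower.tail = FALSE)`.
#' P-values are Benjamini-Hochberg adjusted across the tested terms.
#'
#' Term genes outside the background are dropped (with a warning), as are
#' DE genes outside the background; terms left empty are skipped.
#'
#' @param de_set Character vector of differentially expressed gene ids.
#' @param term_map Data frame with columns `term_id`, `gene_id`.
#' @param background Character vector of background gene ids (the universe;
#'   typically all genes surviving the expression filters).
#' @return A data frame with one row per tested term: `term_id`, `N`, `K`,
#'   `n`, `k`, `fold_enrichment`, `p`, `fdr`, ordered by `p`.
#' @export
hypergeom_ora <- function(de_set, term_map, background) {
  if (!all(c("term_id", "gene_id") %in% names(term_map)))
    stop("term_map needs columns term_id, gene_id")
  background <- unique(background)
  if (!length(background)) stop("background gene set is empty")
  out_bg <- setdiff(term_map$gene_id, background)
  if (length(out_bg)) {
    warning(length(out_bg), " term gene(s) outside background dropped")
    term_map <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  }
  de_set <- unique(de_set)
  de_out <- setdiff(de_set, background)
  if (length(de_out)) {
    warning(length(de_out), " DE gene(s) outside background dropped")
    de_set <- intersect(de_set, background)
  }
  N <- length(background)
  n <- length(de_set)
  sets <- split(unique(term_map)$gene_id, unique(term_map)$term_id)
  sets <- sets[lengths(sets) > 0L]
  if (!length(sets))
    return(data.frame(term_id = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0),
                      fold_enrichment = numeric(0), p = numeric(0),
                      fdr = numeric(0)))
  K <- lengths(sets)
  k <- vapply(sets, function(g) length(intersect(g, de_set)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fe <- if (n > 0) (k / n) / (K / N) else rep(NA_real_, length(k))
  res <- data.frame(term_id = names(sets), N = N, K = unname(K), n = n,
                    k = unname(k), fold_enrichment = unname(fe),
                    p = unname(p), fdr = unname(bh_adjust(p)),
                    row.names = NULL)
  res[order(res$p, res$term_id), , drop = FALSE]
}

#' Read a term-to-gene map
#'
#' Accepts either a two-column TSV (`term_id`, `gene_id`) or a GMT file
#' (term, description, genes...).
#'
#' @param path Input path.
#' @param format `"tsv"` or `"gmt"`; guessed from the file extension by
#'   default.
#' @return A data frame with columns `term_id`, `gene_id`.
#' @export
read_term_map <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("term_id", "gene_id") %in% names(df)))
      stop("term map TSV needs columns term_id, gene_id")
    return(df[, c("term_id", "gene_id")])
  }
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  do.call(rbind, lapply(parts, function(x) {
    if (length(x) < 3L) return(NULL)
    data.frame(term_id = x[1L], gene_id = x[-(1:2)])
  }))
}
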