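#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: for each sample, the median over
#' reference transcripts of the ratio between its count and the
#' geometric mean of that transcript's counts across samples.  By default
#' the reference set is the transcripts with all-positive counts; when none
#' exists, set `allow_pseudo_reference = TRUE` to fall back to geometric
#' means computed over the positive entries of each row.
#'
#' @param cm Count matrix.
#' @param allow_pseudo_reference Fall back to positive-entry geometric means
#'   when no transcript has all-positive counts (default `FALSE`).
#' @return Named numeric vector of positive size factors (one per sample).
#' @export
size_factors <- function(cm, allow_pseudo_reference = FALSE) {
  validate_count_matrix(cm)
  allpos <- rowSums(cm == 0) == 0L
  if (!any(allpos)) {
    if (!allow_pseudo_reference)
      stop("no transcript has all-positive counts; rerun with ",
           "allow_pseudo_reference = TRUE to use a pseudo-reference")
    use <- rowSums(cm > 0) > 0L
    loggeo <- apply(cm[use, , drop = FALSE], 1L, function(x)
      mean(log(x[x > 0])))
    ratios <- log(cm[use, , drop = FALSE])
    ratios[!is.finite(ratios)] <- NA
    sf <- exp(apply(ratios - loggeo, 2L, stats::median, na.rm = TRUE))
  } else {
    sub <- cm[allpos, , drop = FALSE]
    loggeo <- rowMeans(log(sub))
    sf <- exp(apply(log(sub) - loggeo, 2L, stats::median))
  }
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size factor estimation failed (non-positive factor)")
  stats::setNames(sf, colnames(cm))
}

#' Mean normalized expression per transcript
#'
#' The mean across samples of counts divided by size factors; used both as a
#' summary of expression and as the weight of each transcript in gene-level
#' P-value aggregation.
#'
#' @param cm Count matrix.
#' @param sf Size factors from [size_factors()].
#' @return Named numeric vector, one value per transcript.
#' @export
base_mean <- function(cm, sf) {
  stopifnot(all(sf > 0), all(colnames(cm) %in% names(sf)))
  rowMeans(sweep(cm, 2L, sf[colnames(cm)], "/"))
}

design_factors <- function(sheet) {
  type <- factor(sheet$milk_type, levels = c("colostrum", "milk"))
  parity <- factor(sheet$parity, levels = sort(unique(sheet$parity)))
  list(type = type, parity = parity)
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-transcript dispersion `phi` in the parameterization
#' `Var = mu + phi * mu^2`, estimated on size-factor-normalized counts by
#' pooling within-cell sample variances over the cells of the milk-type by
#' parity design and solving the moment equation.  The denominator uses the
#' unbiased moment estimator of the squared cell mean
#' (`m_hat^2 - S2/n_cell`), without which the ratio is biased downward by
#' `Var(m_hat)/m^2` at small cell sizes.  No shrinkage across transcripts is
#' applied; estimates are floored at `1e-8`.
#'
#' @param cm Count matrix.
#' @param sf Size factors.
#' @param sheet Sample sheet (defines the design cells); every cell needs at
#'   least two samples.
#' @return Named numeric vector of dispersions.
#' @export
estimate_dispersion <- function(cm, sf, sheet) {
  validate_sample_sheet(sheet, cm)
  fac <- design_factors(sheet)
  cell <- interaction(fac$type, fac$parity, drop = TRUE)
  if (any(table(cell) < 2L))
    stop("every milk-type x parity cell needs >= 2 samples")
  sfv <- sf[sheet$sample_id]
  y <- sweep(cm[, sheet$sample_id, drop = FALSE], 2L, sfv, "/")
  num <- 0; den <- 0
  for (lev in levels(cell)) {
    j <- which(cell == lev)
    nc <- length(j)
    m <- rowMeans(y[, j, drop = FALSE])
    v <- rowSums((y[, j, drop = FALSE] - m)^2) / (nc - 1L)
    a <- mean(1 / sfv[j])  # Poisson part of Var(count/sf)
    num <- num + (nc - 1L) * (v - m * a)
    den <- den + (nc - 1L) * pmax(m^2 - v / nc, 0)
  }
  phi <- ifelse(den > 0, num / den, 0)
  stats::setNames(pmax(phi, 1e-8), rownames(cm))
}

# model matrices for the nested fits; sheet must already be validated
design_matrices <- function(sheet) {
  fac <- design_factors(sheet)
  d <- data.frame(type = fac$type, parity = fac$parity)
  list(full = stats::model.matrix(~ type * parity, d),
       additive = stats::model.matrix(~ type + parity, d),
       parity_only = stats::model.matrix(~ parity, d),
       type_only = stats::model.matrix(~ type, d))
}

fit_deviance <- function(y, X, fam, off) {
  fit <- suppressWarnings(
    stats::glm.fit(x = X, y = y, family = fam, offset = off,
                   control = list(maxit = 100)))
  if (!fit$converged)
    return(list(dev = NA_real_, coef = fit$coefficients, mu = NULL))
  list(dev = fit$deviance, coef = fit$coefficients,
       mu = fit$fitted.values)
}

#' Negative-binomial GLM tests for one transcript
#'
#' Fits log-link negative-binomial GLMs with a fixed dispersion and an
#' `log(size factor)` offset under the model
#' `counts ~ Type + Parity + Type:Parity` and returns likelihood-ratio
#' P-values for the interaction (full vs additive, 3 df with 4 parities),
#' the milk-type main effect (additive vs parity-only, 1 df), and the parity
#' main effect (additive vs type-only), together with the milk-vs-colostrum
#' log2 fold change taken from the additive model so that it remains
#' interpretable when the interaction is absent.
#'
#' @param counts Integer vector of counts for one transcript (not all zero).
#' @param sheet Sample sheet aligned with `counts`.
#' @param sf Size factors.
#' @param dispersion Fixed dispersion `phi` (`Var = mu + phi mu^2`).
#' @return List with `p_interaction`, `p_type`, `p_parity`, `log2fc_type`,
#'   and `converged`.  Non-converged fits yield `NA` P-values.
#' @export
nb_glm_test <- function(counts, sheet, sf, dispersion) {
  X <- design_matrices(sheet)
  nb_glm_test_raw(counts, X, sf[sheet$sample_id], dispersion)
}

# plug-in likelihood-ratio tests: deviance differences at a fixed
# dispersion referred to chi-squared
nb_glm_test_raw <- function(counts, X, sfv, dispersion) {
  na_out <- list(p_interaction = NA_real_, p_type = NA_real_,
                 p_parity = NA_real_, log2fc_type = NA_real_,
                 converged = FALSE)
  if (all(counts == 0)) return(na_out)
  fam <- if (dispersion < 1e-8) stats::poisson() else
    MASS::negative.binomial(theta = 1 / dispersion)
  off <- log(sfv)
  fits <- tryCatch(
    lapply(X, fit_deviance, y = counts, fam = fam, off = off),
    error = function(e) NULL)
  if (is.null(fits) || anyNA(vapply(fits, `[[`, numeric(1), "dev")))
    return(na_out)
  dev <- vapply(fits, `[[`, numeric(1), "dev")
  df_int <- ncol(X$full) - ncol(X$additive)
  df_type <- ncol(X$additive) - ncol(X$parity_only)
  df_par <- ncol(X$additive) - ncol(X$type_only)
  lrt <- function(d_red, d_full, df)
    stats::pchisq(max(d_red - d_full, 0), df = df, lower.tail = FALSE)
  co <- fits$additive$coef
  l2fc <- unname(co[grep("^typemilk$", names(co))]) / log(2)
  list(p_interaction = lrt(dev["additive"], dev["full"], df_int),
       p_type = lrt(dev["parity_only"], dev["additive"], df_type),
       p_parity = lrt(dev["type_only"], dev["additive"], df_par),
       log2fc_type = if (length(l2fc)) l2fc else NA_real_,
       converged = TRUE)
}

# quasi-likelihood machinery: for every transcript fit the four nested
# models at the pooled dispersion and form, per effect, the deviance LRT
# divided by its df and by the transcript's full-model deviance scale
# (deviance / residual df).  Returns the statistics plus the fitted means
# of each effect's null model for the bootstrap calibration.
ql_fit_all <- function(cm, X, sfv, pooled) {
  nt <- nrow(cm); ns <- ncol(cm)
  fam <- if (pooled < 1e-8) stats::poisson() else
    MASS::negative.binomial(theta = 1 / pooled)
  off <- log(sfv)
  dfr <- ns - ncol(X$full)
  Tstat <- matrix(NA_real_, nt, 3,
                  dimnames = list(NULL, c("interaction", "type", "parity")))
  lfc <- rep(NA_real_, nt)
  conv <- rep(FALSE, nt)
  mu0 <- list(interaction = matrix(NA_real_, nt, ns),
              type = matrix(NA_real_, nt, ns),
              parity = matrix(NA_real_, nt, ns))
  for (i in seq_len(nt)) {
    y <- cm[i, ]
    if (all(y == 0)) next
    fits <- tryCatch(
      lapply(X, fit_deviance, y = y, fam = fam, off = off),
      error = function(e) NULL)
    if (is.null(fits) || anyNA(vapply(fits, `[[`, numeric(1), "dev"))) next
    s2 <- max(fits$full$dev / dfr, 1e-6)
    Tstat[i, ] <- c(
      max(fits$additive$dev - fits$full$dev, 0) / 3 / s2,
      max(fits$parity_only$dev - fits$additive$dev, 0) / 1 / s2,
      max(fits$type_only$dev - fits$additive$dev, 0) / 3 / s2)
    mu0$interaction[i, ] <- fits$additive$mu
    mu0$type[i, ] <- fits$parity_only$mu
    mu0$parity[i, ] <- fits$type_only$mu
    co <- fits$additive$coef
    l <- unname(co[grep("^typemilk$", names(co))]) / log(2)
    if (length(l)) lfc[i] <- l
    conv[i] <- TRUE
  }
  list(Tstat = Tstat, lfc = lfc, converged = conv, mu0 = mu0,
       dfr = dfr, fam = fam, off = off)
}

# parametric-bootstrap scale calibration of the quasi-likelihood F
# reference: simulate null counts from each effect's fitted null means at
# the pooled dispersion, recompute the scaled statistics, and match their
# upper quantiles against the nominal F distribution
ql_calibrate <- function(fit, X, pooled, n_boot) {
  nt <- nrow(fit$Tstat); ns <- length(fit$off)
  dfr <- fit$dfr
  pairs <- list(interaction = list(red = "additive", full = "full", df = 3),
                type = list(red = "parity_only", full = "additive", df = 1),
                parity = list(red = "type_only", full = "additive", df = 3))
  qs <- c(0.90, 0.925, 0.95, 0.975, 0.99)
  out <- c(interaction = 1, type = 1, parity = 1)
  usable <- which(fit$converged)
  if (length(usable) * n_boot < 200) return(out)
  for (eff in names(pairs)) {
    pr <- pairs[[eff]]
    mu0 <- fit$mu0[[eff]]
    Ts <- numeric(0)
    for (b in seq_len(n_boot)) {
      ysim <- matrix(
        if (pooled < 1e-8) stats::rpois(nt * ns, as.vector(mu0))
        else stats::rnbinom(nt * ns, mu = as.vector(mu0), size = 1 / pooled),
        nt, ns)
      tb <- vapply(usable, function(i) {
        fr <- fit_deviance(ysim[i, ], X[[pr$red]], fit$fam, fit$off)
        ff <- fit_deviance(ysim[i, ], X[[pr$full]], fit$fam, fit$off)
        fu <- if (pr$full == "full") ff else
          fit_deviance(ysim[i, ], X$full, fit$fam, fit$off)
        if (anyNA(c(fr$dev, ff$dev, fu$dev))) return(NA_real_)
        max(fr$dev - ff$dev, 0) / pr$df / max(fu$dev / dfr, 1e-6)
      }, numeric(1))
      Ts <- c(Ts, tb[!is.na(tb)])
    }
    if (length(Ts) >= 200)
      out[eff] <- mean(stats::quantile(Ts, qs) / stats::qf(qs, pr$df, dfr))
  }
  out
}

#' Transcript-level differential expression
#'
#' Runs the full per-transcript analysis: size factors, base means,
#' method-of-moments dispersions, negative-binomial deviance tests for the
#' interaction and both main effects, and Benjamini-Hochberg adjustment of
#' each P-value column (over the tested, i.e. non-missing, transcripts).
#'
#' By default (`method = "ql"`) the per-transcript deviance statistics are
#' referred to a calibrated quasi-likelihood F reference: the
#' negative-binomial family uses the pooled (median) dispersion, each
#' transcript's full-model deviance scale forms the F denominator with the
#' residual degrees of freedom (absorbing per-transcript departures from
#' the pooled dispersion), and a per-effect scale constant for the F
#' reference is estimated by a parametric bootstrap under each effect's
#' fitted null model.  This keeps the null rejection rate at its nominal
#' level at small sample sizes, where a plug-in chi-squared LRT with noisy
#' per-transcript dispersions is markedly anticonservative.  Set
#' `method = "lrt"` for the plug-in likelihood-ratio test with
#' per-transcript dispersions.
#'
#' Inputs are canonicalized internally (transcripts by id, samples by id),
#' so results do not depend on row or column order; the bootstrap uses its
#' own seeded RNG stream and restores the caller's RNG state.
#'
#' @param cm Count matrix.
#' @param sheet Sample sheet.
#' @param sf Optional pre-computed size factors.
#' @param dispersions Optional pre-computed per-transcript dispersions.
#' @param method `"ql"` (default) or `"lrt"`; see above.
#' @param n_boot Bootstrap replicates for the F-scale calibration
#'   (default 3; only used by `"ql"`).
#' @param calib_seed Seed of the bootstrap RNG stream (default 1).
#' @param allow_pseudo_reference Passed to [size_factors()].
#' @return A data frame with one row per transcript (input order):
#'   `transcript_id`, `base_mean`, `log2fc_type`, `p_interaction`,
#'   `p_type`, `p_parity`, `fdr_interaction`, `fdr_type`, `fdr_parity`,
#'   `converged`.  All-zero transcripts get `NA` P-values.
#' @export
de_test <- function(cm, sheet, sf = NULL, dispersions = NULL,
                    method = c("ql", "lrt"), n_boot = 3, calib_seed = 1L,
                    allow_pseudo_reference = FALSE) {
  method <- match.arg(method)
  validate_count_matrix(cm)
  validate_sample_sheet(sheet, cm)
  in_order <- rownames(cm)
  sheet <- sheet[order(sheet$sample_id), , drop = FALSE]
  cm <- cm[order(rownames(cm)), sheet$sample_id, drop = FALSE]
  if (is.null(sf))
    sf <- size_factors(cm, allow_pseudo_reference = allow_pseudo_reference)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(cm, sf, sheet)
  dispersions <- dispersions[rownames(cm)]
  X <- design_matrices(sheet)
  if (qr(X$full)$rank < ncol(X$full))
    stop("design matrix is rank deficient: unpopulated design cells")
  sfv <- sf[sheet$sample_id]

  if (method == "ql") {
    expressed <- rowSums(cm) > 0
    pooled <- stats::median(dispersions[expressed])
    fit <- ql_fit_all(cm, X, sfv, pooled)
    cal <- with_boot_rng(calib_seed,
                         ql_calibrate(fit, X, pooled, n_boot = n_boot))
    dfr <- fit$dfr
    pv <- function(eff, df)
      stats::pf(fit$Tstat[, eff] / cal[eff], df1 = df, df2 = dfr,
                lower.tail = FALSE)
    out <- data.frame(
      transcript_id = rownames(cm),
      base_mean = unname(base_mean(cm, sf)),
      log2fc_type = fit$lfc,
      p_interaction = unname(pv("interaction", 3)),
      p_type = unname(pv("type", 1)),
      p_parity = unname(pv("parity", 3)),
      converged = fit$converged,
      row.names = NULL)
  } else {
    res <- lapply(seq_len(nrow(cm)), function(i)
      nb_glm_test_raw(cm[i, ], X, sfv, dispersions[i]))
    out <- data.frame(
      transcript_id = rownames(cm),
      base_mean = unname(base_mean(cm, sf)),
      log2fc_type = vapply(res, `[[`, numeric(1), "log2fc_type"),
      p_interaction = vapply(res, `[[`, numeric(1), "p_interaction"),
      p_type = vapply(res, `[[`, numeric(1), "p_type"),
      p_parity = vapply(res, `[[`, numeric(1), "p_parity"),
      converged = vapply(res, `[[`, logical(1), "converged"),
      row.names = NULL)
  }
  out <- out[match(in_order, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out$fdr_interaction <- bh_adjust(out$p_interaction)
  out$fdr_type <- bh_adjust(out$p_type)
  out$fdr_parity <- bh_adjust(out$p_parity)
  out
}

# evaluate `expr` under a private seeded RNG stream, restoring the caller's
with_boot_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted P-values, capped at 1.  Missing entries (untested
#' transcripts) are passed through unchanged and do not count toward the
#' number of tests.
#'
#' @param p Numeric vector of P-values in `[0, 1]` (may contain `NA`).
#' @return Numeric vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- p
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Partition transcripts into differential-expression sets
#'
#' Transcripts with interaction FDR at or below `fdr` are interaction DET.
#' Among the remainder, milk-type DET additionally require
#' `|log2FC| >= lfc_transcript`, and parity DET require only the parity FDR
#' cut (no fold-change filter).  The three sets are disjoint by
#' construction.
#'
#' @param res Result table from [de_test()].
#' @param fdr FDR threshold (default 0.01).
#' @param lfc_transcript Absolute log2-fold-change threshold for the
#'   milk-type set (default 2).
#' @return A list of character vectors `interaction`, `type`, `parity`.
#' @export
det_partition <- function(res, fdr = 0.01, lfc_transcript = 2) {
  isTrue <- function(x) !is.na(x) & x
  int <- isTrue(res$fdr_interaction <= fdr)
  typ <- !int & isTrue(res$fdr_type <= fdr) &
    isTrue(abs(res$log2fc_type) >= lfc_transcript)
  par <- !int & isTrue(res$fdr_parity <= fdr)
  list(interaction = res$transcript_id[int],
       type = res$transcript_id[typ],
       parity = res$transcript_id[par])
}

#' Per-group mean normalized expression with ranks
#'
#' Averages size-factor-normalized counts within each sample group and ranks
#' features within groups by decreasing mean; features with equal means get
#' adjacent ranks, broken deterministically by id.
#'
#' @param cm Count matrix (transcript- or gene-level).
#' @param sf Size factors.
#' @param groups Factor or character vector assigning each column of `cm`
#'   to a group (names or order matching `colnames(cm)`).
#' @return A data frame with the feature id, one `mean_<group>` and one
#'   `rank_<group>` column per group.
#' @export
expression_summary <- function(cm, sf, groups) {
  stopifnot(length(groups) == ncol(cm))
  if (!is.null(names(groups))) groups <- groups[colnames(cm)]
  groups <- factor(groups)
  y <- sweep(cm, 2L, sf[colnames(cm)], "/")
  ids <- rownames(cm)
  out <- data.frame(id = ids, row.names = NULL)
  for (g in levels(groups)) {
    m <- rowMeans(y[, groups == g, drop = FALSE])
    o <- order(-m, ids)
    r <- integer(length(m)); r[o] <- seq_along(m)
    out[[paste0("mean_", g)]] <- unname(m)
    out[[paste0("rank_", g)]] <- r
  }
  out
}
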