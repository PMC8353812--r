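#' Per-test alpha from a marginal false-discovery-rate target
#'
#' Inverts the marginal FDR identity for a multiple-testing experiment with
#' `m` tests of which `m1` are expected true positives detected with the
#' given `power`:
#' `alpha = f * m1 * power / ((m - m1) * (1 - f))`, clipped to `(0, 1)`.
#'
#' @param f Target FDR level in `(0, 1)`.
#' @param m Total number of tested genes.
#' @param m1 Expected number of differentially expressed genes (`< m`).
#' @param power Anticipated per-gene power in `(0, 1]`.
#' @return Per-test significance level alpha.
#' @export
fdr_alpha <- function(f, m, m1, power) {
  if (!(f > 0 && f < 1)) stop("f must lie in (0, 1)")
  if (!(m1 > 0 && m1 < m)) stop("need 0 < m1 < m")
  if (!(power > 0 && power <= 1)) stop("power must lie in (0, 1]")
  a <- f * m1 * power / ((m - m1) * (1 - f))
  min(max(a, .Machine$double.xmin), 1 - 1e-12)
}

#' A-priori power for a two-group negative-binomial RNA-seq design
#'
#' Wald-approximation power for detecting a fold change `rho` between two
#' groups of `n` samples each, for a gene with minimal average normalized
#' count `mu0` in the reference group and negative-binomial dispersion
#' `phi` (`Var = mu + phi mu^2`).  The variance of the log fold-change
#' estimate is `SE^2 = (1/n) * ((1/mu0 + phi) + (1/(rho*mu0) + phi))`.
#' The per-test alpha is tied to the FDR target through [fdr_alpha()], which
#' itself depends on power, so the (power, alpha) pair is iterated to a
#' fixed point (tolerance `1e-6`, at most 100 iterations).
#'
#' @param n_per_group Samples per group.
#' @param dispersion NB dispersion `phi` (use the maximum plausible value
#'   for a conservative answer).
#' @param fold_change Minimal fold change `rho > 0` to detect.
#' @param fdr_level Target FDR `f` in `(0, 1)`.
#' @param m Total tested genes.
#' @param m1 Expected DE genes.
#' @param mu0 Minimal average normalized count (default 10).
#' @param start Starting power for the iteration (default 0.8).
#' @return Converged power in `[0, 1]`, with attributes `alpha` and
#'   `iterations`.
#' @export
#' @examples
#' nb_power(65, 0.5, 2.82, 0.05, 17740, 1000)  # > 0.99
nb_power <- function(n_per_group, dispersion, fold_change, fdr_level,
                     m, m1, mu0 = 10, start = 0.8) {
  stopifnot(n_per_group > 0, dispersion >= 0, fold_change > 0, mu0 > 0,
            start > 0, start <= 1)
  se <- sqrt((1 / n_per_group) *
               ((1 / mu0 + dispersion) +
                  (1 / (fold_change * mu0) + dispersion)))
  delta <- log(fold_change)
  power <- start
  for (it in seq_len(100)) {
    alpha <- fdr_alpha(fdr_level, m, m1, power)
    z <- stats::qnorm(1 - alpha / 2)
    new_power <- stats::pnorm(delta / se - z) + stats::pnorm(-delta / se - z)
    if (abs(new_power - power) < 1e-6) {
      power <- new_power
      return(structure(power, alpha = alpha, iterations = it))
    }
    power <- new_power
  }
  stop("power iteration did not converge in 100 iterations")
}
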