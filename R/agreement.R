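#' Bland-Altman agreement between manual and automated densities
#'
#' Computes the mean difference (bias) of `automated - manual`, the 95%
#' limits of agreement `bias +/- 1.96 * sd(d)` with sample (n - 1) standard
#' deviation, the classic `1.96 * sd(d) * sqrt(3 / n)` confidence
#' half-width for each limit, and the ordinary least-squares slope of the
#' differences on the pair means — the oblique proportional-bias trend
#' line. Exact t-based limit CIs exist as an alternative formulation; the
#' classic large-sample form is used here.
#'
#' @param manual,automated equal-length numeric vectors of paired
#'   measurements (%), `n >= 2`.
#' @return A [BlandAltmanResult-class].
#' @examples
#' ba <- blandAltman(c(10, 20, 30), c(12, 19, 33))
#' bias(ba); limitsOfAgreement(ba)
#' @export
blandAltman <- function(manual, automated) {
    stopifnot(is.numeric(manual), is.numeric(automated))
    if (length(manual) != length(automated))
        stop("'manual' and 'automated' must have equal length")
    n <- length(manual)
    if (n < 2L) stop("at least 2 pairs are required")
    if (any(!is.finite(manual)) || any(!is.finite(automated)))
        stop("measurements must be finite")
    d <- automated - manual
    m <- (automated + manual) / 2
    b <- mean(d)
    s <- stats::sd(d)
    sxx <- sum((m - mean(m))^2)
    slope <- if (sxx > 0) sum((m - mean(m)) * (d - b)) / sxx else 0
    new("BlandAltmanResult", bias = b,
        loaLow = b - 1.96 * s, loaHigh = b + 1.96 * s,
        loaCiHalfwidth = 1.96 * s * sqrt(3 / n),
        slopeDiffVsMean = slope, n = as.integer(n))
}

#' Paired test for nonzero Bland-Altman bias
#'
#' One-sample two-sided t-test on the differences `automated - manual`.
#' Zero-variance differences are flagged degenerate: with zero bias the
#' p-value is 1 by the no-signal convention; with nonzero bias it is
#' reported as the smallest representable positive double.
#'
#' @inheritParams blandAltman
#' @return list with `bias`, `t` (statistic, `NA` when degenerate), `df`,
#'   `p`, `degenerate`.
#' @export
pairedBiasTest <- function(manual, automated) {
    stopifnot(is.numeric(manual), is.numeric(automated))
    if (length(manual) != length(automated))
        stop("'manual' and 'automated' must have equal length")
    n <- length(manual)
    if (n < 2L) stop("at least 2 pairs are required")
    d <- automated - manual
    b <- mean(d)
    if (stats::sd(d) == 0) {
        return(list(bias = b, t = NA_real_, df = n - 1L,
                    p = if (b == 0) 1 else .Machine$double.xmin,
                    degenerate = TRUE))
    }
    tt <- stats::t.test(d, mu = 0)
    list(bias = b, t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, degenerate = FALSE)
}
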