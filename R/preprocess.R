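# Reflective (half-sample symmetric) index mapping: ... c b a | a b c ... | c b a
.reflectIdx <- function(idx, n) {
    repeat {
        low <- idx < 1L
        if (any(low)) idx[low] <- 1L - idx[low]
        high <- idx > n
        if (any(high)) idx[high] <- 2L * n + 1L - idx[high]
        if (!any(idx < 1L | idx > n)) return(idx)
    }
}

.padReflect <- function(m, rRow, rCol) {
    ri <- .reflectIdx(seq.int(1L - rRow, nrow(m) + rRow), nrow(m))
    ci <- .reflectIdx(seq.int(1L - rCol, ncol(m) + rCol), ncol(m))
    m[ri, ci, drop = FALSE]
}

# Separable correlation with a symmetric 1-D kernel, reflective boundaries.
.convSep <- function(m, k) {
    r <- (length(k) - 1L) / 2L
    if (r == 0L) return(m * k)
    n <- nrow(m)
    p <- .padReflect(m, r, 0L)
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(k))
        out <- out + k[t] * p[t:(t + n - 1L), , drop = FALSE]
    m2 <- ncol(out)
    p <- .padReflect(out, 0L, r)
    out2 <- matrix(0, n, m2)
    for (t in seq_along(k))
        out2 <- out2 + k[t] * p[, t:(t + m2 - 1L), drop = FALSE]
    out2
}

.gaussKernel <- function(sigma) {
    r <- max(1L, as.integer(ceiling(4 * sigma)))
    x <- (-r):r
    k <- exp(-x^2 / (2 * sigma^2))
    k / sum(k)
}

#' Histogram equalization
#'
#' Maps intensities through the empirical cumulative distribution computed
#' on a `bins`-bin histogram over \[0, 1\]. The mapping is monotone
#' non-decreasing, so the rank order of distinct input intensities is
#' preserved; an already-uniform image is (up to one bin width) a fixed
#' point, and a constant image stays constant.
#'
#' @param img an [EnFaceImage-class] with intensities in \[0, 1\].
#' @param bins number of histogram bins (>= 2), default 256.
#' @return An [EnFaceImage-class] with equalized intensities in (0, 1\].
#' @export
equalizeHistogram <- function(img, bins = 256L) {
    stopifnot(is(img, "EnFaceImage"), bins >= 2L)
    x <- img@pixels
    idx <- pmin.int(floor(x * bins) + 1L, bins)
    cdf <- cumsum(tabulate(idx, nbins = bins)) / length(x)
    out <- x
    out[] <- cdf[idx]
    EnFaceImage(out, mmPerPx = img@mmPerPx)
}

#' Gaussian low-pass filter
#'
#' Separable Gaussian smoothing with reflective (half-sample symmetric)
#' boundary handling, which conserves the image mean. The kernel is
#' truncated at four standard deviations. `sigmaPx = 0` is the identity.
#'
#' @param img an [EnFaceImage-class].
#' @param sigmaPx Gaussian standard deviation in pixels (>= 0), default 2.
#' @return the smoothed [EnFaceImage-class].
#' @export
lowpass <- function(img, sigmaPx = 2) {
    stopifnot(is(img, "EnFaceImage"), sigmaPx >= 0)
    if (sigmaPx == 0) return(img)
    out <- .convSep(img@pixels, .gaussKernel(sigmaPx))
    # clamp fp droop so the result stays a valid [0,1] raster
    out[out < 0] <- 0
    out[out > 1] <- 1
    EnFaceImage(out, mmPerPx = img@mmPerPx)
}

#' Preprocess an en face image for shadow localization
#'
#' Histogram equalization followed by Gaussian low-pass filtering. The
#' preprocessed image feeds only the shadow-localization stage; capillary
#' segmentation runs on the original normalized image (equalization before
#' the Otsu stage would change the threshold semantics).
#'
#' @param img an [EnFaceImage-class].
#' @param equalizeBins histogram bins for equalization.
#' @param lowpassSigmaPx Gaussian sigma in pixels.
#' @return the preprocessed [EnFaceImage-class].
#' @seealso [shadowMask()]
#' @export
preprocessEnface <- function(img, equalizeBins = 256L, lowpassSigmaPx = 2) {
    lowpass(equalizeHistogram(img, equalizeBins), lowpassSigmaPx)
}
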