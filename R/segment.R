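#' Modified Otsu threshold with pixel exclusion (stage two)
#'
#' Otsu's method maximizes the between-class variance of a two-class split
#' of the intensity histogram. In the modified form used for parapapillary
#' capillary segmentation, pixels flagged in `exclude` — large-vessel
#' shadows and the device-black disc interior — are expurgated from the
#' histogram before the threshold is computed, so their (dark) intensities
#' cannot distort the background class.
#'
#' The histogram has `bins` equal-width bins on \[0, 1\] with pixel `x`
#' assigned to bin `floor(x * bins) + 1` (clamped at the top); bin `i` is
#' represented by its midpoint. Candidate thresholds are the interior bin
#' edges `i / bins`; ties are broken toward the lowest qualifying
#' threshold.
#'
#' @param img an [EnFaceImage-class] with intensities in \[0, 1\].
#' @param exclude logical matrix of pixels to leave out of the histogram
#'   (`TRUE` = excluded), or `NULL` for none.
#' @param bins number of histogram bins (default 256).
#' @return An [OtsuResult-class].
#' @section Errors:
#' Fewer than two distinct intensity values among non-excluded pixels is a
#' degenerate histogram and raises an error.
#' @seealso [capillaryMask()]
#' @export
modifiedOtsu <- function(img, exclude = NULL, bins = 256L) {
    stopifnot(is(img, "EnFaceImage"), bins >= 2L)
    bins <- as.integer(bins)
    x <- img@pixels
    if (!is.null(exclude)) {
        stopifnot(is.logical(exclude), identical(dim(exclude), dim(x)))
        x <- x[!exclude]
    }
    if (length(x) == 0L || length(unique(as.vector(x))) < 2L)
        stop("degenerate histogram: fewer than 2 distinct non-excluded ",
             "intensity values")
    idx <- pmin.int(floor(x * bins) + 1L, bins)
    p <- tabulate(idx, nbins = bins) / length(x)
    mid <- (seq_len(bins) - 0.5) / bins
    w0 <- cumsum(p)[-bins]
    m0 <- cumsum(p * mid)[-bins]
    mT <- sum(p * mid)
    vb <- ifelse(w0 > 0 & w0 < 1,
                 (mT * w0 - m0)^2 / (w0 * (1 - w0)),
                 -Inf)
    iStar <- which.max(vb)  # first maximum = lowest qualifying threshold
    new("OtsuResult", threshold = iStar / bins,
        betweenClassVariance = max(0, vb[iStar]),
        histogramBins = bins, nPixelsUsed = length(x))
}

#' Capillary mask (role C)
#'
#' Binarizes the original normalized image at the modified-Otsu threshold:
#' a pixel is capillary iff it is not excluded (not shadow, not disc) and
#' its intensity is strictly above the threshold — capillaries are the
#' bright, flow-positive class in en face OCT-A. Shadow pixels are never
#' capillary, so `C` and the shadow mask `U` are disjoint by construction.
#'
#' @param img the [EnFaceImage-class] the threshold was computed from.
#' @param otsu an [OtsuResult-class] from [modifiedOtsu()] on
#'   `(img, exclude)`.
#' @param exclude logical exclusion matrix used for the threshold (or
#'   `NULL`).
#' @return logical matrix, `TRUE` = capillary (the mask `C`).
#' @export
capillaryMask <- function(img, otsu, exclude = NULL) {
    stopifnot(is(img, "EnFaceImage"), is(otsu, "OtsuResult"))
    cmask <- img@pixels > otsu@threshold
    if (!is.null(exclude)) {
        stopifnot(is.logical(exclude),
                  identical(dim(exclude), dim(img@pixels)))
        cmask <- cmask & !exclude
    }
    cmask
}

#' Threshold transfer check between disc-centered and macular scans
#'
#' Advisory reliability check: computes the modified-Otsu threshold on a
#' macular en face image (no shadow exclusion) and on a disc-centered image
#' (shadow and disc exclusion from the standard pipeline) and reports both
#' together with their absolute difference. Comparable thresholds across
#' scan locations of the same device indicate the capillary/background
#' separation is a device property rather than an artifact of the disc
#' scan. No pass/fail is applied.
#'
#' @param maculaImg macular [EnFaceImage-class] (no disc, no exclusion).
#' @param discImg disc-centered [EnFaceImage-class]; its shadow mask and
#'   disc are recomputed with `config`.
#' @param bins histogram bins.
#' @param config a [ppcmvConfig()] list for the disc-image pipeline.
#' @return list with `thresholdMacula`, `thresholdDisc`, `delta`.
#' @export
checkThresholdTransfer <- function(maculaImg, discImg, bins = 256L,
                                   config = ppcmvConfig()) {
    tm <- modifiedOtsu(maculaImg, NULL, bins)
    pre <- preprocessEnface(discImg, config$preprocess$equalizeBins,
                            config$preprocess$lowpassSigmaPx)
    u <- shadowMask(pre, config$shadow$windowPx, config$shadow$k,
                    config$shadow$minObjectPx, config$shadow$dilatePx)
    # tolerate images without a device-marked disc (e.g. macular scans
    # passed on both sides): exclusion then reduces to the shadow mask
    disc <- tryCatch(detectDisc(discImg, config$roi$blackLevel,
                                config$roi$minDiscAreaMm2),
                     error = function(e) NULL)
    excl <- if (is.null(disc)) u
            else u | .discInteriorMask(disc, dim(discImg@pixels))
    td <- modifiedOtsu(discImg, excl, bins)
    list(thresholdMacula = tm@threshold, thresholdDisc = td@threshold,
         delta = abs(tm@threshold - td@threshold))
}
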