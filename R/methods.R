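#' @include AllClasses.R
NULL

#' @rdname ppcmv-accessors
#' @aliases pixels,EnFaceImage-method
#' @export
setMethod("pixels", "EnFaceImage", function(object) object@pixels)

#' @rdname ppcmv-accessors
#' @aliases mmPerPx,EnFaceImage-method
#' @export
setMethod("mmPerPx", "EnFaceImage", function(object) object@mmPerPx)

#' @rdname ppcmv-accessors
#' @aliases roiMasks,RoiSet-method
#' @export
setMethod("roiMasks", "RoiSet", function(object) object@masks)

#' @rdname ppcmv-accessors
#' @aliases roiTable,DensityReport-method
#' @export
setMethod("roiTable", "DensityReport", function(object) object@roi)

#' @rdname ppcmv-accessors
#' @aliases threshold,OtsuResult-method
#' @export
setMethod("threshold", "OtsuResult", function(object) object@threshold)

#' @rdname ppcmv-accessors
#' @aliases bias,BlandAltmanResult-method
#' @export
setMethod("bias", "BlandAltmanResult", function(object) object@bias)

#' @rdname ppcmv-accessors
#' @aliases limitsOfAgreement,BlandAltmanResult-method
#' @export
setMethod("limitsOfAgreement", "BlandAltmanResult",
          function(object) c(object@loaLow, object@loaHigh))

#' @describeIn EnFaceImage-class image dimensions (rows, columns).
#' @param x an `EnFaceImage`.
#' @export
setMethod("dim", "EnFaceImage", function(x) dim(x@pixels))

setMethod("show", "EnFaceImage", function(object) {
    d <- dim(object@pixels)
    cat(sprintf("EnFaceImage: %d x %d px, %.4f mm/px (%.2f x %.2f mm)\n",
                d[1], d[2], object@mmPerPx,
                d[1] * object@mmPerPx, d[2] * object@mmPerPx))
    cat(sprintf("  intensity range [%.3f, %.3f]\n",
                min(object@pixels), max(object@pixels)))
})

setMethod("show", "DiscCircle", function(object) {
    cat(sprintf(
        "DiscCircle: center (%.1f, %.1f) px, radius %.1f px = %.3f mm%s\n",
        object@centerX, object@centerY, object@radiusPx, object@radiusMm,
        if (object@lowConfidence) " [low confidence]" else ""))
})

setMethod("show", "RoiSet", function(object) {
    cat("RoiSet around ")
    show(object@disc)
    px <- vapply(object@masks, sum, numeric(1))
    cat(sprintf("  %s: %d px\n", names(px), px), sep = "")
    if (object@clipped) cat("  [clipped at image border]\n")
})

setMethod("show", "OtsuResult", function(object) {
    cat(sprintf(
        "OtsuResult: threshold %.4f (%d bins, %d px used, sigma_b^2 = %.4g)\n",
        object@threshold, object@histogramBins, object@nPixelsUsed,
        object@betweenClassVariance))
})

setMethod("show", "DensityReport", function(object) {
    cat(sprintf("DensityReport '%s' (disc radius %.3f mm)\n",
                object@imageId, object@discRadiusMm))
    print(object@roi, row.names = FALSE)
})

setMethod("show", "BlandAltmanResult", function(object) {
    cat(sprintf(
        "BlandAltmanResult (n = %d): bias %.3f%%, LoA [%.3f, %.3f]%%\n",
        object@n, object@bias, object@loaLow, object@loaHigh))
    cat(sprintf("  LoA CI half-width %.3f%%, slope(diff ~ mean) %.4f\n",
                object@loaCiHalfwidth, object@slopeDiffVsMean))
})
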