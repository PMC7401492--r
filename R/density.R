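#' PPCMv density within one region of interest (stage three)
#'
#' Density is the percentage of capillary pixels among the shadow-free
#' (evaluable) pixels of the region:
#' `100 * |C intersect roi| / |roi intersect complement(U)|`.
#' Shadow pixels are excluded from numerator and denominator alike; `C`
#' never overlaps `U` by construction, so the numerator needs no further
#' masking. An empty evaluable set yields a missing density with a warning
#' rather than an error.
#'
#' @param capillary logical capillary mask `C`.
#' @param shadow logical shadow mask `U`.
#' @param roi logical region-of-interest mask.
#' @param roiName label carried into the record.
#' @return one-row `data.frame` with `roi_name`, `density_pct` (NA when no
#'   evaluable pixel), `capillary_px`, `evaluable_px`, `shadow_px`,
#'   `total_roi_px`.
#' @examples
#' C <- matrix(FALSE, 4, 4); C[1, 1:2] <- TRUE
#' U <- matrix(FALSE, 4, 4); U[4, ] <- TRUE
#' roi <- matrix(TRUE, 4, 4)
#' ppcmvDensity(C, U, roi)  # 100 * 2 / 12
#' @export
ppcmvDensity <- function(capillary, shadow, roi, roiName = "roi") {
    stopifnot(is.logical(capillary), is.logical(shadow), is.logical(roi),
              identical(dim(capillary), dim(shadow)),
              identical(dim(capillary), dim(roi)))
    total <- sum(roi)
    shadowPx <- sum(roi & shadow)
    evaluable <- total - shadowPx
    capPx <- sum(capillary & roi & !shadow)
    density <- if (evaluable > 0L) 100 * capPx / evaluable else {
        warning("ROI '", roiName, "' has no evaluable pixel; density is NA")
        NA_real_
    }
    data.frame(roi_name = roiName, density_pct = density,
               capillary_px = capPx, evaluable_px = evaluable,
               shadow_px = shadowPx, total_roi_px = total,
               stringsAsFactors = FALSE)
}

#' Measure PPCMv density on one en face image
#'
#' Runs the full three-stage pipeline: preprocessing (equalization +
#' low-pass) feeding shadow localization; disc detection and ROI
#' construction; modified Otsu segmentation with the shadow mask and disc
#' interior expurgated from the histogram; and per-ROI density computation
#' for the inner/outer annuli and their superior/inferior hemifields. The
#' computation is deterministic for a fixed image and configuration.
#'
#' @param img an [EnFaceImage-class] (normalized; [readEnface()] output).
#' @param config configuration list from [ppcmvConfig()].
#' @param imageId identifier recorded in the report.
#' @param full when `TRUE` also return the intermediate masks and objects.
#' @return A [DensityReport-class]; with `full = TRUE`, a list with
#'   elements `report`, `shadow` (U), `capillary` (C), `exclude`,
#'   `rois`, `disc`, `otsu`, `preprocessed`.
#' @section Errors:
#' A disc-not-found error propagates; per-ROI degeneracies (no evaluable
#' pixel) downgrade to missing density values.
#' @export
measureImage <- function(img, config = ppcmvConfig(), imageId = "image",
                         full = FALSE) {
    stopifnot(is(img, "EnFaceImage"))
    pre <- preprocessEnface(img, config$preprocess$equalizeBins,
                            config$preprocess$lowpassSigmaPx)
    u <- shadowMask(pre, config$shadow$windowPx, config$shadow$k,
                    config$shadow$minObjectPx, config$shadow$dilatePx)
    disc <- detectDisc(img, config$roi$blackLevel, config$roi$minDiscAreaMm2)
    rois <- buildRois(disc, img)
    exclude <- u | .discInteriorMask(disc, dim(img@pixels))
    otsu <- modifiedOtsu(img, exclude, config$segment$bins)
    cmask <- capillaryMask(img, otsu, exclude)
    rows <- do.call(rbind, lapply(.ROI_NAMES, function(nm)
        ppcmvDensity(cmask, u, rois@masks[[nm]], nm)))
    report <- new("DensityReport", imageId = imageId, roi = rows,
                  discRadiusMm = disc@radiusMm, otsu = otsu)
    if (!full) return(report)
    list(report = report, shadow = u, capillary = cmask, exclude = exclude,
         rois = rois, disc = disc, otsu = otsu, preprocessed = pre)
}
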