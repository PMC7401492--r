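#' @include AllGenerics.R
NULL

#' En face OCT-A image with physical scale
#'
#' Container for a single-channel en face OCT angiography raster together
#' with its physical pixel pitch. Intensities are stored min-max normalized
#' to \[0, 1\]; the scale ties pixel geometry to millimetres so that annular
#' regions of interest can be expressed in physical units.
#'
#' Pixel coordinates are 0-based, row-major with the origin at the top-left
#' pixel center; all geometry in the package measures distances between
#' pixel centers.
#'
#' @slot pixels numeric matrix of intensities in \[0, 1\] (rows = image rows).
#' @slot mmPerPx positive scalar, millimetres per pixel.
#'
#' @seealso [readEnface()], [normalizeIntensity()]
#' @export
setClass("EnFaceImage",
    representation(pixels = "matrix", mmPerPx = "numeric"),
    validity = function(object) {
        msg <- NULL
        p <- object@pixels
        if (!is.numeric(p) || length(p) == 0L)
            msg <- c(msg, "'pixels' must be a non-empty numeric matrix")
        if (is.numeric(p) && length(p) > 0L) {
            rng <- range(p, finite = TRUE)
            if (!all(is.finite(p)))
                msg <- c(msg, "'pixels' must be finite")
            else if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
                msg <- c(msg, "'pixels' must lie in [0, 1]")
        }
        if (length(object@mmPerPx) != 1L || !is.finite(object@mmPerPx) ||
                object@mmPerPx <= 0)
            msg <- c(msg, "'mmPerPx' must be a single positive number")
        if (is.null(msg)) TRUE else msg
    })

#' Construct an EnFaceImage
#'
#' @param pixels numeric matrix of intensities; values outside \[0, 1\] are
#'   rejected (use [normalizeIntensity()] first for raw data).
#' @param mmPerPx millimetres per pixel. If `NULL`, derived as
#'   `scanWidthMm / ncol(pixels)`.
#' @param scanWidthMm physical scan width in mm (default 4.5, the
#'   disc-centered protocol width); used only when `mmPerPx` is `NULL`.
#' @return An [EnFaceImage-class] object.
#' @examples
#' img <- EnFaceImage(matrix(runif(64), 8, 8), scanWidthMm = 4.5)
#' mmPerPx(img) * ncol(pixels(img))  # ~4.5 mm
#' @export
EnFaceImage <- function(pixels, mmPerPx = NULL, scanWidthMm = 4.5) {
    if (is.null(mmPerPx)) {
        stopifnot(is.numeric(scanWidthMm), length(scanWidthMm) == 1L,
                  scanWidthMm > 0)
        mmPerPx <- scanWidthMm / ncol(pixels)
    }
    new("EnFaceImage", pixels = pixels, mmPerPx = as.numeric(mmPerPx))
}

#' Optic disc circle
#'
#' Circle circumscribed around the device-marked (black) optic disc region:
#' the minimum enclosing circle of the detected black component. Coordinates
#' are 0-based pixel-center coordinates (x = column, y = row).
#'
#' @slot centerX,centerY circle center in pixel coordinates.
#' @slot radiusPx radius in pixels.
#' @slot radiusMm radius in millimetres (`radiusPx * mmPerPx`).
#' @slot lowConfidence `TRUE` when the disc component touches the image
#'   border, or when the circle expanded by the 1.0-mm outer annulus margin
#'   does not fit inside the image.
#'
#' @seealso [detectDisc()]
#' @export
setClass("DiscCircle",
    representation(centerX = "numeric", centerY = "numeric",
                   radiusPx = "numeric", radiusMm = "numeric",
                   lowConfidence = "logical"),
    validity = function(object) {
        msg <- NULL
        for (s in c("centerX", "centerY", "radiusPx", "radiusMm"))
            if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
                msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
        if (length(object@radiusPx) == 1L && is.finite(object@radiusPx) &&
                object@radiusPx <= 0)
            msg <- c(msg, "'radiusPx' must be positive")
        if (length(object@radiusMm) == 1L && is.finite(object@radiusMm) &&
                object@radiusMm <= 0)
            msg <- c(msg, "'radiusMm' must be positive")
        if (length(object@lowConfidence) != 1L)
            msg <- c(msg, "'lowConfidence' must be a single logical")
        if (is.null(msg)) TRUE else msg
    })

#' @rdname DiscCircle-class
#' @param centerX,centerY,radiusPx see slots.
#' @param mmPerPx physical scale used to derive `radiusMm`.
#' @param lowConfidence see slots.
#' @export
DiscCircle <- function(centerX, centerY, radiusPx, mmPerPx,
                       lowConfidence = FALSE) {
    new("DiscCircle", centerX = as.numeric(centerX),
        centerY = as.numeric(centerY), radiusPx = as.numeric(radiusPx),
        radiusMm = as.numeric(radiusPx * mmPerPx),
        lowConfidence = isTRUE(lowConfidence))
}

.ROI_NAMES <- c("inner_annulus", "inner_sup", "inner_inf",
                "outer_annulus", "outer_sup", "outer_inf")

#' Annular regions of interest around the optic disc
#'
#' The inner annulus spans disc radius to disc radius + 0.5 mm, the outer
#' annulus disc radius + 0.5 mm to disc radius + 1.0 mm (the three
#' concentric circles have diameters equal to, 1 mm greater and 2 mm greater
#' than the disc-circumscribing circle). Each annulus is split into superior
#' and inferior hemifields by the horizontal line through the disc center;
#' pixels exactly on the line are superior. Membership is half-open in
#' radius (`r_low < r <= r_high`) so the annuli partition without double
#' counting and exclude the disc interior.
#'
#' @slot disc the [DiscCircle-class] the set is built around.
#' @slot masks named list of six logical matrices:
#'   `inner_annulus`, `inner_sup`, `inner_inf`,
#'   `outer_annulus`, `outer_sup`, `outer_inf`.
#' @slot clipped `TRUE` when the outer circle extends beyond the image and
#'   the masks are truncated at the border.
#'
#' @seealso [buildRois()]
#' @export
setClass("RoiSet",
    representation(disc = "DiscCircle", masks = "list", clipped = "logical"),
    validity = function(object) {
        msg <- NULL
        if (!identical(sort(names(object@masks)), sort(.ROI_NAMES)))
            msg <- c(msg, sprintf("masks must be named %s",
                                  paste(.ROI_NAMES, collapse = ", ")))
        else {
            dims <- unique(lapply(object@masks, dim))
            if (length(dims) != 1L)
                msg <- c(msg, "all masks must share one shape")
            if (!all(vapply(object@masks, is.logical, logical(1))))
                msg <- c(msg, "masks must be logical matrices")
            m <- object@masks
            if (is.null(msg)) {
                if (any(m$inner_sup & m$inner_inf) ||
                        any(m$outer_sup & m$outer_inf))
                    msg <- c(msg, "hemifields must be disjoint")
                if (!identical(m$inner_sup | m$inner_inf, m$inner_annulus) ||
                        !identical(m$outer_sup | m$outer_inf, m$outer_annulus))
                    msg <- c(msg, "hemifields must partition their annulus")
                if (any(m$inner_annulus & m$outer_annulus))
                    msg <- c(msg, "annuli must be disjoint")
            }
        }
        if (length(object@clipped) != 1L)
            msg <- c(msg, "'clipped' must be a single logical")
        if (is.null(msg)) TRUE else msg
    })

#' Modified-Otsu threshold result
#'
#' Result of Otsu's between-class-variance maximization computed on the
#' histogram of evaluable pixels only (shadow and disc pixels excluded).
#' The threshold lies at a bin upper edge `i / histogramBins`; ties are
#' broken toward the lowest qualifying threshold.
#'
#' @slot threshold scalar in \[0, 1\].
#' @slot betweenClassVariance between-class variance attained at the
#'   threshold.
#' @slot histogramBins number of histogram bins over \[0, 1\].
#' @slot nPixelsUsed number of pixels entering the histogram
#'   (non-excluded).
#'
#' @seealso [modifiedOtsu()]
#' @export
setClass("OtsuResult",
    representation(threshold = "numeric", betweenClassVariance = "numeric",
                   histogramBins = "integer", nPixelsUsed = "integer"),
    validity = function(object) {
        msg <- NULL
        if (length(object@threshold) != 1L || object@threshold < 0 ||
                object@threshold > 1)
            msg <- c(msg, "'threshold' must be a scalar in [0, 1]")
        if (length(object@betweenClassVariance) != 1L ||
                object@betweenClassVariance < 0)
            msg <- c(msg, "'betweenClassVariance' must be non-negative")
        if (object@histogramBins < 1L)
            msg <- c(msg, "'histogramBins' must be positive")
        if (object@nPixelsUsed < 0L)
            msg <- c(msg, "'nPixelsUsed' must be non-negative")
        if (is.null(msg)) TRUE else msg
    })

#' Per-image PPCMv density report
#'
#' One row per region of interest with the density percentage and the pixel
#' accounting behind it. `density_pct` is `NA` (missing, not zero) for
#' regions with no evaluable pixel. Invariants:
#' `capillary_px <= evaluable_px` and
#' `evaluable_px + shadow_px == total_roi_px`.
#'
#' @slot imageId image identifier.
#' @slot roi `data.frame` with columns `roi_name`, `density_pct`,
#'   `capillary_px`, `evaluable_px`, `shadow_px`, `total_roi_px`.
#' @slot discRadiusMm radius (mm) of the disc-circumscribing circle.
#' @slot otsu the [OtsuResult-class] used for segmentation.
#'
#' @seealso [measureImage()], [writeDensityCsv()]
#' @export
setClass("DensityReport",
    representation(imageId = "character", roi = "data.frame",
                   discRadiusMm = "numeric", otsu = "OtsuResult"),
    validity = function(object) {
        msg <- NULL
        need <- c("roi_name", "density_pct", "capillary_px", "evaluable_px",
                  "shadow_px", "total_roi_px")
        if (!all(need %in% names(object@roi)))
            msg <- c(msg, sprintf("roi table must have columns %s",
                                  paste(need, collapse = ", ")))
        else {
            r <- object@roi
            if (any(r$capillary_px > r$evaluable_px))
                msg <- c(msg, "capillary_px must not exceed evaluable_px")
            if (any(r$evaluable_px + r$shadow_px != r$total_roi_px))
                msg <- c(msg, "evaluable_px + shadow_px must equal total_roi_px")
            d <- r$density_pct
            if (any(!is.na(d) & (d < 0 | d > 100)))
                msg <- c(msg, "density_pct must lie in [0, 100] or be NA")
        }
        if (length(object@imageId) != 1L)
            msg <- c(msg, "'imageId' must be a single string")
        if (is.null(msg)) TRUE else msg
    })

#' Bland-Altman agreement result
#'
#' Agreement between two paired measurement methods: mean difference
#' (bias), 95% limits of agreement `bias +/- 1.96 * sd(differences)`
#' (sample sd, n - 1 denominator), the classic `1.96 * sd * sqrt(3/n)`
#' confidence half-width for each limit, and the least-squares slope of the
#' differences on the pair means (proportional-bias trend, advisory).
#' Differences are taken as `automated - manual`.
#'
#' @slot bias mean difference (%).
#' @slot loaLow,loaHigh 95% limits of agreement (%).
#' @slot loaCiHalfwidth 95% CI half-width of each limit (%).
#' @slot slopeDiffVsMean slope of differences vs. means.
#' @slot n number of pairs.
#'
#' @seealso [blandAltman()], [pairedBiasTest()]
#' @export
setClass("BlandAltmanResult",
    representation(bias = "numeric", loaLow = "numeric", loaHigh = "numeric",
                   loaCiHalfwidth = "numeric", slopeDiffVsMean = "numeric",
                   n = "integer"),
    validity = function(object) {
        msg <- NULL
        if (object@n < 2L) msg <- c(msg, "'n' must be >= 2")
        if (!(object@loaLow <= object@bias && object@bias <= object@loaHigh))
            msg <- c(msg, "limits of agreement must bracket the bias")
        if (is.null(msg)) TRUE else msg
    })
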