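#' Min-max normalize an intensity raster to \[0, 1\]
#'
#' Zero-dynamic-range rasters (all pixels equal) normalize to all-zero
#' rather than erroring, so blank or failed scans propagate as empty
#' capillary masks downstream. Normalization is idempotent on rasters
#' already spanning \[0, 1\].
#'
#' @param m numeric matrix.
#' @return numeric matrix in \[0, 1\].
#' @export
normalizeIntensity <- function(m) {
    stopifnot(is.matrix(m), is.numeric(m), length(m) > 0L, all(is.finite(m)))
    rng <- range(m)
    if (rng[2] - rng[1] <= 0) {
        m[] <- 0
        return(m)
    }
    (m - rng[1]) / (rng[2] - rng[1])
}

.readRaster <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    a <- switch(ext,
        png = png::readPNG(path),
        tif = , tiff = tiff::readTIFF(path),
        stop("unsupported image format '", ext, "' (use PNG or TIFF): ", path))
    if (length(dim(a)) == 3L) {
        nc <- dim(a)[3]
        # grayscale-as-RGB: channels must agree; alpha channel is ignored
        ch <- min(nc, 3L)
        if (ch > 1L) {
            for (i in 2:ch)
                if (max(abs(a[, , i] - a[, , 1])) > 0)
                    stop("multi-channel image with non-identical channels: ",
                         path)
        }
        a <- a[, , 1]
    }
    a
}

#' Read an en face OCT-A image
#'
#' Reads an 8- or 16-bit grayscale PNG/TIFF (or an RGB image whose channels
#' are identical), min-max normalizes intensities to \[0, 1\] and attaches
#' the physical scale `mmPerPx = scanWidthMm / width_px`.
#'
#' @param path image file path.
#' @param scanWidthMm physical width of the scan in mm (default 4.5, the
#'   disc-centered scan protocol).
#' @return An [EnFaceImage-class].
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(64), 8, 8), f)
#' readEnface(f)
#' @export
readEnface <- function(path, scanWidthMm = 4.5) {
    a <- .readRaster(path)
    EnFaceImage(normalizeIntensity(a), scanWidthMm = scanWidthMm)
}

#' Read and write binary masks as bilevel PNG
#'
#' Masks use 0 for background and 255 for foreground; reading thresholds at
#' 0.5 so a written mask round-trips bit-exactly.
#'
#' @param path PNG file path.
#' @return `readMask()`: a logical matrix.
#' @export
readMask <- function(path) {
    .readRaster(path) > 0.5
}

#' @rdname readMask
#' @param mask logical matrix (`TRUE` = foreground).
#' @return `writeMask()`: the path, invisibly.
#' @export
writeMask <- function(mask, path) {
    stopifnot(is.matrix(mask), is.logical(mask))
    png::writePNG(mask * 1, path)
    invisible(path)
}

#' Write density reports to CSV
#'
#' One row per image per region of interest, grouped by image in input
#' order, with columns `image_id`, `roi_name`, `density_pct`,
#' `capillary_px`, `evaluable_px`, `shadow_px`, `disc_radius_mm`.
#' A missing density (no evaluable pixel) is written as an empty field,
#' never as 0.
#'
#' @param reports a [DensityReport-class] or a list of them.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @seealso [measureImage()]
#' @export
writeDensityCsv <- function(reports, path) {
    if (is(reports, "DensityReport")) reports <- list(reports)
    stopifnot(length(reports) > 0L,
              all(vapply(reports, is, logical(1), "DensityReport")))
    rows <- lapply(reports, function(rep) {
        r <- rep@roi
        data.frame(
            image_id = rep@imageId,
            roi_name = r$roi_name,
            density_pct = ifelse(is.na(r$density_pct), "",
                                 sprintf("%.10g", r$density_pct)),
            capillary_px = r$capillary_px,
            evaluable_px = r$evaluable_px,
            shadow_px = r$shadow_px,
            disc_radius_mm = sprintf("%.10g", rep@discRadiusMm),
            stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(tab, con, sep = ",", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    invisible(path)
}
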