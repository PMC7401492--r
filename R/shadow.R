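# Windowed sums by offset accumulation on a reflect-padded matrix.
.boxSum <- function(m, r) {
    n <- nrow(m)
    p <- .padReflect(m, r, 0L)
    out <- matrix(0, n, ncol(m))
    for (t in seq_len(2L * r + 1L))
        out <- out + p[t:(t + n - 1L), , drop = FALSE]
    m2 <- ncol(out)
    p <- .padReflect(out, 0L, r)
    out2 <- matrix(0, n, m2)
    for (t in seq_len(2L * r + 1L))
        out2 <- out2 + p[, t:(t + m2 - 1L), drop = FALSE]
    out2
}

#' Local first-order statistics
#'
#' Per-pixel mean and standard deviation over a square window centered at
#' each pixel, with reflective boundary handling. The standard deviation is
#' the population form (window-size denominator).
#'
#' @param img an [EnFaceImage-class].
#' @param windowPx odd window side length, `>= 3` and at most the smaller
#'   image dimension.
#' @return list with numeric matrices `mean` and `sd`.
#' @seealso [shadowMask()]
#' @export
localStats <- function(img, windowPx) {
    stopifnot(is(img, "EnFaceImage"))
    windowPx <- as.integer(windowPx)
    if (windowPx < 3L || windowPx %% 2L == 0L)
        stop("'windowPx' must be odd and >= 3")
    x <- img@pixels
    if (windowPx > min(dim(x)))
        stop("'windowPx' exceeds the image dimensions")
    r <- (windowPx - 1L) %/% 2L
    nw <- windowPx^2
    mu <- .boxSum(x, r) / nw
    v <- .boxSum(x * x, r) / nw - mu * mu
    v[v < 0] <- 0
    list(mean = mu, sd = sqrt(v))
}

#' Large retinal-vessel shadow mask (stage one)
#'
#' Niblack-style locally adaptive thresholding: pixel `p` is shadow iff
#' `img[p] < mean_w(p) - k * sd_w(p)` (strict, so ties are non-shadow and a
#' constant image yields an empty mask at `k = 0`). Connected components
#' (4-connected) smaller than `minObjectPx` are then removed — enforcing
#' that only large retinal-vessel shadows survive — and the result is
#' dilated by a disc-shaped structuring element of radius `dilatePx` as a
#' partial-volume safety margin. Cleanup order is fixed: size filter first,
#' then dilation, so dilation cannot rescue sub-threshold specks.
#'
#' The mask is built from the preprocessed image (see
#' [preprocessEnface()]); it may overlap the disc region — ROI geometry
#' handles the disc separately.
#'
#' @param imgPre the preprocessed [EnFaceImage-class].
#' @param windowPx odd local-window side length (default 25).
#' @param k offset multiplier on the local standard deviation (default
#'   0.9).
#' @param minObjectPx minimum connected-component size retained (default
#'   50).
#' @param dilatePx dilation radius in pixels (default 1).
#' @return logical matrix, `TRUE` = shadow (the mask `U`).
#' @export
shadowMask <- function(imgPre, windowPx = 25L, k = 0.9, minObjectPx = 50L,
                       dilatePx = 1L) {
    stopifnot(is(imgPre, "EnFaceImage"), minObjectPx >= 0L, dilatePx >= 0L)
    s <- localStats(imgPre, windowPx)
    u <- imgPre@pixels < s$mean - k * s$sd
    u <- .filterSmallComponents(u, minObjectPx)
    .dilateMask(u, dilatePx)
}

.filterSmallComponents <- function(mask, minPx) {
    if (minPx <= 1L || !any(mask)) return(mask)
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask * 1))))
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= minPx)
    t(matrix(lab %in% keep, nrow = nrow(lab), ncol = ncol(lab)))
}

.dilateMask <- function(mask, radiusPx) {
    if (radiusPx <= 0L || !any(mask)) return(mask)
    brush <- EBImage::makeBrush(2L * as.integer(radiusPx) + 1L, shape = "disc")
    out <- EBImage::imageData(
        EBImage::dilate(EBImage::Image(t(mask * 1)), brush))
    t(out > 0.5)
}
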