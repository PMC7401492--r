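# Squared distance of every pixel center (0-based) to (cx, cy).
.pixelDist <- function(dims, cx, cy) {
    dy <- (seq_len(dims[1]) - 1) - cy
    dx <- (seq_len(dims[2]) - 1) - cx
    sqrt(outer(dy^2, dx^2, "+"))
}

.discInteriorMask <- function(disc, dims) {
    .pixelDist(dims, disc@centerX, disc@centerY) <= disc@radiusPx
}

# Minimum enclosing circle of 2-D points (Welzl, on the convex hull, with a
# deterministic stride permutation standing in for random shuffling).
.minEnclosingCircle <- function(pts) {
    stopifnot(ncol(pts) == 2L, nrow(pts) >= 1L)
    if (nrow(pts) == 1L)
        return(list(cx = pts[1, 1], cy = pts[1, 2], r = 0))
    if (nrow(pts) > 3L) {
        h <- grDevices::chull(pts)
        pts <- pts[h, , drop = FALSE]
    }
    n <- nrow(pts)
    if (n > 2L) {
        ord <- order((seq_len(n) * 0.6180339887498949) %% 1)
        pts <- pts[ord, , drop = FALSE]
    }
    eps <- 1e-9
    inC <- function(c, p) (p[1] - c$cx)^2 + (p[2] - c$cy)^2 <= c$r2 + eps
    circ2 <- function(a, b) {
        cx <- (a[1] + b[1]) / 2; cy <- (a[2] + b[2]) / 2
        list(cx = cx, cy = cy, r2 = (a[1] - cx)^2 + (a[2] - cy)^2)
    }
    circ3 <- function(a, b, c) {
        d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                  c[1] * (a[2] - b[2]))
        if (abs(d) < 1e-12) {
            # collinear: fall back to the farthest pair
            cands <- list(circ2(a, b), circ2(a, c), circ2(b, c))
            return(cands[[which.max(vapply(cands, `[[`, 0, "r2"))]])
        }
        ux <- ((a[1]^2 + a[2]^2) * (b[2] - c[2]) +
               (b[1]^2 + b[2]^2) * (c[2] - a[2]) +
               (c[1]^2 + c[2]^2) * (a[2] - b[2])) / d
        uy <- ((a[1]^2 + a[2]^2) * (c[1] - b[1]) +
               (b[1]^2 + b[2]^2) * (a[1] - c[1]) +
               (c[1]^2 + c[2]^2) * (b[1] - a[1])) / d
        list(cx = ux, cy = uy, r2 = (a[1] - ux)^2 + (a[2] - uy)^2)
    }
    cc <- circ2(pts[1, ], pts[2, ])
    if (n > 2L) for (i in 3:n) {
        if (inC(cc, pts[i, ])) next
        cc <- circ2(pts[i, ], pts[1, ])
        if (i > 2L) for (j in 2:(i - 1L)) {
            if (inC(cc, pts[j, ])) next
            cc <- circ2(pts[i, ], pts[j, ])
            if (j > 1L) for (k in seq_len(j - 1L)) {
                if (inC(cc, pts[k, ])) next
                cc <- circ3(pts[i, ], pts[j, ], pts[k, ])
            }
        }
    }
    list(cx = cc$cx, cy = cc$cy, r = sqrt(cc$r2))
}

#' Detect the device-marked optic disc
#'
#' The disc is rendered as a black region in the device's en face export.
#' Detection takes the connected components (4-connected) of pixels with
#' intensity `<= blackLevel`, discards components smaller than
#' `minDiscAreaMm2`, selects the qualifying component whose centroid is
#' nearest the image center, and circumscribes it with its minimum
#' enclosing circle — guaranteeing the disc is wholly excluded from the
#' annuli built around it. Detection is invariant to intensity changes
#' strictly above `blackLevel`.
#'
#' The result is flagged low-confidence when the component touches the
#' image border or the circle grown by the 1.0-mm outer annulus margin
#' leaves the image.
#'
#' @param img normalized [EnFaceImage-class].
#' @param blackLevel intensity at or below which a pixel counts as black
#'   (default 0.02: the device marking is pure black, the margin absorbs
#'   quantization).
#' @param minDiscAreaMm2 minimum black-component area in mm^2 (default 0.8;
#'   a typical disc is >= 1 mm^2), which rejects specks and dark noise.
#' @return A [DiscCircle-class].
#' @section Errors:
#' No qualifying component raises a disc-not-found error.
#' @export
detectDisc <- function(img, blackLevel = 0.02, minDiscAreaMm2 = 0.8) {
    stopifnot(is(img, "EnFaceImage"), blackLevel >= 0, blackLevel <= 1,
              minDiscAreaMm2 > 0)
    x <- img@pixels
    bw <- x <= blackLevel
    if (!any(bw)) stop("disc not found: no pixel at or below blackLevel")
    lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(bw * 1)))))
    sizes <- tabulate(lab[lab > 0L])
    minPx <- minDiscAreaMm2 / img@mmPerPx^2
    cand <- which(sizes >= minPx)
    if (length(cand) == 0L)
        stop("disc not found: no black component of at least ",
             format(minDiscAreaMm2), " mm^2")
    dims <- dim(x)
    cx0 <- (dims[2] - 1) / 2
    cy0 <- (dims[1] - 1) / 2
    pick <- cand[which.min(vapply(cand, function(l) {
        w <- which(lab == l, arr.ind = TRUE)
        (mean(w[, 2]) - 1 - cx0)^2 + (mean(w[, 1]) - 1 - cy0)^2
    }, numeric(1)))]
    w <- which(lab == pick, arr.ind = TRUE)
    touches <- any(w[, 1] == 1L | w[, 1] == dims[1] |
                   w[, 2] == 1L | w[, 2] == dims[2])
    mec <- .minEnclosingCircle(cbind(w[, 2] - 1, w[, 1] - 1))  # (x, y)
    marginPx <- mec$r + 1.0 / img@mmPerPx
    fits <- mec$cx - marginPx >= -0.5 && mec$cx + marginPx <= dims[2] - 0.5 &&
            mec$cy - marginPx >= -0.5 && mec$cy + marginPx <= dims[1] - 0.5
    DiscCircle(mec$cx, mec$cy, mec$r, img@mmPerPx,
               lowConfidence = touches || !fits)
}

#' Build annular regions of interest around the disc
#'
#' Overlays three concentric circles on the image: the disc-circumscribing
#' circle and circles with diameters 1 mm and 2 mm greater, giving an inner
#' and an outer annulus each 0.5 mm wide. Each annulus is split into its
#' superior and inferior hemifields by the horizontal line through the disc
#' center (rows at or above the center row are superior). Radial membership
#' is half-open (`r_low < r <= r_high`) over pixel-center distances, so the
#' annuli partition cleanly and exclude the disc interior.
#'
#' @param disc a [DiscCircle-class].
#' @param img the [EnFaceImage-class] supplying shape and scale.
#' @return An [RoiSet-class]; `clipped` is `TRUE` (with a warning) when the
#'   outer circle extends past the image border and the masks are truncated
#'   there.
#' @export
buildRois <- function(disc, img) {
    stopifnot(is(disc, "DiscCircle"), is(img, "EnFaceImage"))
    dims <- dim(img@pixels)
    halfMmPx <- 0.5 / img@mmPerPx
    r0 <- disc@radiusPx
    r1 <- r0 + halfMmPx
    r2 <- r0 + 2 * halfMmPx
    d <- .pixelDist(dims, disc@centerX, disc@centerY)
    inner <- d > r0 & d <= r1
    outer <- d > r1 & d <= r2
    sup <- matrix((seq_len(dims[1]) - 1) <= disc@centerY,
                  dims[1], dims[2])
    clipped <- disc@centerX - r2 < -0.5 || disc@centerX + r2 > dims[2] - 0.5 ||
               disc@centerY - r2 < -0.5 || disc@centerY + r2 > dims[1] - 0.5
    if (clipped)
        warning("outer annulus extends beyond the image; masks are clipped")
    new("RoiSet", disc = disc,
        masks = list(inner_annulus = inner,
                     inner_sup = inner & sup, inner_inf = inner & !sup,
                     outer_annulus = outer,
                     outer_sup = outer & sup, outer_inf = outer & !sup),
        clipped = clipped)
}
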