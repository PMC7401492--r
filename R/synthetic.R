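# Run expr with a temporarily seeded RNG, restoring the caller's stream.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

#' Synthetic en face image configuration
#'
#' Study-condition defaults emulate a 304 x 304 px, 4.5 x 4.5 mm
#' disc-centered choriocapillaris scan: a bright capillary texture with a
#' controlled fill fraction (0.25, the scale of a healthy inner-annulus
#' density), dark branching retinal-vessel shadows 0.06-0.20 mm wide
#' attenuating intensity by 80%, a device-black disc of 0.75 mm radius,
#' additive Gaussian noise (sd 0.04) and a mild linear illumination ramp.
#' `discRadiusMm = 0` generates a macular-like field with no disc.
#'
#' @param sizePx image side length in pixels.
#' @param scanWidthMm physical scan width (mm).
#' @param discRadiusMm disc radius (mm); 0 for no disc. Must satisfy
#'   `discRadiusMm + 1.0 < scanWidthMm / 2` so the annuli fit.
#' @param discCenterOffsetMm disc center offset from image center, (x, y)
#'   in mm.
#' @param capillaryFill fraction of choroid (non-disc) pixels that are
#'   capillary, in (0, 1).
#' @param capillaryBlobSigmaPx correlation length (px) of the capillary
#'   texture.
#' @param nShadowVessels number of shadow vessel trees.
#' @param shadowWidthMmRange min/max shadow vessel width (mm).
#' @param shadowDepth relative intensity attenuation inside shadows,
#'   in (0, 1\].
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param illuminationGradient relative amplitude of the left-right linear
#'   illumination ramp.
#' @param seed integer seed; generation is bit-reproducible per seed.
#' @return validated configuration list.
#' @seealso [synthEnface()]
#' @export
syntheticConfig <- function(sizePx = 304L, scanWidthMm = 4.5,
                            discRadiusMm = 0.75,
                            discCenterOffsetMm = c(0, 0),
                            capillaryFill = 0.25,
                            capillaryBlobSigmaPx = 1.5,
                            nShadowVessels = 8L,
                            shadowWidthMmRange = c(0.06, 0.2),
                            shadowDepth = 0.8, noiseSd = 0.04,
                            illuminationGradient = 0.1, seed = 1L) {
    cfg <- list(sizePx = as.integer(sizePx), scanWidthMm = scanWidthMm,
                discRadiusMm = discRadiusMm,
                discCenterOffsetMm = discCenterOffsetMm,
                capillaryFill = capillaryFill,
                capillaryBlobSigmaPx = capillaryBlobSigmaPx,
                nShadowVessels = as.integer(nShadowVessels),
                shadowWidthMmRange = shadowWidthMmRange,
                shadowDepth = shadowDepth, noiseSd = noiseSd,
                illuminationGradient = illuminationGradient,
                seed = as.integer(seed))
    stopifnot(cfg$sizePx >= 16L, cfg$scanWidthMm > 0, cfg$discRadiusMm >= 0,
              length(cfg$discCenterOffsetMm) == 2L,
              cfg$capillaryFill > 0, cfg$capillaryFill < 1,
              cfg$capillaryBlobSigmaPx > 0, cfg$nShadowVessels >= 0L,
              length(cfg$shadowWidthMmRange) == 2L,
              all(cfg$shadowWidthMmRange > 0),
              diff(cfg$shadowWidthMmRange) >= 0,
              cfg$shadowDepth > 0, cfg$shadowDepth <= 1, cfg$noiseSd >= 0)
    if (cfg$discRadiusMm + 1.0 >= cfg$scanWidthMm / 2)
        stop("annuli do not fit: need discRadiusMm + 1.0 < scanWidthMm / 2")
    cfg
}

# Stamp a filled disc of radius rad (px) at 0-based center (x, y).
.stamp <- function(mask, x, y, rad) {
    n1 <- nrow(mask); n2 <- ncol(mask)
    r <- max(rad, 0.5)
    i0 <- max(1L, floor(y - r) + 1L); i1 <- min(n1, ceiling(y + r) + 1L)
    j0 <- max(1L, floor(x - r) + 1L); j1 <- min(n2, ceiling(x + r) + 1L)
    if (i0 > i1 || j0 > j1) return(mask)
    ii <- i0:i1; jj <- j0:j1
    sub <- outer((ii - 1) - y, (jj - 1) - x,
                 function(a, b) a^2 + b^2) <= r^2
    mask[ii, jj] <- mask[ii, jj] | sub
    mask
}

# Branching random-walk shadow trees radiating from startRadius.
.shadowTrees <- function(n, nVessels, cx, cy, startRadius, radRangePx) {
    mask <- matrix(FALSE, n, n)
    if (nVessels == 0L) return(mask)
    for (v in seq_len(nVessels)) {
        th <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, radRangePx[1], radRangePx[2])
        stack <- list(list(x = cx + startRadius * cos(th),
                           y = cy + startRadius * sin(th),
                           dir = th + stats::rnorm(1, 0, 0.2),
                           rad = rad, depth = 0L))
        while (length(stack) > 0L) {
            w <- stack[[length(stack)]]
            stack[[length(stack)]] <- NULL
            for (s in seq_len(400L)) {
                if (w$x < 0 || w$x > n - 1 || w$y < 0 || w$y > n - 1) break
                mask <- .stamp(mask, w$x, w$y, w$rad)
                w$x <- w$x + 1.5 * cos(w$dir)
                w$y <- w$y + 1.5 * sin(w$dir)
                # persistent, gently meandering course: vessels radiate
                # outward and leave the field rather than curling back
                w$dir <- w$dir + stats::rnorm(1, 0, 0.06)
                if (w$depth < 2L && stats::runif(1) < 0.015)
                    stack[[length(stack) + 1L]] <-
                        list(x = w$x, y = w$y,
                             dir = w$dir + sample(c(-1, 1), 1) *
                                 stats::runif(1, 0.4, 0.9),
                             rad = w$rad * 0.7, depth = w$depth + 1L)
            }
        }
    }
    mask
}

#' Generate a synthetic en face OCT-A image with ground truth
#'
#' Composes, deterministically for a fixed seed: a capillary mask from a
#' Gaussian random field thresholded at the `1 - capillaryFill` quantile of
#' its non-disc pixels (exact fill control with realistic spatial
#' correlation); bright capillary / dark background intensities; branching
#' random-walk shadow trees multiplying intensity by `1 - shadowDepth`;
#' additive Gaussian noise; a linear illumination ramp; and finally the
#' device-black disc overlay. Ground-truth per-ROI densities are computed
#' from the generator's own masks by the same pixel counting as
#' [ppcmvDensity()], so the generator is its own oracle.
#'
#' @param cfg configuration from [syntheticConfig()].
#' @return list with `image` (an [EnFaceImage-class]) and `truth`, a list
#'   holding `disc` ([DiscCircle-class] or `NULL`), `shadowMask`,
#'   `capillaryMask`, `densities` (named vector over the six ROIs, `NULL`
#'   when there is no disc) and `capillaryFill`.
#' @examples
#' g <- synthEnface(syntheticConfig(sizePx = 128L, seed = 7L))
#' g$truth$densities
#' @export
synthEnface <- function(cfg = syntheticConfig()) {
    .withSeed(cfg$seed, {
        n <- cfg$sizePx
        mmpp <- cfg$scanWidthMm / n
        cx <- (n - 1) / 2 + cfg$discCenterOffsetMm[1] / mmpp
        cy <- (n - 1) / 2 + cfg$discCenterOffsetMm[2] / mmpp
        rpx <- cfg$discRadiusMm / mmpp
        discM <- if (rpx > 0) .pixelDist(c(n, n), cx, cy) <= rpx
                 else matrix(FALSE, n, n)
        f <- .convSep(matrix(stats::rnorm(n * n), n, n),
                      .gaussKernel(cfg$capillaryBlobSigmaPx))
        q <- stats::quantile(f[!discM], 1 - cfg$capillaryFill, names = FALSE)
        capM <- f > q & !discM
        shadowM <- .shadowTrees(n, cfg$nShadowVessels, cx, cy,
                                startRadius = if (rpx > 0) rpx else 0.05 * n,
                                radRangePx = cfg$shadowWidthMmRange /
                                    (2 * mmpp))
        img <- 0.30 + 0.55 * capM
        img[shadowM] <- img[shadowM] * (1 - cfg$shadowDepth)
        if (cfg$noiseSd > 0)
            img <- img + matrix(stats::rnorm(n * n, 0, cfg$noiseSd), n, n)
        ramp <- (seq_len(n) - 1) / (n - 1) - 0.5
        img <- img * (1 + cfg$illuminationGradient *
                          matrix(ramp, n, n, byrow = TRUE))
        img[img < 0] <- 0
        img[img > 1] <- 1
        img[discM] <- 0  # device-black disc overlay on the final export
        image <- EnFaceImage(img, mmPerPx = mmpp)
        disc <- if (rpx > 0) DiscCircle(cx, cy, rpx, mmpp) else NULL
        densities <- NULL
        if (!is.null(disc)) {
            rois <- buildRois(disc, image)
            rows <- do.call(rbind, lapply(.ROI_NAMES, function(nm)
                ppcmvDensity(capM, shadowM, rois@masks[[nm]], nm)))
            densities <- stats::setNames(rows$density_pct, rows$roi_name)
        }
        list(image = image,
             truth = list(disc = disc, shadowMask = shadowM,
                          capillaryMask = capM, densities = densities,
                          capillaryFill = cfg$capillaryFill))
    })
}

#' Generate a cohort of synthetic eyes
#'
#' Per-eye capillary fill fractions are drawn from a normal profile
#' distribution truncated to (0.02, 0.98); each eye then gets its own
#' derived seed, so the whole cohort is reproducible from one seed.
#'
#' @param nEyes number of eyes.
#' @param profile list with `mean` and `sd` of the capillary fill fraction
#'   (both on the 0-1 scale, mean in (0, 1)); e.g. mean 0.25 for a
#'   control-like group or 0.16 for a glaucoma-like group.
#' @param seed integer cohort seed.
#' @param config base [syntheticConfig()]; its `capillaryFill` and `seed`
#'   are replaced per eye.
#' @return list of [synthEnface()] results, length `nEyes`.
#' @export
synthCohort <- function(nEyes, profile = list(mean = 0.25, sd = 0.07),
                        seed = 1L, config = syntheticConfig()) {
    stopifnot(nEyes >= 1L, is.list(profile),
              all(c("mean", "sd") %in% names(profile)),
              profile$mean > 0, profile$mean < 1, profile$sd >= 0)
    draws <- .withSeed(seed, {
        fills <- numeric(nEyes)
        for (i in seq_len(nEyes)) {
            repeat {
                v <- stats::rnorm(1, profile$mean, profile$sd)
                if (v > 0.02 && v < 0.98) break
            }
            fills[i] <- v
        }
        list(fills = fills, seeds = sample.int(99999999L, nEyes))
    })
    lapply(seq_len(nEyes), function(i) {
        cfg <- config
        cfg$capillaryFill <- draws$fills[i]
        cfg$seed <- draws$seeds[i]
        synthEnface(cfg)
    })
}
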