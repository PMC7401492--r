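test_that("disc detection recovers generator geometry within a pixel", {
    for (off in list(c(0, 0), c(0.3, -0.2))) {
        g <- synthEnface(syntheticConfig(sizePx = 304L,
                                         discCenterOffsetMm = off,
                                         seed = 81L))
        disc <- detectDisc(g$image)
        truth <- g$truth$disc
        expect_lt(abs(disc@centerX - truth@centerX), 1)
        expect_lt(abs(disc@centerY - truth@centerY), 1)
        expect_lt(abs(disc@radiusPx - truth@radiusPx), 1)
        expect_equal(disc@radiusMm, disc@radiusPx * mmPerPx(g$image))
        expect_false(disc@lowConfidence)
    }
})

test_that("small black specks are ignored and an all-bright image errors", {
    n <- 304L
    m <- matrix(0.8, n, n)
    d <- ppcmv:::.pixelDist(c(n, n), 151.5, 151.5)
    m[d <= 40] <- 0
    m[20, 20] <- 0  # 1-px speck far from center
    img <- EnFaceImage(m, scanWidthMm = 4.5)
    disc <- detectDisc(img)
    expect_lt(abs(disc@radiusPx - 40), 1)
    expect_lt(abs(disc@centerX - 151.5), 1)

    expect_error(detectDisc(EnFaceImage(matrix(0.8, 64, 64))), "disc not found")
})

test_that("disc detection ignores intensity changes strictly above the black level", {
    g <- synthEnface(syntheticConfig(sizePx = 200L, seed = 83L))
    d1 <- detectDisc(g$image)
    m <- pixels(g$image)
    above <- m > 0.02
    m[above] <- pmin(1, m[above] * 0.9 + 0.1)
    d2 <- detectDisc(EnFaceImage(m, mmPerPx = mmPerPx(g$image)))
    expect_equal(d1@centerX, d2@centerX)
    expect_equal(d1@centerY, d2@centerY)
    expect_equal(d1@radiusPx, d2@radiusPx)
})

test_that("annulus areas match the analytic ring area within discretization", {
    n <- 304L
    mmpp <- 4.5 / n
    img <- EnFaceImage(matrix(0.5, n, n), mmPerPx = mmpp)
    disc <- DiscCircle((n - 1) / 2, (n - 1) / 2, 0.75 / mmpp, mmpp)
    rois <- buildRois(disc, img)
    innerAnalytic <- pi * (1.25^2 - 0.75^2)
    outerAnalytic <- pi * (1.75^2 - 1.25^2)
    expect_equal(sum(roiMasks(rois)$inner_annulus) * mmpp^2, innerAnalytic,
                 tolerance = 0.02)
    expect_equal(sum(roiMasks(rois)$outer_annulus) * mmpp^2, outerAnalytic,
                 tolerance = 0.02)
})

test_that("hemifields partition each annulus exactly and are symmetric at a centered disc", {
    n <- 304L
    mmpp <- 4.5 / n
    img <- EnFaceImage(matrix(0.5, n, n), mmPerPx = mmpp)
    disc <- DiscCircle((n - 1) / 2, (n - 1) / 2, 0.75 / mmpp, mmpp)
    m <- roiMasks(buildRois(disc, img))
    expect_identical(m$inner_sup | m$inner_inf, m$inner_annulus)
    expect_false(any(m$inner_sup & m$inner_inf))
    expect_equal(sum(m$inner_sup) + sum(m$inner_inf), sum(m$inner_annulus))
    expect_equal(sum(m$outer_sup) + sum(m$outer_inf), sum(m$outer_annulus))
    # centered disc between pixel rows: halves are exactly equal
    expect_equal(sum(m$inner_sup), sum(m$inner_inf))
    expect_equal(sum(m$outer_sup), sum(m$outer_inf))
    # annuli nest without overlap and exclude the disc interior
    expect_false(any(m$inner_annulus & m$outer_annulus))
    discM <- ppcmv:::.discInteriorMask(disc, c(n, n))
    expect_false(any(discM & (m$inner_annulus | m$outer_annulus)))
})

test_that("pixel-counted annulus area converges to the analytic area with resolution", {
    errs <- vapply(c(152L, 304L, 608L), function(n) {
        mmpp <- 4.5 / n
        img <- EnFaceImage(matrix(0.5, n, n), mmPerPx = mmpp)
        disc <- DiscCircle((n - 1) / 2, (n - 1) / 2, 0.75 / mmpp, mmpp)
        a <- sum(roiMasks(buildRois(disc, img))$inner_annulus) * mmpp^2
        abs(a / (pi * (1.25^2 - 0.75^2)) - 1)
    }, numeric(1))
    expect_true(all(diff(errs) < 0))
    expect_lt(errs[3], 0.005)
})

test_that("an outer circle leaving the image clips the masks and flags the set", {
    n <- 120L
    mmpp <- 4.5 / 304
    img <- EnFaceImage(matrix(0.5, n, n), mmPerPx = mmpp)
    disc <- DiscCircle((n - 1) / 2, (n - 1) / 2, 0.75 / mmpp, mmpp)
    expect_warning(rois <- buildRois(disc, img), "clipped")
    expect_true(rois@clipped)
})
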