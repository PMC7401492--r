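test_that("modified Otsu separates a two-valued population with pure classes", {
    m <- matrix(0.8, 10, 10)
    m[1:40] <- 0.2
    otsu <- modifiedOtsu(asEnface(m), NULL, bins = 256L)
    expect_gt(threshold(otsu), 0.2)
    expect_lt(threshold(otsu), 0.8)
    cm <- capillaryMask(asEnface(m), otsu)
    expect_identical(cm, m > 0.5)
    expect_equal(otsu@nPixelsUsed, 100L)
    # threshold sits on a bin edge
    expect_equal(threshold(otsu) * 256, round(threshold(otsu) * 256))
})

test_that("excluded pixels have no effect on the threshold", {
    m <- matrix(0.1, 8, 8)
    m[, 5:8] <- 0.3
    bright <- matrix(FALSE, 8, 8)
    bright[1:2, ] <- TRUE
    m[bright] <- 0.9
    otsu <- modifiedOtsu(asEnface(m), bright, bins = 256L)
    expect_gt(threshold(otsu), 0.1)
    expect_lte(threshold(otsu), 0.3)
    # altering intensities only at excluded pixels changes nothing
    m2 <- m
    m2[bright] <- runif(sum(bright))
    # keep the raster valid and the exclusion identical
    otsu2 <- modifiedOtsu(asEnface(m2), bright, bins = 256L)
    expect_identical(threshold(otsu2), threshold(otsu))
    expect_identical(capillaryMask(asEnface(m2), otsu2, bright),
                     capillaryMask(asEnface(m), otsu, bright))
})

test_that("with no exclusion the modified Otsu reduces to the standard scan", {
    set.seed(51)
    for (i in 1:5) {
        x <- matrix(runif(30 * 30), 30, 30)
        otsu <- modifiedOtsu(asEnface(x), NULL, bins = 128L)
        expect_identical(threshold(otsu),
                         oracleOtsuThreshold(as.vector(x), 128L))
    }
})

test_that("degenerate histograms raise an explicit error", {
    expect_error(modifiedOtsu(asEnface(matrix(0.5, 4, 4))), "degenerate")
    m <- matrix(0.2, 4, 4)
    m[1, ] <- 0.9
    excl <- matrix(FALSE, 4, 4)
    excl[1, ] <- TRUE  # excluding the bright row leaves one value
    expect_error(modifiedOtsu(asEnface(m), excl), "degenerate")
})

test_that("capillary mask uses a strict threshold and never includes excluded pixels", {
    m <- matrix(runif(64, 0.6, 1), 8, 8)
    excl <- matrix(FALSE, 8, 8)
    excl[1:2, 1:2] <- TRUE
    low <- new("OtsuResult", threshold = 0.5, betweenClassVariance = 0.1,
               histogramBins = 256L, nPixelsUsed = 60L)
    expect_identical(capillaryMask(asEnface(m), low, excl), !excl)

    high <- new("OtsuResult", threshold = max(m), betweenClassVariance = 0.1,
                histogramBins = 256L, nPixelsUsed = 60L)
    expect_false(any(capillaryMask(asEnface(m), high, excl)))
})

test_that("Otsu recovers the generator's bright fill fraction on bimodal images", {
    g <- synthEnface(syntheticConfig(sizePx = 304L, capillaryFill = 0.3,
                                     nShadowVessels = 0L, noiseSd = 0,
                                     illuminationGradient = 0, seed = 61L))
    disc <- detectDisc(g$image)
    excl <- ppcmv:::.discInteriorMask(disc, dim(pixels(g$image)))
    otsu <- modifiedOtsu(g$image, excl)
    cm <- capillaryMask(g$image, otsu, excl)
    expect_equal(sum(cm) / sum(!excl), 0.30, tolerance = 0.02 / 0.30)
})

test_that("the capillary threshold transfers between macular and disc-centered textures", {
    # identical shadow-free, disc-free textures give identical thresholds
    mac <- synthEnface(syntheticConfig(sizePx = 200L, discRadiusMm = 0,
                                       nShadowVessels = 0L, seed = 71L))
    tr <- checkThresholdTransfer(mac$image, mac$image)
    expect_equal(tr$delta, 0)

    # draws from the same texture distribution stay within 0.05
    deltas <- vapply(1:10, function(s) {
        mac <- synthEnface(syntheticConfig(sizePx = 200L, discRadiusMm = 0,
                                           nShadowVessels = 0L,
                                           seed = 100L + s))
        eye <- synthEnface(syntheticConfig(sizePx = 200L, seed = 200L + s))
        checkThresholdTransfer(mac$image, eye$image)$delta
    }, numeric(1))
    expect_lt(max(deltas), 0.05)

    # a constant image on either side is a degenerate histogram
    expect_error(
        checkThresholdTransfer(asEnface(matrix(0.5, 64, 64)), mac$image),
        "degenerate")
})

test_that("between-class variance at the returned threshold dominates every other split", {
    set.seed(53)
    x <- matrix(runif(400), 20, 20)
    bins <- 64L
    otsu <- modifiedOtsu(asEnface(x), NULL, bins)
    vals <- as.vector(x)
    mids <- (seq_len(bins) - 0.5) / bins
    counts <- tabulate(pmin(floor(vals * bins) + 1L, bins), bins)
    p <- counts / length(vals)
    for (i in seq_len(bins - 1L)) {
        w0 <- sum(p[1:i])
        if (w0 <= 0 || w0 >= 1) next
        m0 <- sum(p[1:i] * mids[1:i]) / w0
        m1 <- sum(p[(i + 1):bins] * mids[(i + 1):bins]) / (1 - w0)
        expect_lte(w0 * (1 - w0) * (m0 - m1)^2,
                   otsu@betweenClassVariance + 1e-12)
    }
})
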