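# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the vectorized/cumulative code paths of the
# package: explicit loops, direct summation, no separable tricks.

# Exhaustive Otsu scan: per-pixel histogram fill, direct summation of class
# weights and means at every interior bin edge, first (lowest) maximum wins.
oracleOtsuThreshold <- function(values, bins) {
    counts <- numeric(bins)
    for (v in values) {
        i <- min(floor(v * bins) + 1, bins)
        counts[i] <- counts[i] + 1
    }
    p <- counts / length(values)
    mid <- (seq_len(bins) - 0.5) / bins
    best <- -Inf
    bestI <- NA_integer_
    for (i in seq_len(bins - 1)) {
        w0 <- sum(p[1:i])
        w1 <- 1 - w0
        if (w0 <= 0 || w1 <= 0) next
        m0 <- sum(p[1:i] * mid[1:i]) / w0
        m1 <- sum(p[(i + 1):bins] * mid[(i + 1):bins]) / w1
        vb <- w0 * w1 * (m0 - m1)^2
        if (vb > best) {
            best <- vb
            bestI <- i
        }
    }
    bestI / bins
}

.oracleReflect <- function(i, n) {
    while (i < 1 || i > n) {
        if (i < 1) i <- 1 - i
        if (i > n) i <- 2 * n + 1 - i
    }
    i
}

# Direct window summation (no separability), half-sample reflective edges.
oracleLocalStats <- function(x, w) {
    r <- (w - 1) / 2
    n <- nrow(x)
    m <- ncol(x)
    mu <- sdv <- matrix(0, n, m)
    for (i in seq_len(n)) for (j in seq_len(m)) {
        vals <- numeric(w * w)
        t <- 0L
        for (di in -r:r) for (dj in -r:r) {
            t <- t + 1L
            vals[t] <- x[.oracleReflect(i + di, n), .oracleReflect(j + dj, m)]
        }
        mu[i, j] <- mean(vals)
        sdv[i, j] <- sqrt(mean((vals - mean(vals))^2))
    }
    list(mean = mu, sd = sdv)
}

# Eq.-1 counting by explicit pixel loop.
oracleDensity <- function(C, U, roi) {
    cap <- ev <- sh <- tot <- 0L
    for (i in seq_len(nrow(C))) for (j in seq_len(ncol(C))) {
        if (!roi[i, j]) next
        tot <- tot + 1L
        if (U[i, j]) {
            sh <- sh + 1L
        } else {
            ev <- ev + 1L
            if (C[i, j]) cap <- cap + 1L
        }
    }
    list(density = if (ev > 0L) 100 * cap / ev else NA_real_,
         capillary = cap, evaluable = ev, shadow = sh, total = tot)
}

# Convenience: wrap a matrix as an EnFaceImage at the 4.5-mm protocol scale.
asEnface <- function(m, scanWidthMm = 4.5) {
    EnFaceImage(m, scanWidthMm = scanWidthMm)
}
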