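test_that("bootstrap difference test behaves at the degenerate extremes", {
    set.seed(1)
    az <- matrix(0.5 + rnorm(40 * 20, 0, 0.05), 40, 20)
    # identical conditions: zero difference, nothing significant
    bs <- bootstrapAzDifference(az, az, nBoot = 200, seed = 1)
    expect_true(all(bs$medianDiff == 0))
    expect_false(any(bs$significant))
    # constant +0.05 shift: everything significant
    bs2 <- bootstrapAzDifference(az, az + 0.05, nBoot = 200, seed = 1)
    expect_true(all(abs(bs2$medianDiff - 0.05) < 1e-12))
    expect_true(all(bs2$significant))
    expect_error(bootstrapAzDifference(az[1:3, ], az[1:3, ], nBoot = 200),
                 "5 participants")
    expect_error(bootstrapAzDifference(az, az, nBoot = 50), "at least 100")
})

test_that("bootstrap and permutation routines are seed-reproducible and participant-exchangeable", {
    set.seed(2)
    azV <- matrix(0.5 + rnorm(12 * 30, 0, 0.05), 12, 30)
    azAV <- azV + matrix(rnorm(12 * 30, 0.02, 0.05), 12, 30)
    b1 <- bootstrapAzDifference(azV, azAV, nBoot = 200, seed = 7)
    b2 <- bootstrapAzDifference(azV, azAV, nBoot = 200, seed = 7)
    expect_identical(b1, b2)
    # participant exchangeability: permuting participant order changes only
    # which rows the resampler picks, so outputs agree within Monte-Carlo
    # error at large bootstrap counts
    p <- sample(12)
    b1L <- bootstrapAzDifference(azV, azAV, nBoot = 4000, seed = 7)
    b3L <- bootstrapAzDifference(azV[p, ], azAV[p, ], nBoot = 4000,
                                 seed = 7)
    expect_lt(max(abs(b3L$medianDiff - b1L$medianDiff)), 0.02)
    expect_lt(max(abs(b3L$ciLow - b1L$ciLow)), 0.03)
    m1 <- minClusterSizeNull(azV, azAV, nPerm = 100, seed = 3, nBoot = 100)
    m2 <- minClusterSizeNull(azV, azAV, nPerm = 100, seed = 3, nBoot = 100)
    expect_identical(m1, m2)
})

test_that("minimum cluster size follows the exceedance definition", {
    set.seed(5)
    azV <- matrix(rnorm(40 * 40, 0, 0.05), 40, 40)
    azAV <- matrix(rnorm(40 * 40, 0, 0.05), 40, 40)
    m <- minClusterSizeNull(azV, azAV, nPerm = 100, seed = 1, nBoot = 100)
    # smallest m with null exceedance probability <= 5%
    expect_true(mean(m$null >= m$minClusterSize) <= 0.05)
    expect_true(m$minClusterSize == 1 ||
                mean(m$null >= m$minClusterSize - 1) > 0.05)
    # quantile 0 -> floor of 1
    m0 <- minClusterSizeNull(azV, azAV, nPerm = 100, quantile = 0,
                             seed = 1, nBoot = 100)
    expect_equal(m0$minClusterSize, 1L)
})

test_that("cluster finding equals a brute-force run-length scan", {
    expect_equal(findSignificantClusters(c(0, 1, 1, 1, 0), 3),
                 cbind(start = 2, end = 4))
    expect_equal(nrow(findSignificantClusters(c(1, 1, 0, 1, 1), 3)), 0)
    bruteForce <- function(sig, k) {
        out <- NULL
        i <- 1
        while (i <= length(sig)) {
            if (sig[i]) {
                j <- i
                while (j < length(sig) && sig[j + 1]) j <- j + 1
                if (j - i + 1 >= k) out <- rbind(out, c(i, j))
                i <- j + 1
            } else i <- i + 1
        }
        if (is.null(out)) matrix(numeric(0), 0, 2) else out
    }
    set.seed(9)
    for (rep in 1:1000) {
        sig <- runif(sample(5:40, 1)) < 0.4
        k <- sample(1:4, 1)
        got <- findSignificantClusters(sig, k)
        want <- bruteForce(sig, k)
        dimnames(got) <- NULL
        expect_equal(got, want)
    }
})

test_that("participant consistency counts sign agreement with the group mean", {
    azV <- matrix(0.5, 4, 1)
    expect_equal(participantConsistency(azV, azV + 0.1), 1.0)
    d <- matrix(c(0.1, 0.1, -0.1, 0.1), 4, 1)          # +,+,-,+; mean +
    expect_equal(participantConsistency(azV, azV + d), 0.75)
    d2 <- matrix(c(0.3, 0.3, -0.1, -0.1), 4, 1)        # split 2/2, mean +
    expect_equal(participantConsistency(matrix(0.5, 4, 1),
                                        matrix(0.5, 4, 1) + d2), 0.5)
})

test_that("percentage-bend correlation matches the frozen reference and resists outliers", {
    x <- c(0.8, 1.6, 2.1, 3.0, 3.9, 4.6, 5.2, 6.1, 7.0, 7.7, 8.4, 9.1)
    y <- c(1.1, 1.9, 2.4, 3.4, 4.1, 5.0, 5.7, 6.3, 7.4, 8.0, 8.9, 30.0)
    res <- percentileBendCorrelation(x, y, bend = 0.2)
    # frozen from an independently coded reference implementation
    expect_equal(res$r, 0.99925645388873297, tolerance = 1e-10)
    expect_equal(res$p, 1.787523757796577e-15, tolerance = 1e-3)
    # closer to the outlier-free Pearson r than the contaminated one
    rClean <- cor(x[-12], y[-12])
    rDirty <- cor(x, y)
    expect_lt(abs(res$r - rClean), abs(res$r - rDirty))
    # exact linear relations
    expect_equal(percentileBendCorrelation(x, x)$r, 1)
    expect_equal(percentileBendCorrelation(x, -x)$r, -1)
    expect_error(percentileBendCorrelation(rep(1, 12), y), "zero robust")
})

test_that("ex-Gaussian density reaches the Gaussian limit as tau -> 0", {
    x <- seq(-4, 4, by = 0.01)
    expect_lt(max(abs(dexgauss(x, 0, 1, 1e-6) - dnorm(x))), 1e-6)
    # density integrates to ~1 for a generic parameter set
    expect_equal(integrate(dexgauss, -Inf, Inf, mu = 0.3, sigma = 0.4,
                           tau = 0.6)$value, 1, tolerance = 1e-6)
})

test_that("ex-Gaussian mixture BIC distinguishes unimodal from bimodal RTs", {
    rexg <- function(n, mu, sigma, tau) rnorm(n, mu, sigma) + rexp(n, 1 / tau)
    oneWins <- 0; twoWins <- 0
    nSeeds <- 10
    for (s in 1:nSeeds) {
        set.seed(s)
        x1 <- scale(rexg(1000, 0, 1, 0.8))
        oneWins <- oneWins +
            (fitExGaussianMixtureBIC(x1, seed = s)$bestK == 1)
        x2 <- scale(c(rexg(500, 0, 1, 0.5), rexg(500, 6, 1, 0.5)))
        twoWins <- twoWins +
            (fitExGaussianMixtureBIC(x2, seed = s)$bestK == 2)
    }
    expect_gte(oneWins / nSeeds, 0.9)
    expect_gte(twoWins / nSeeds, 0.9)
})
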