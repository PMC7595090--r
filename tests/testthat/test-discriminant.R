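test_that("window enumeration matches the sliding-window convention", {
    stim <- slidingWindowConfig(range = c(-0.100, 1.000))
    resp <- slidingWindowConfig(range = c(-0.600, 0.500))
    expect_equal(nrow(enumerateWindows(stim, 1000)), 111)
    expect_equal(nrow(enumerateWindows(resp, 1000)), 111)
    w <- enumerateWindows(stim, 1000, t0 = -0.2, nSamples = 1500)
    expect_true(all(w$last - w$first + 1 == 60))
    # trimming and full-outside handling
    ws <- capture_warnings(
        enumerateWindows(slidingWindowConfig(range = c(-0.1, 0.5)), 100,
                         t0 = -0.1, nSamples = 40))
    expect_true(any(grepl("trimmed", ws)))
    expect_error(
        enumerateWindows(slidingWindowConfig(range = c(2, 3)), 100,
                         t0 = 0, nSamples = 50), "outside")
})

test_that("window discriminator finds informative channels with the face-positive convention", {
    set.seed(1)
    n <- 40
    labels <- rep(c(TRUE, FALSE), n / 2)
    x <- cbind(ifelse(labels, 1, -1) + rnorm(n, 0, 0.3), rnorm(n, 0, 0.3))
    fit <- fitWindowDiscriminator(x, labels)
    expect_gt(abs(fit$w[1]), 5 * abs(fit$w[2]))
    expect_gt(fit$w[1], 0)                       # face -> positive y
    # label antisymmetry
    fit2 <- fitWindowDiscriminator(x, !labels)
    expect_equal(fit2$w, -fit$w, tolerance = 1e-6)
    expect_error(fitWindowDiscriminator(x, rep(TRUE, n)), "both classes")
})

test_that("in-sample ordering matches an unpenalized reference logistic fit", {
    set.seed(7)
    n <- 20
    labels <- rep(c(TRUE, FALSE), n / 2)
    x <- matrix(rnorm(n * 3), n, 3) + outer(ifelse(labels, 0.8, -0.8),
                                            c(1, 0.5, 0))
    fit <- fitWindowDiscriminator(x, labels, l2 = 1e-8)
    ref <- glm(labels ~ x, family = binomial())
    yOurs <- drop(x %*% fit$w)
    yRef <- drop(x %*% coef(ref)[-1])
    expect_identical(order(yOurs), order(yRef))
})

test_that("Az equals the normalized Mann-Whitney statistic and the trapezoid ROC area", {
    set.seed(3)
    for (i in 1:25) {
        n1 <- sample(5:20, 1); n0 <- sample(5:20, 1)
        y <- rnorm(n1 + n0)
        labels <- c(rep(TRUE, n1), rep(FALSE, n0))
        # Mann-Whitney pairwise-comparison counting oracle
        U <- sum(outer(y[labels], y[!labels],
                       function(a, b) (a > b) + 0.5 * (a == b)))
        expect_equal(rocArea(y, labels), U / (n1 * n0), tolerance = 1e-12)
        # trapezoidal ROC area on tie-free amplitudes
        th <- c(Inf, sort(unique(y), decreasing = TRUE), -Inf)
        tpr <- vapply(th, function(t) mean(y[labels] >= t), 0)
        fpr <- vapply(th, function(t) mean(y[!labels] >= t), 0)
        trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
        expect_equal(rocArea(y, labels), trap, tolerance = 1e-12)
    }
})

test_that("leave-one-out predictions never use the held-out trial", {
    truth <- smallTruth(nChannels = 4)
    tab <- smallSession(truth, nTrials = 16)
    ep <- smallEpochs(tab, truth)
    cfg <- slidingWindowConfig(range = c(0.5, 0.52), step = 0.04)
    labels <- tab$category == "face"
    m <- looAz(ep, labels, cfg = cfg)
    # each held-out amplitude equals the projection through a fit that
    # never saw that trial (penalized logistic is convex, so the refit is
    # init-independent)
    win <- enumerateWindows(cfg, samplingRate(ep), ep@t0,
                            dim(epochsData(ep))[3])
    xw <- epochsData(ep)[, , win$first[1]:win$last[1], drop = FALSE]
    for (i in c(3, 11)) {
        fit <- fitWindowDiscriminator(xw[-i, , , drop = FALSE], labels[-i])
        xi <- matrix(xw[i, , ], nrow = dim(xw)[2])
        expect_equal(trialAmplitudes(m)[i, 1],
                     mean(colSums(xi * fit$w)), tolerance = 1e-6)
    }
    # corrupting the held-out trial's data moves its own prediction
    ep2 <- ep
    ep2@data[7, , ] <- ep2@data[7, , ] + 50
    m2 <- looAz(ep2, labels, cfg = cfg)
    expect_gt(abs(trialAmplitudes(m2)[7, 1] - trialAmplitudes(m)[7, 1]),
              1e-3)
})

test_that("forward model obeys the rank-one identity, homogeneity and hand arithmetic", {
    set.seed(11)
    aTrue <- c(1.5, -0.7, 0.3)
    y <- rnorm(12)
    x <- outer(y, aTrue)                         # exact rank-one data
    expect_equal(forwardModel(x, y), aTrue, tolerance = 1e-12)
    expect_equal(forwardModel(x, 3 * y), aTrue / 3, tolerance = 1e-12)
    # 3-channel, 5-trial fixture against elementwise hand computation
    x5 <- matrix(c(1, 2, 0, -1, 3,
                   0, 1, 1,  2, -1,
                   2, 0, 1,  1,  1), 5, 3)
    y5 <- c(0.5, -1, 2, 1.5, -0.5)
    expect_equal(forwardModel(x5, y5),
                 as.numeric(t(x5) %*% y5 / sum(y5^2)), tolerance = 1e-14)
    expect_error(forwardModel(x5, rep(1, 5)), "zero variance")
})

test_that("peak latency uses the earliest-time tie rule", {
    centers <- seq(0.1, 0.5, by = 0.1)
    expect_equal(extractPeakLatency(1:5, centers, c(0.1, 0.5)), 0.5)
    expect_equal(extractPeakLatency(c(1, 2, 5, 2, 1), centers, c(0.1, 0.5)),
                 0.3)
    expect_equal(extractPeakLatency(rep(1, 5), centers, c(0.1, 0.5)), 0.1)
    expect_equal(extractPeakLatency(1:5, centers, c(0.15, 0.45)), 0.4)
    expect_error(extractPeakLatency(1:5, centers, c(0.6, 0.7)), "no window")
})

test_that("permutation threshold is the upper quantile of the pooled null and exceeds 0.5", {
    truth <- smallTruth(nChannels = 4)
    tab <- smallSession(truth, nTrials = 16)
    ep <- smallEpochs(tab, truth)
    cfg <- slidingWindowConfig(range = c(0.25, 0.29), step = 0.04)
    res <- permutationThreshold(ep, tab$category == "face", cfg = cfg,
                                nPerm = 100, seed = 2)
    expect_equal(res$azSig, unname(quantile(res$null, 0.95)))
    expect_gt(res$azSig, 0.5)
    expect_error(permutationThreshold(ep, tab$category == "face",
                                      cfg = cfg, nPerm = 50), "at least 100")
})

test_that("degenerate-projection null quantile approaches the analytic Mann-Whitney bound", {
    # identity projection: fixed amplitudes, labels randomized
    set.seed(4)
    n1 <- 150; n0 <- 150
    y <- rnorm(n1 + n0)
    null <- replicate(2000, {
        labs <- sample(c(rep(TRUE, n1), rep(FALSE, n0)))
        rocArea(y, labs)
    })
    analytic <- 0.5 + qnorm(0.95) * sqrt((n1 + n0 + 1) / (12 * n1 * n0))
    expect_equal(unname(quantile(null, 0.95)), analytic, tolerance = 0.015)
})

test_that("component-amplitude extraction selects peak windows and keeps the sign convention", {
    truth <- smallTruth(nChannels = 4, noiseSD = 0)
    tab <- smallSession(truth, nTrials = 16)
    ep <- smallEpochs(tab, truth)
    cfg <- slidingWindowConfig(range = c(0.2, 0.56), step = 0.04)
    labels <- tab$category == "face"
    mV <- looAz(ep, labels, cfg = cfg, condition = "V")
    mAV <- mV
    # zero extension with a one-window selection returns that window's y
    amp <- suppressWarnings(extractComponentAmplitudes(
        mV, mAV, earlyRange = c(0.18, 0.36), lateRange = c(0.48, 0.52),
        extension = 0))
    centers <- windowCenters(mV)
    tE <- extractPeakLatency(azTimecourse(mV), centers, c(0.18, 0.36))
    expect_equal(amp$V@yEarly,
                 trialAmplitudes(mV)[, which(centers == tE)])
    # noiseless data: early amplitude sign matches the category
    expect_true(all(sign(amp$V@yEarly) == ifelse(labels, 1, -1)))
    # empty significant range falls back with a warning
    expect_warning(extractComponentAmplitudes(mV, mAV, lateRange = NULL),
                   "falling back")
})
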