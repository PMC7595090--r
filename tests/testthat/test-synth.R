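test_that("session designs are exactly balanced and blocked", {
    d <- generateSessionDesign(720, 60, seed = 1)
    expect_equal(nrow(d), 720)
    expect_true(all(table(d$modality, d$category) == 180))
    expect_true(all(table(d$modality, d$category, d$coherence) == 45))
    expect_equal(max(d$block), 12)
    expect_true(all(table(d$block) == 60))
    # minimal balanced design: one trial per full cell
    d2 <- generateSessionDesign(16, 16, seed = 2)
    expect_true(all(table(d2$modality, d2$category, d2$coherence) == 1))
    # divisibility violations name the offending cell count
    expect_error(generateSessionDesign(100, 10), "cells")
    expect_error(generateSessionDesign(720, 50), "blockSize")
})

test_that("design generation is deterministic under seed", {
    expect_identical(generateSessionDesign(80, 20, seed = 9),
                     generateSessionDesign(80, 20, seed = 9))
    expect_false(identical(generateSessionDesign(80, 20, seed = 9)$category,
                           generateSessionDesign(80, 20, seed = 10)$category))
})

test_that("symmetric diffusion yields unbiased choices", {
    truth <- smallTruth(nParticipants = 1)
    truth@params$g0 <- 0
    truth@params$g1 <- 0
    truth@params$g2 <- 0
    truth@params$beta <- 0.5
    d <- generateSessionDesign(1024, 256, seed = 4)
    tab <- simulateDDMDataset(d, truth, seed = 5)
    resp <- tab$choice != "none"
    pFace <- mean(tab$choice[resp] == "face")
    se <- sqrt(0.25 / sum(resp))
    expect_lt(abs(pFace - 0.5), 3 * se)
})

test_that("mean RT increases with boundary separation", {
    base <- simulateWienerFPT(1e4, delta = 1, alpha = 1, beta = 0.5,
                              ndt = 0.3, seed = 1)
    wide <- simulateWienerFPT(1e4, delta = 1, alpha = 2, beta = 0.5,
                              ndt = 0.3, seed = 2)
    expect_gt(mean(wide$rt, na.rm = TRUE), mean(base$rt, na.rm = TRUE))
})

test_that("simulated latents couple to realized drift as specified", {
    truth <- smallTruth(nParticipants = 1)
    tab <- smallSession(truth, nTrials = 320, seed = 7)
    r <- .truthRow(truth, 1, "V")
    i <- tab$modality == "V"
    drift <- r$g0 + r$g1 * tab$y_early[i] +
        r$g2 * tab$y_late[i] * tab$coherence[i] / 100
    expect_gt(cor(tab$y_late[i] * tab$coherence[i] / 100, drift), 0)
})

test_that("EEG synthesis is seed-deterministic and aligned", {
    truth <- smallTruth()
    tab <- smallSession(truth, nTrials = 32)
    e1 <- smallEpochs(tab, truth, seed = 5)
    e2 <- smallEpochs(tab, truth, seed = 5)
    expect_identical(epochsData(e1), epochsData(e2))
    expect_equal(dim(epochsData(e1))[1], nrow(tab))
    expect_equal(dim(epochsData(e1))[2], 6)
    expect_error(synthesizeEEGEpochs(tab, truth, fs = 100,
                                     epochWindow = c(0, 0.3), seed = 1),
                 "cover")
})

test_that("trial exclusions follow the RT and amplitude rules", {
    truth <- smallTruth()
    tab <- smallSession(truth, nTrials = 32)
    ep <- smallEpochs(tab, truth)
    # clean data: no exclusions
    tab$rt <- runif(32, 0.4, 1.2)
    tab$choice <- tab$category
    res <- applyTrialExclusions(tab, ep)
    expect_equal(sum(res$counts), 0)
    expect_equal(nrow(res$table), 32)
    # one slow trial removed with the right reason
    tab2 <- tab
    tab2$rt[5] <- 1.6
    res2 <- applyTrialExclusions(tab2, ep)
    expect_equal(unname(res2$counts["too_slow"]), 1)
    expect_false(5 %in% res2$table$trial_id)
    expect_equal(res2$flagged$exclusion_reason[5], "too_slow")
    # toy table: 2 slow, 1 fast, 1 high amplitude -> 6 of 10 survive
    tab3 <- tab[1:10, ]
    ep3 <- ep
    ep3@data <- ep@data[1:10, , , drop = FALSE]
    tab3$rt <- rep(0.8, 10)
    tab3$rt[1:2] <- 1.7
    tab3$rt[3] <- 0.1
    ep3@data[4, 1, 1] <- 200
    res3 <- applyTrialExclusions(tab3, ep3)
    expect_equal(nrow(res3$table), 6)
    expect_equal(unname(res3$counts),  c(2, 1, 1))
    expect_equal(dim(epochsData(res3$epochs))[1], 6)
    # misalignment is an error
    expect_error(applyTrialExclusions(tab3[1:5, ], ep3), "aligned")
})

test_that("regression power is exact noncentral F", {
    # frozen against 1 - pf(qf(.95, 2, 32), 2, 32, ncp = 17.5)
    expect_equal(powerFixedRegression(35, 2, 0.5, 0.05), 0.9554912841,
                 tolerance = 1e-9)
    expect_gte(powerFixedRegression(35, 2, 0.5, 0.05), 0.95)
    # null noncentrality returns alpha
    expect_equal(powerFixedRegression(35, 2, 0, 0.05), 0.05,
                 tolerance = 1e-12)
    # strictly increasing in n
    pw <- vapply(10:100, powerFixedRegression, numeric(1),
                 nPredictors = 2, f2 = 0.3)
    expect_true(all(diff(pw) > 0))
    expect_error(powerFixedRegression(3, 2, 0.5), "degrees of freedom")
})
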