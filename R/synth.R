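## Synthetic study generator: balanced session designs, diffusion-model
## behaviour with latent component amplitudes, and coupled multichannel EEG
## epochs. Ground truth is retained in a SyntheticTruth object so that
## decoding, clustering and posterior-recovery tests can score themselves.

#' Generate a balanced session design
#'
#' Builds the per-trial design of one experimental session: `nTrials` trials
#' divided equally between modality (V/AV), category (face/car) and the
#' visual phase-coherence levels, randomly interleaved and cut into blocks.
#' Choices and RTs are unset (`choice = "none"`, `rt = NA`) until
#' [simulateDDMDataset()] fills them in.
#'
#' The returned trial table is a plain `data.frame` with columns
#' `trial_id`, `participant_id`, `block`, `modality` ("V"/"AV"),
#' `category` ("face"/"car"), `coherence` (percent phase coherence),
#' `choice` ("face"/"car"/"none"), `accuracy`, `rt` (seconds), `excluded`,
#' `exclusion_reason`.
#'
#' @param nTrials total number of trials; must be divisible by
#'   `4 * length(coherenceLevels)`.
#' @param blockSize trials per block; must divide `nTrials`.
#' @param coherenceLevels percent phase-coherence levels (default the four
#'   levels spanning psychophysical threshold).
#' @param seed RNG seed for the trial-order interleaving.
#' @param participant participant identifier stamped on all rows.
#' @return a trial table `data.frame` (see Details).
#' @examples
#' d <- generateSessionDesign(720, 60, seed = 1)
#' table(d$modality, d$category)   # 180 per cell
#' @export
generateSessionDesign <- function(nTrials = 720, blockSize = 60,
                                  coherenceLevels = c(27.5, 30, 32.5, 35),
                                  seed = 1, participant = 1L) {
    nLev <- length(coherenceLevels)
    nCell <- 2L * 2L * nLev
    if (nTrials %% nCell != 0)
        stop(sprintf(
            "nTrials = %d is not divisible by the %d modality x category x coherence cells (%.2f trials per cell)",
            nTrials, nCell, nTrials / nCell))
    if (nTrials %% blockSize != 0)
        stop(sprintf("blockSize = %d does not divide nTrials = %d",
                     blockSize, nTrials))
    per <- nTrials %/% nCell
    cells <- expand.grid(modality = c("V", "AV"),
                         category = c("face", "car"),
                         coherence = coherenceLevels,
                         stringsAsFactors = FALSE)
    design <- cells[rep(seq_len(nrow(cells)), each = per), ]
    set.seed(seed)
    design <- design[sample.int(nrow(design)), ]
    rownames(design) <- NULL
    data.frame(trial_id = seq_len(nTrials),
               participant_id = as.integer(participant),
               block = rep(seq_len(nTrials %/% blockSize), each = blockSize),
               modality = design$modality,
               category = design$category,
               coherence = design$coherence,
               choice = "none",
               accuracy = NA,
               rt = NA_real_,
               excluded = FALSE,
               exclusion_reason = "none",
               stringsAsFactors = FALSE)
}

#' Construct the generating ground truth of a synthetic study
#'
#' Draws per-participant diffusion parameters from group-level Gaussians and
#' fixes the EEG component structure (two unit-norm topographies with
#' Hanning-window time courses in the Early and Late latency ranges, plus a
#' spatially correlated sensor-noise model). The defaults emulate the study
#' conditions the analysis assumes: 40 participants, 64 channels, boundary
#' separation ~1.2, nondecision time ~370 ms (V) / ~410 ms (AV), and a
#' multisensory amplification confined to the Late component amplitude.
#'
#' @param nParticipants number of participants.
#' @param nChannels number of EEG sensors.
#' @param seed RNG seed.
#' @param groupMeans named list of group-level means per condition; see
#'   defaults in the function signature. `g0`, `g1`, `g2` are the drift
#'   intercept and the Early / Late-by-coherence regression weights (the
#'   coherence regressor enters as a proportion, e.g. 0.275-0.35).
#' @param groupSDs named list of between-participant SDs (same names).
#' @param lateGainAV multiplicative AV amplification of the mean Late
#'   amplitude (the Early mean is identical across conditions).
#' @param ampMean mean latent amplitude magnitude (V condition).
#' @param ampSD trial-to-trial SD of the latent amplitudes.
#' @param noiseSD sensor noise SD (microvolts).
#' @param noiseCorLen exponential spatial-correlation length (channels).
#' @param gain microvolts of scalp signal per unit latent amplitude.
#' @param timing list with `earlyCenter`, `earlyWidth`, `lateCenter`,
#'   `lateWidth` (seconds) of the two component time courses.
#' @return a [SyntheticTruth-class] object.
#' @export
makeSyntheticTruth <- function(nParticipants = 40, nChannels = 64, seed = 1,
        groupMeans = list(g0 = 0, g1 = 0.4, g2 = 4, alpha = 1.2,
                          beta = 0.5, ndt_V = 0.37, ndt_AV = 0.41),
        groupSDs = list(g0 = 0.1, g1 = 0.15, g2 = 0.4, alpha = 0.12,
                        beta = 0.04, ndt = 0.04),
        lateGainAV = 1.4, ampMean = 0.9, ampSD = 0.45,
        noiseSD = 6, noiseCorLen = 5, gain = 1,
        timing = list(earlyCenter = 0.27, earlyWidth = 0.18,
                      lateCenter = 0.50, lateWidth = 0.20)) {
    set.seed(seed)
    draw <- function(m, s, lo = -Inf, hi = Inf)
        pmin(pmax(rnorm(nParticipants, m, s), lo), hi)
    mk <- function(cond) {
        ndtM <- if (cond == "V") groupMeans$ndt_V else groupMeans$ndt_AV
        data.frame(participant_id = seq_len(nParticipants),
                   condition = cond,
                   g0 = draw(groupMeans$g0, groupSDs$g0),
                   g1 = draw(groupMeans$g1, groupSDs$g1),
                   g2 = draw(groupMeans$g2, groupSDs$g2),
                   alpha = draw(groupMeans$alpha, groupSDs$alpha, lo = 0.3),
                   beta = draw(groupMeans$beta, groupSDs$beta, 0.15, 0.85),
                   ndt = draw(ndtM, groupSDs$ndt, lo = 0.1),
                   mE = ampMean,
                   mL = if (cond == "V") ampMean else ampMean * lateGainAV,
                   ampSD = ampSD,
                   stringsAsFactors = FALSE)
    }
    params <- rbind(mk("V"), mk("AV"))
    aE <- rnorm(nChannels)
    aE <- aE / sqrt(sum(aE^2))
    aL <- rnorm(nChannels)
    aL <- aL - sum(aL * aE) * aE         # distinct (orthogonal) topography
    aL <- aL / sqrt(sum(aL^2))
    new("SyntheticTruth", params = params, aEarly = aE, aLate = aL,
        timing = timing,
        noise = list(sd = noiseSD, corLen = noiseCorLen, gain = gain),
        seed = as.integer(seed))
}

.truthRow <- function(truth, participant, condition) {
    p <- truth@params
    r <- p[p$participant_id == participant & p$condition == condition, ]
    if (nrow(r) != 1L)
        stop(sprintf("no ground-truth parameters for participant %s / %s",
                     participant, condition))
    r
}

#' Simulate choices and RTs from the generative diffusion model
#'
#' Fills the `choice`, `accuracy` and `rt` columns of a session design by
#' first drawing signed latent component amplitudes per trial (sign given by
#' the stimulus category, magnitude Gaussian around the condition mean; the
#' Late mean additionally scales linearly with the trial's phase coherence,
#' reflecting the proportionality of the late component amplitude to the
#' available visual evidence), then
#' setting the trial drift rate to `g0 + g1*yE + g2*yL*C` (C = phase
#' coherence as a proportion) and simulating a Wiener process between
#' boundaries 0 and alpha (start `beta*alpha`) by Euler-Maruyama with a
#' within-step Brownian-bridge crossing check. RT is the first-passage time
#' plus the nondecision time; trials not absorbed before `deadline` keep
#' `choice = "none"`.
#'
#' @param design a trial table from [generateSessionDesign()] (may contain
#'   several participants).
#' @param truth a [SyntheticTruth-class] object.
#' @param dt Euler step (s); must be <= 1 ms.
#' @param deadline response deadline (s).
#' @param seed RNG seed.
#' @return the trial table with `choice`, `accuracy`, `rt` filled and the
#'   generative latents appended as columns `y_early`, `y_late`.
#' @export
simulateDDMDataset <- function(design, truth, dt = 1e-4, deadline = 1.5,
                               seed = 1) {
    stopifnot(is(truth, "SyntheticTruth"))
    if (dt > 1e-3) stop("dt must be <= 1 ms")
    if (any(truth@params$alpha <= 0) || any(truth@params$ndt <= 0))
        stop("alpha and ndt must be positive")
    set.seed(seed)
    tab <- design
    s <- ifelse(tab$category == "face", 1, -1)
    n <- nrow(tab)
    # latent amplitudes; per-trial means depend on participant x condition
    key <- paste(tab$participant_id, tab$modality)
    rows <- do.call(rbind, lapply(strsplit(unique(key), " "), function(k)
        .truthRow(truth, as.integer(k[1]), k[2])))
    rownames(rows) <- unique(key)
    tr <- rows[key, ]
    tab$y_early <- s * (tr$mE + rnorm(n, 0, tr$ampSD))
    cRel <- tab$coherence / mean(unique(design$coherence))
    tab$y_late  <- s * (tr$mL * cRel + rnorm(n, 0, tr$ampSD))
    drift <- tr$g0 + tr$g1 * tab$y_early +
        tr$g2 * tab$y_late * tab$coherence / 100
    for (k in unique(key)) {
        i <- which(key == k)
        r <- rows[k, ]
        sim <- .simWienerCpp(drift[i], r$alpha, r$beta, r$ndt, dt, deadline)
        tab$rt[i] <- sim$rt
        tab$choice[i] <- ifelse(is.na(sim$choice), "none",
                                ifelse(sim$choice == 1, "face", "car"))
    }
    tab$accuracy <- ifelse(tab$choice == "none", NA,
                           tab$choice == tab$category)
    tab
}

.hanningBump <- function(t, center, width) {
    u <- (t - center) / width
    ifelse(abs(u) < 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
}

#' Synthesize multichannel EEG epochs coupled to the behavioural latents
#'
#' Builds a trials x channels x samples tensor as the sum of two rank-one
#' spatiotemporal components and spatially correlated Gaussian sensor noise:
#' `x(t) = gain * (aE * yE * sE(t) + aL * yL * sL(t)) + noise`, where `sE`,
#' `sL` are smooth unimodal (Hanning) time courses centred in the Early and
#' Late latency ranges and `yE`, `yL` are the same latents that drove the
#' simulated behaviour. Noise is white in time with exponential spatial
#' correlation across the channel index.
#'
#' @param table a trial table carrying `y_early`/`y_late` columns (from
#'   [simulateDDMDataset()]).
#' @param truth the [SyntheticTruth-class] used to simulate the behaviour.
#' @param fs sampling rate (Hz).
#' @param epochWindow c(start, end) of the epoch relative to stimulus (s);
#'   must cover both component time courses.
#' @param seed RNG seed.
#' @return an [EEGEpochs-class] object aligned 1:1 with `table` rows.
#' @export
synthesizeEEGEpochs <- function(table, truth, fs = 1000,
                                epochWindow = c(-0.1, 1.0), seed = 1) {
    stopifnot(is(truth, "SyntheticTruth"))
    if (!all(c("y_early", "y_late") %in% names(table)))
        stop("table lacks y_early/y_late; run simulateDDMDataset() first")
    tm <- truth@timing
    if (epochWindow[1] > tm$earlyCenter - tm$earlyWidth / 2 ||
        epochWindow[2] < tm$lateCenter + tm$lateWidth / 2)
        stop("epoch window does not cover both component time courses")
    D <- length(truth@aEarly)
    tt <- seq(epochWindow[1], epochWindow[2], by = 1 / fs)
    S <- length(tt)
    n <- nrow(table)
    sE <- .hanningBump(tt, tm$earlyCenter, tm$earlyWidth)
    sL <- .hanningBump(tt, tm$lateCenter, tm$lateWidth)
    g <- truth@noise$gain
    # channel-space cholesky of the exponential spatial correlation
    L <- if (truth@noise$sd > 0) {
        C <- truth@noise$sd^2 *
            exp(-abs(outer(seq_len(D), seq_len(D), "-")) / truth@noise$corLen)
        t(chol(C))
    } else NULL
    set.seed(seed)
    data <- array(0, dim = c(n, D, S))
    for (i in seq_len(n)) {
        sig <- g * (outer(truth@aEarly, table$y_early[i] * sE) +
                    outer(truth@aLate, table$y_late[i] * sL))
        if (!is.null(L))
            sig <- sig + L %*% matrix(rnorm(D * S), D, S)
        data[i, , ] <- sig
    }
    EEGEpochs(data, fs = fs, lock = "stimulus", t0 = epochWindow[1])
}

#' Apply the standard trial-exclusion rules
#'
#' Flags and removes trials that exceeded the RT deadline (or gave no
#' response), responded faster than `rtMin`, or whose EEG exceeded the
#' amplitude ceiling, keeping trial table and epochs aligned. Reasons are
#' assigned with precedence too_slow, too_fast, amplitude.
#'
#' @param table trial table.
#' @param epochs optional [EEGEpochs-class] aligned with `table` (required
#'   for the amplitude rule).
#' @param rtMax RT ceiling (s); slower responses and non-responses are
#'   excluded as `too_slow`.
#' @param rtMin RT floor (s); faster responses are excluded as `too_fast`.
#' @param ampMax maximum absolute EEG amplitude (microvolts).
#' @return list with elements `table` and `epochs` (filtered), `flagged`
#'   (the full annotated table) and `counts` (exclusions per reason).
#' @export
applyTrialExclusions <- function(table, epochs = NULL, rtMax = 1.5,
                                 rtMin = 0.3, ampMax = 150) {
    if (!is.null(epochs) && dim(epochs@data)[1] != nrow(table))
        stop("table and epochs are not aligned (row/trial count differs)")
    reason <- rep("none", nrow(table))
    slow <- table$choice == "none" | (!is.na(table$rt) & table$rt > rtMax)
    fast <- !is.na(table$rt) & table$rt < rtMin
    if (!is.null(epochs)) {
        amp <- apply(abs(epochs@data), 1, max) > ampMax
    } else amp <- rep(FALSE, nrow(table))
    reason[amp] <- "amplitude"
    reason[fast] <- "too_fast"
    reason[slow] <- "too_slow"
    keep <- reason == "none"
    flagged <- table
    flagged$excluded <- !keep
    flagged$exclusion_reason <- reason
    counts <- c(too_slow = sum(reason == "too_slow"),
                too_fast = sum(reason == "too_fast"),
                amplitude = sum(reason == "amplitude"))
    out <- list(table = flagged[keep, , drop = FALSE], epochs = NULL,
                flagged = flagged, counts = counts)
    if (!is.null(epochs)) {
        e <- epochs
        e@data <- epochs@data[keep, , , drop = FALSE]
        out$epochs <- e
    }
    out
}

#' A priori power of the fixed-model multiple-regression F test
#'
#' Exact power of the test that R-squared deviates from zero in a fixed
#' linear multiple regression, using the noncentral F distribution with
#' `df1 = nPredictors`, `df2 = n - nPredictors - 1` and noncentrality
#' `lambda = f2 * n`, where `f2` is Cohen's f-squared effect size.
#'
#' @param n sample size.
#' @param nPredictors number of predictors.
#' @param f2 effect size (Cohen's f-squared).
#' @param alpha type-I error rate.
#' @return the power (probability).
#' @examples
#' powerFixedRegression(35, 2, 0.5)   # ~0.955
#' @export
powerFixedRegression <- function(n, nPredictors, f2, alpha = 0.05) {
    df2 <- n - nPredictors - 1
    if (df2 < 1 || nPredictors < 1)
        stop("invalid degrees of freedom: need n > nPredictors + 1")
    crit <- qf(1 - alpha, nPredictors, df2)
    1 - pf(crit, nPredictors, df2, ncp = f2 * n)
}
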