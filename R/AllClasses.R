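## S4 containers for the analysis chain.
##
## The per-trial behavioural record ("trial table") is deliberately a plain
## data.frame with documented columns (see generateSessionDesign()); the
## heavier multichannel / posterior objects get S4 classes with validity.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' EEGEpochs: epoched multichannel EEG
#'
#' Trials x channels x samples tensor (microvolts) with its sampling rate,
#' lock type and epoch timing. The trials axis is aligned 1:1 with the rows
#' of the trial table it was built from (after exclusions).
#'
#' @slot data numeric array, trials x channels x samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot lock `"stimulus"` or `"response"`.
#' @slot t0 time (seconds) of the first sample relative to the lock event.
#' @slot channels channel labels, length = dim(data)[2].
#' @export
setClass("EEGEpochs",
    representation(data = "array", fs = "numeric", lock = "character",
                   t0 = "numeric", channels = "character"),
    validity = function(object) {
        d <- dim(object@data)
        if (length(d) != 3L) return("data must be a 3-d array")
        if (d[2] < 2L) return("at least 2 channels are required")
        if (length(object@channels) != d[2])
            return("channel labels do not match channel dimension")
        if (length(object@fs) != 1L || object@fs <= 0)
            return("fs must be a positive scalar")
        if (!object@lock %in% c("stimulus", "response"))
            return("lock must be 'stimulus' or 'response'")
        TRUE
    })

#' @describeIn EEGEpochs-class constructor
#' @param data trials x channels x samples array (microvolts).
#' @param fs sampling rate (Hz).
#' @param lock `"stimulus"` or `"response"`.
#' @param t0 time of the first sample relative to the lock event (s).
#' @param channels optional channel labels.
#' @export
EEGEpochs <- function(data, fs, lock = "stimulus", t0 = 0,
                      channels = NULL) {
    if (is.null(channels))
        channels <- sprintf("ch%02d", seq_len(dim(data)[2]))
    new("EEGEpochs", data = data, fs = fs, lock = lock, t0 = t0,
        channels = channels)
}

#' @describeIn EEGEpochs-class the trials x channels x samples array
#' @param x an `EEGEpochs` object.
#' @export
epochsData <- function(x) x@data

#' @describeIn EEGEpochs-class sampling rate (Hz)
#' @export
samplingRate <- function(x) x@fs

#' @describeIn EEGEpochs-class channel labels
#' @export
channelLabels <- function(x) x@channels

#' @describeIn EEGEpochs-class per-sample times relative to the lock (s)
#' @export
epochTimes <- function(x) x@t0 + (seq_len(dim(x@data)[3]) - 1L) / x@fs

setMethod("show", "EEGEpochs", function(object) {
    d <- dim(object@data)
    cat(sprintf(
        "EEGEpochs: %d trials x %d channels x %d samples @ %g Hz (%s-locked, t0 = %g s)\n",
        d[1], d[2], d[3], object@fs, object@lock, object@t0))
})

#' DiscriminantMap: sliding-window decoding result for one condition
#'
#' Per-window spatial weights, out-of-sample component amplitudes, Az
#' timecourse and forward-model topographies from [looAz()].
#'
#' @slot centers window center times (s relative to lock).
#' @slot width window width (s).
#' @slot weights windows x channels spatial filters (full-data fits).
#' @slot bias per-window logistic intercepts (not part of the projection).
#' @slot y trials x windows out-of-sample amplitudes.
#' @slot az per-window leave-one-trial-out ROC area.
#' @slot azSig scalar permutation significance threshold (NA until set).
#' @slot forward windows x channels forward models (microvolts).
#' @slot condition condition label (e.g. "V" or "AV").
#' @export
setClass("DiscriminantMap",
    representation(centers = "numeric", width = "numeric",
                   weights = "matrix", bias = "numeric", y = "matrix",
                   az = "numeric", azSig = "numeric", forward = "matrix",
                   condition = "character"),
    validity = function(object) {
        W <- length(object@centers)
        if (nrow(object@weights) != W || nrow(object@forward) != W)
            return("weights/forward models must have one row per window")
        if (ncol(object@y) != W)
            return("y must have one column per window")
        if (length(object@az) != W)
            return("az must have one value per window")
        if (any(object@az < 0 | object@az > 1, na.rm = TRUE))
            return("az values must lie in [0, 1]")
        TRUE
    })

#' @describeIn DiscriminantMap-class Az timecourse
#' @param x a `DiscriminantMap`.
#' @export
azTimecourse <- function(x) x@az

#' @describeIn DiscriminantMap-class window center times (s)
#' @export
windowCenters <- function(x) x@centers

#' @describeIn DiscriminantMap-class windows x channels forward models
#' @export
forwardModels <- function(x) x@forward

#' @describeIn DiscriminantMap-class trials x windows out-of-sample amplitudes
#' @export
trialAmplitudes <- function(x) x@y

#' @describeIn DiscriminantMap-class windows x channels spatial filters
#' @export
discriminantWeights <- function(x) x@weights

setMethod("show", "DiscriminantMap", function(object) {
    cat(sprintf(
        "DiscriminantMap [%s]: %d windows (%.0f ms wide), %d trials; peak Az = %.3f at %.0f ms%s\n",
        object@condition, length(object@centers), 1000 * object@width,
        nrow(object@y), max(object@az),
        1000 * object@centers[which.max(object@az)],
        if (is.na(object@azSig)) "" else sprintf("; Az_sig = %.3f", object@azSig)))
})

#' ComponentAmplitudes: trial-wise Early/Late component amplitudes
#'
#' Single-trial amplitudes averaged over the participant-specific Early and
#' Late selection windows, as produced by [extractComponentAmplitudes()].
#'
#' @slot yEarly per-trial Early amplitude.
#' @slot yLate per-trial Late amplitude.
#' @slot earlyWindow selected Early window, c(start, end) in s.
#' @slot lateWindow selected Late window, c(start, end) in s.
#' @slot participant participant identifier.
#' @slot condition condition label.
#' @export
setClass("ComponentAmplitudes",
    representation(yEarly = "numeric", yLate = "numeric",
                   earlyWindow = "numeric", lateWindow = "numeric",
                   participant = "integer", condition = "character"),
    validity = function(object) {
        if (length(object@yEarly) != length(object@yLate))
            return("yEarly and yLate must have the same length")
        if (length(object@earlyWindow) != 2L || length(object@lateWindow) != 2L)
            return("windows must be length-2 (start, end)")
        TRUE
    })

setMethod("show", "ComponentAmplitudes", function(object) {
    cat(sprintf(
        "ComponentAmplitudes [%s, participant %d]: %d trials; early %d-%d ms, late %d-%d ms\n",
        object@condition, object@participant, length(object@yEarly),
        round(1000 * object@earlyWindow[1]), round(1000 * object@earlyWindow[2]),
        round(1000 * object@lateWindow[1]), round(1000 * object@lateWindow[2])))
})

#' ComponentWindows: Early/Late window definition
#'
#' Transition time between the two spatiotemporal components and the Early
#' and Late windows it induces under a guard gap (see
#' [defineComponentWindows()]).
#'
#' @slot transition transition time (s).
#' @slot gap guard gap centred on the transition (s).
#' @slot early c(start, end) of the Early window (s).
#' @slot late c(start, end) of the Late window (s).
#' @slot k number of topography clusters selected.
#' @export
setClass("ComponentWindows",
    representation(transition = "numeric", gap = "numeric",
                   early = "numeric", late = "numeric", k = "integer"),
    validity = function(object) {
        if (object@k < 1L) return("k must be >= 1")
        if (object@k > 1L) {
            if (object@early[1] >= object@early[2] ||
                object@late[1] >= object@late[2])
                return("degenerate component window")
            if (object@early[2] + object@gap > object@late[1] + 1e-9)
                return("early end + gap must not exceed late start")
        }
        TRUE
    })

setMethod("show", "ComponentWindows", function(object) {
    cat(sprintf(
        "ComponentWindows: k = %d, transition %.0f ms, early %.0f-%.0f ms, late %.0f-%.0f ms (gap %.0f ms)\n",
        object@k, 1000 * object@transition, 1000 * object@early[1],
        1000 * object@early[2], 1000 * object@late[1], 1000 * object@late[2],
        1000 * object@gap))
})

#' BootstrapResult: group-level Az-difference cluster test
#'
#' Output of the percentile-bootstrap comparison of decoding performance
#' between conditions, with the data-driven minimum cluster size applied
#' (see [bootstrapAzDifference()] and [minClusterSizeNull()]).
#'
#' @slot times per-sample times (s).
#' @slot medianDiff per-sample bootstrap median of the AV-V difference.
#' @slot ciLow,ciHigh 2.5/97.5 percentile bounds of the bootstrap medians.
#' @slot minClusterSize minimum run length for a significant cluster.
#' @slot clusters matrix with columns start, end (s), one row per cluster.
#' @export
setClass("BootstrapResult",
    representation(times = "numeric", medianDiff = "numeric",
                   ciLow = "numeric", ciHigh = "numeric",
                   minClusterSize = "integer", clusters = "matrix"),
    validity = function(object) {
        n <- length(object@times)
        if (length(object@medianDiff) != n || length(object@ciLow) != n ||
            length(object@ciHigh) != n)
            return("per-sample vectors must share the time axis")
        if (any(object@ciLow > object@medianDiff + 1e-12) ||
            any(object@ciHigh < object@medianDiff - 1e-12))
            return("confidence bounds must bracket the median")
        TRUE
    })

setMethod("show", "BootstrapResult", function(object) {
    cat(sprintf(
        "BootstrapResult: %d samples, min cluster size %d, %d significant cluster(s)\n",
        length(object@times), object@minClusterSize, nrow(object@clusters)))
    if (nrow(object@clusters) > 0)
        for (i in seq_len(nrow(object@clusters)))
            cat(sprintf("  cluster %d: %.0f-%.0f ms\n", i,
                        1000 * object@clusters[i, 1], 1000 * object@clusters[i, 2]))
})

#' SyntheticTruth: generating parameters of a synthetic study
#'
#' Ground-truth diffusion and EEG parameters used by the synthetic-data
#' generator, retained for recovery tests. See [makeSyntheticTruth()].
#'
#' @slot params data.frame: one row per participant x condition with columns
#'   participant_id, condition, g0, g1, g2, alpha, beta, ndt, mE, mL
#'   (latent amplitude means) and ampSD.
#' @slot aEarly,aLate unit-norm component topographies (length = channels).
#' @slot timing list with earlyCenter, earlyWidth, lateCenter, lateWidth (s).
#' @slot noise list with sd (microvolts), corLen (channels) and gain
#'   (microvolts per unit amplitude).
#' @slot seed the seed the truth was drawn under.
#' @export
setClass("SyntheticTruth",
    representation(params = "data.frame", aEarly = "numeric",
                   aLate = "numeric", timing = "list", noise = "list",
                   seed = "integer"),
    validity = function(object) {
        need <- c("participant_id", "condition", "g0", "g1", "g2", "alpha",
                  "beta", "ndt", "mE", "mL", "ampSD")
        if (!all(need %in% names(object@params)))
            return(paste("params must contain columns:",
                         paste(need, collapse = ", ")))
        if (abs(sum(object@aEarly^2) - 1) > 1e-8 ||
            abs(sum(object@aLate^2) - 1) > 1e-8)
            return("topographies must have unit norm")
        if (any(object@params$alpha <= 0) || any(object@params$ndt <= 0))
            return("alpha and ndt must be positive")
        if (any(object@params$ampSD <= 0) || object@noise$sd < 0)
            return("variance parameters must be positive")
        TRUE
    })

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf(
        "SyntheticTruth: %d participants x %d conditions, %d channels (seed %d)\n",
        length(unique(object@params$participant_id)),
        length(unique(object@params$condition)), length(object@aEarly),
        object@seed))
})

#' PosteriorSamples: MCMC draws from the hierarchical DDM posterior
#'
#' Chains of retained draws with parameter names, convergence diagnostics
#' and the fitted model context needed for DIC and posterior predictions.
#'
#' @slot draws list of per-chain matrices (retained draws x parameters).
#' @slot paramNames column names of the draw matrices.
#' @slot groupNames names of the group-level parameters (mu/sigma).
#' @slot rhat per-group-parameter Gelman-Rubin statistic.
#' @slot dicValue DIC (NA until [dic()] is called).
#' @slot settings list: variant, nChains, nSamples, burnIn, thin, seed.
#' @slot model internal prepared-data structure used for likelihoods.
#' @export
setClass("PosteriorSamples",
    representation(draws = "list", paramNames = "character",
                   groupNames = "character", rhat = "numeric",
                   dicValue = "numeric", settings = "list", model = "list"),
    validity = function(object) {
        if (!all(vapply(object@draws, is.matrix, logical(1))))
            return("draws must be a list of matrices")
        nc <- vapply(object@draws, ncol, integer(1))
        if (length(unique(nc)) > 1 || nc[1] != length(object@paramNames))
            return("all chains must share the parameter axis")
        TRUE
    })

#' @describeIn PosteriorSamples-class retained draws, chains stacked
#' @param x a `PosteriorSamples` object.
#' @export
posteriorDraws <- function(x) do.call(rbind, x@draws)

#' @describeIn PosteriorSamples-class names of group-level parameters
#' @export
groupParameterNames <- function(x) x@groupNames

setMethod("show", "PosteriorSamples", function(object) {
    s <- object@settings
    cat(sprintf(
        "PosteriorSamples [%s]: %d chains x %d retained draws, %d parameters\n",
        s$variant, length(object@draws), nrow(object@draws[[1]]),
        length(object@paramNames)))
    if (length(object@rhat))
        cat(sprintf("  max group-level Rhat = %.4f\n", max(object@rhat)))
    if (!is.na(object@dicValue))
        cat(sprintf("  DIC = %.1f\n", object@dicValue))
})
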