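## Sliding-window linear discrimination of face vs car trials.
##
## Within each 60 ms window every time sample is treated as an independent
## observation sharing one spatial weight vector w, learned by L2-penalized
## logistic regression (IRLS, zero initialization). Decoding performance is
## the ROC area (Az) of out-of-sample amplitudes from leave-one-trial-out
## cross-validation; scalp couplings come from the forward model
## a = X y / (y'y).

#' Sliding-window configuration
#'
#' @param width window width in seconds.
#' @param step onset interval between consecutive windows (s).
#' @param range c(start, end) of window centers relative to the lock event
#'   (s); the conventional stimulus-locked range is -0.1..1.0 and the
#'   response-locked range -0.6..0.5.
#' @return a list with class `"SlidingWindowConfig"`.
#' @export
slidingWindowConfig <- function(width = 0.060, step = 0.010,
                                range = c(-0.100, 1.000)) {
    stopifnot(width > 0, step > 0, range[1] < range[2])
    structure(list(width = width, step = step, range = range),
              class = "SlidingWindowConfig")
}

#' Enumerate sliding windows as sample-index slices
#'
#' Window centers span `cfg$range` inclusively at `cfg$step`; each center
#' maps to a contiguous slice of `round(width * fs)` samples. When the epoch
#' extent (`t0`, `nSamples`) is supplied, windows reaching past the epoch
#' are trimmed with a warning and windows fully outside are an error.
#'
#' @param cfg a [slidingWindowConfig()].
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample (s); optional, enables trimming.
#' @param nSamples number of samples per epoch; optional.
#' @return data.frame with columns `center` (s), `first`, `last` (1-based
#'   sample indices).
#' @export
enumerateWindows <- function(cfg, fs, t0 = NULL, nSamples = NULL) {
    centers <- seq(cfg$range[1], cfg$range[2], by = cfg$step)
    len <- max(1L, round(cfg$width * fs))
    if (is.null(t0)) t0 <- cfg$range[1] - cfg$width / 2
    first <- round((centers - cfg$width / 2 - t0) * fs) + 1L
    last <- first + len - 1L
    if (!is.null(nSamples)) {
        outside <- last < 1L | first > nSamples
        if (all(outside))
            stop("all windows fall outside the epoch extent")
        if (any(outside)) {
            warning(sprintf("%d window(s) fully outside the epoch dropped",
                            sum(outside)))
            centers <- centers[!outside]
            first <- first[!outside]
            last <- last[!outside]
        }
        if (any(first < 1L | last > nSamples))
            warning("windows exceeding the epoch extent were trimmed")
        first <- pmax(first, 1L)
        last <- pmin(last, nSamples)
    }
    data.frame(center = centers, first = first, last = last)
}

## stacked design matrix of one window: (trials*samples) x channels
.stackWindow <- function(x) {
    if (length(dim(x)) == 2L) return(x)
    d <- dim(x)
    matrix(aperm(x, c(1, 3, 2)), nrow = d[1] * d[3], ncol = d[2])
}

.irlsFit <- function(X, y, lambda, init = NULL, maxIter = 500, tol = 1e-8) {
    Z <- cbind(1, X)
    P <- diag(c(0, rep(lambda, ncol(X))))
    beta <- if (is.null(init)) numeric(ncol(Z)) else init
    for (it in seq_len(maxIter)) {
        eta <- drop(Z %*% beta)
        mu <- 1 / (1 + exp(-eta))
        w <- pmax(mu * (1 - mu), 1e-10)
        z <- eta + (y - mu) / w
        new <- tryCatch(
            drop(solve(crossprod(Z, Z * w) + P, crossprod(Z, w * z))),
            error = function(e) stop("singular system in logistic fit: ",
                                     conditionMessage(e)))
        if (max(abs(new - beta)) < tol * (1 + max(abs(new)))) {
            return(list(beta = new, iterations = it))
        }
        beta <- new
    }
    stop(sprintf("logistic discriminant did not converge in %d iterations",
                 maxIter))
}

#' Fit the spatial discriminator of one window
#'
#' Learns the spatial weighting `w` (and an intercept, which is not part of
#' the scalp projection) by L2-penalized logistic regression on the stacked
#' window samples, mapping face trials to positive and car trials to
#' negative projections.
#'
#' @param x trials x channels x samples array (or trials x channels matrix)
#'   restricted to one window.
#' @param labels logical/0-1 vector, TRUE/1 = face.
#' @param l2 penalty strength; the effective ridge is
#'   `l2 * sum(x^2) / channels` (trace-scaled), keeping the penalty small
#'   but scale-free for 64-channel stability.
#' @param init optional warm-start coefficient vector c(intercept, w).
#' @param maxIter,tol IRLS iteration cap and convergence tolerance.
#' @return list with `w` (length channels), `b` (intercept), `iterations`.
#' @export
fitWindowDiscriminator <- function(x, labels, l2 = 1e-4, init = NULL,
                                   maxIter = 500, tol = 1e-8) {
    labels <- as.integer(as.logical(labels))
    if (length(unique(labels)) < 2L)
        stop("both classes must be present to fit a discriminator")
    X <- .stackWindow(x)
    S <- nrow(X) / length(labels)
    y <- rep(labels, times = S)
    lambda <- l2 * sum(X^2) / ncol(X)
    fit <- .irlsFit(X, y, lambda, init = init, maxIter = maxIter, tol = tol)
    list(w = fit$beta[-1], b = fit$beta[1], iterations = fit$iterations)
}

#' ROC area of component amplitudes
#'
#' Area under the ROC curve computed by the rank (Mann-Whitney) statistic
#' with midrank tie correction: the probability that a randomly chosen face
#' trial has a larger amplitude than a randomly chosen car trial.
#'
#' @param y amplitudes (one per trial).
#' @param labels logical/0-1 vector, TRUE = face.
#' @return the Az value in `[0, 1]`.
#' @export
rocArea <- function(y, labels) {
    labels <- as.logical(labels)
    n1 <- sum(labels)
    n0 <- sum(!labels)
    if (n1 == 0 || n0 == 0) stop("both classes must be present")
    r <- rank(y)
    (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
.rankAz <- rocArea

#' Forward model of a discriminating component
#'
#' Scalp projection coupling the component amplitudes to the sensor data,
#' `a = X y / (y' y)` with the window data in matrix and the amplitudes in
#' vector form; interpretable as the topography of the discriminating
#' activity (microvolts per unit amplitude).
#'
#' @param x window data: observations x channels matrix, or a trials x
#'   channels x samples array (samples are stacked as observations).
#' @param y component amplitudes, one per observation.
#' @return the forward-model vector (length channels).
#' @export
forwardModel <- function(x, y) {
    X <- .stackWindow(x)
    if (length(y) != nrow(X))
        stop("y must have one value per observation")
    if (var(y) == 0) stop("y has zero variance")
    colSums(X * y) / sum(y^2)
}

#' Leave-one-trial-out decoding across sliding windows
#'
#' For each window, fits N discriminators on N-1 trials, projects each
#' held-out trial to its out-of-sample amplitude (the mean projection over
#' the window's samples, excluding the intercept) and scores the window by
#' the ROC area of those amplitudes. Full-data weights and forward-model
#' topographies are also returned per window.
#'
#' @param epochs an [EEGEpochs-class] object.
#' @param labels logical/0-1 vector per trial, TRUE = face.
#' @param cfg a [slidingWindowConfig()].
#' @param l2 penalty passed to [fitWindowDiscriminator()].
#' @param condition label stored in the result (e.g. "V").
#' @return a [DiscriminantMap-class] object.
#' @export
looAz <- function(epochs, labels, cfg = slidingWindowConfig(), l2 = 1e-4,
                  condition = "") {
    labels <- as.logical(labels)
    n <- dim(epochs@data)[1]
    if (length(labels) != n) stop("labels must match the trial count")
    if (min(sum(labels), sum(!labels)) < 2L)
        stop("each class needs at least 2 trials for leave-one-out decoding")
    win <- enumerateWindows(cfg, epochs@fs, epochs@t0, dim(epochs@data)[3])
    W <- nrow(win)
    D <- dim(epochs@data)[2]
    weights <- matrix(0, W, D)
    bias <- numeric(W)
    forward <- matrix(0, W, D)
    yout <- matrix(0, n, W)
    az <- numeric(W)
    for (j in seq_len(W)) {
        xw <- epochs@data[, , win$first[j]:win$last[j], drop = FALSE]
        full <- fitWindowDiscriminator(xw, labels, l2 = l2)
        weights[j, ] <- full$w
        bias[j] <- full$b
        X <- .stackWindow(xw)
        yfull <- drop(X %*% full$w)
        forward[j, ] <- forwardModel(X, yfull)
        init <- c(full$b, full$w)
        for (i in seq_len(n)) {
            fit <- fitWindowDiscriminator(
                xw[-i, , , drop = FALSE], labels[-i], l2 = l2, init = init)
            xi <- matrix(xw[i, , ], nrow = D)   # channels x samples
            yout[i, j] <- mean(colSums(xi * fit$w))
        }
        az[j] <- .rankAz(yout[, j], labels)
    }
    new("DiscriminantMap", centers = win$center, width = cfg$width,
        weights = weights, bias = bias, y = yout, az = az,
        azSig = NA_real_, forward = forward, condition = condition)
}

#' Permutation significance threshold for decoding performance
#'
#' Randomizes the class labels `nPerm` times, reruns the full
#' leave-one-trial-out pipeline on each randomization, pools the null Az
#' values over windows and returns their `1 - alpha` quantile as the
#' participant-level significance threshold.
#'
#' @inheritParams looAz
#' @param nPerm number of label randomizations (>= 100).
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return list with `azSig` (the threshold) and `null` (all stored null Az
#'   draws, windows x permutations pooled).
#' @export
permutationThreshold <- function(epochs, labels, cfg = slidingWindowConfig(),
                                 nPerm = 1000, alpha = 0.05, seed = 1,
                                 l2 = 1e-4) {
    if (nPerm < 100) stop("nPerm must be at least 100")
    set.seed(seed)
    null <- unlist(lapply(seq_len(nPerm), function(p) {
        labs <- sample(as.logical(labels))
        azTimecourse(looAz(epochs, labs, cfg = cfg, l2 = l2))
    }))
    list(azSig = unname(quantile(null, 1 - alpha)), null = null)
}

#' Peak-Az latency within a search window
#'
#' Returns the center time of the maximum-Az window inside the search range;
#' ties are broken by the earliest time.
#'
#' @param az per-window Az values.
#' @param centers per-window center times (s).
#' @param searchWindow c(start, end) in seconds.
#' @return the peak time (s).
#' @export
extractPeakLatency <- function(az, centers, searchWindow) {
    idx <- which(centers >= searchWindow[1] - 1e-9 &
                 centers <= searchWindow[2] + 1e-9)
    if (!length(idx)) stop("search window contains no window centers")
    centers[idx][which.max(az[idx])]
}

#' Extract participant-specific Early/Late component amplitudes
#'
#' Selects the Early window at the individual peak Az across the V and AV
#' timecourses within `earlyRange`, and the Late window at the individual
#' peak Az difference (AV - V) within the group-significant `lateRange`;
#' both selections are extended by `extension` on either side (the decoding
#' windows are wider than their centers), and the single-trial amplitudes
#' are averaged over the selected windows, per condition.
#'
#' @param mapV,mapAV [DiscriminantMap-class] objects for the V and AV
#'   conditions of one participant (shared window axis).
#' @param earlyRange Early search range, c(start, end) s.
#' @param lateRange group-significant Late range; if `NULL` or empty the
#'   full 0.40-0.60 s range is used with a warning.
#' @param extension seconds added on either side of the selected windows.
#' @param participant participant identifier stored in the result.
#' @return list with elements `V` and `AV`, each a
#'   [ComponentAmplitudes-class] object.
#' @export
extractComponentAmplitudes <- function(mapV, mapAV,
                                       earlyRange = c(0.18, 0.36),
                                       lateRange = NULL, extension = 0.03,
                                       participant = 1L) {
    if (!isTRUE(all.equal(mapV@centers, mapAV@centers)))
        stop("V and AV maps must share the window axis")
    centers <- mapV@centers
    if (is.null(lateRange) || !length(lateRange) ||
        diff(range(lateRange)) <= 0) {
        warning("empty significant Late range; falling back to 0.40-0.60 s")
        lateRange <- c(0.40, 0.60)
    }
    tE <- extractPeakLatency(pmax(mapV@az, mapAV@az), centers, earlyRange)
    tL <- extractPeakLatency(mapAV@az - mapV@az, centers,
                             c(lateRange[1], lateRange[2]))
    earlyWin <- c(tE - extension, tE + extension)
    lateWin <- c(tL - extension, tL + extension)
    avg <- function(map, wn) {
        idx <- which(centers >= wn[1] - 1e-9 & centers <= wn[2] + 1e-9)
        rowMeans(map@y[, idx, drop = FALSE])
    }
    mk <- function(map, cond)
        new("ComponentAmplitudes",
            yEarly = avg(map, earlyWin), yLate = avg(map, lateWin),
            earlyWindow = earlyWin, lateWindow = lateWin,
            participant = as.integer(participant), condition = cond)
    list(V = mk(mapV, "V"), AV = mk(mapAV, "AV"))
}
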