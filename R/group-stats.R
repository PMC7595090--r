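## Group-level inference: percentile-bootstrap comparison of decoding
## timecourses between conditions with a data-driven minimum cluster size,
## participant-consistency fractions, and the robust percentage-bend
## correlation.

#' Percentile-bootstrap test of the group Az difference
#'
#' Per time sample, resamples participants with replacement `nBoot` times
#' and records the median of the AV - V difference; the reported statistic
#' is the median of those bootstrap medians with its 2.5-97.5 percentile
#' envelope. A sample is significant when the lower bound exceeds zero
#' (one-sided, p < 0.025). By default one participant resample per
#' bootstrap iteration is applied to every sample (preserving each
#' participant's timecourse); `perSample = TRUE` draws independent
#' resamples per sample instead.
#'
#' @param azV,azAV participants x samples Az matrices (matched rows).
#' @param nBoot number of bootstrap iterations (>= 100).
#' @param seed RNG seed.
#' @param conf two-sided confidence level (default 0.95, i.e. 2.5-97.5).
#' @param perSample resample participants independently per sample.
#' @return list with `medianDiff`, `ciLow`, `ciHigh`, `significant`
#'   (per-sample logicals).
#' @export
bootstrapAzDifference <- function(azV, azAV, nBoot = 1000, seed = 1,
                                  conf = 0.95, perSample = FALSE) {
    azV <- as.matrix(azV); azAV <- as.matrix(azAV)
    if (!all(dim(azV) == dim(azAV)))
        stop("azV and azAV must have matching dimensions")
    if (nrow(azV) < 5) stop("need at least 5 participants")
    if (nBoot < 100) stop("nBoot must be at least 100")
    d <- azAV - azV
    lo <- (1 - conf) / 2
    set.seed(seed)
    if (perSample) {
        res <- lapply(seq_len(ncol(d)), function(s)
            .bootMedianCICpp(d[, s, drop = FALSE], nBoot, lo, 1 - lo))
        out <- list(medianDiff = vapply(res, function(r) r$median[1], 0),
                    ciLow = vapply(res, function(r) r$ciLow[1], 0),
                    ciHigh = vapply(res, function(r) r$ciHigh[1], 0))
    } else {
        r <- .bootMedianCICpp(d, nBoot, lo, 1 - lo)
        out <- list(medianDiff = r$median, ciLow = r$ciLow,
                    ciHigh = r$ciHigh)
    }
    out$significant <- out$ciLow > 0
    out
}

#' Data-driven minimum cluster size from a temporal-shuffling null
#'
#' Destroys the relationship across temporal samples by shuffling the sample
#' axis without replacement, independently within each participant while
#' keeping the per-sample AV - V pairing intact; reruns the per-sample
#' bootstrap significance test on each permutation and records the largest
#' run of adjacent significant samples. The minimum cluster size is the
#' smallest run length whose probability of occurring anywhere in a null
#' timecourse is at most `1 - quantile` (i.e. the smallest length strictly
#' exceeding the stated quantile of the null maxima, floor 1) — e.g. a null
#' 95th-percentile maximum of two adjacent samples yields a minimum cluster
#' size of three. This exceedance rule is what controls the family-wise
#' false-cluster rate at the nominal level.
#'
#' @inheritParams bootstrapAzDifference
#' @param nPerm number of permutations (>= 100).
#' @param quantile quantile of the null maxima used as threshold.
#' @param nBoot bootstrap iterations inside each permutation.
#' @return list with `minClusterSize` and `null` (the max-cluster draws).
#' @export
minClusterSizeNull <- function(azV, azAV, nPerm = 1000, quantile = 0.95,
                               seed = 1, nBoot = 200, conf = 0.95) {
    azV <- as.matrix(azV); azAV <- as.matrix(azAV)
    if (!all(dim(azV) == dim(azAV)))
        stop("azV and azAV must have matching dimensions")
    if (nPerm < 100) stop("nPerm must be at least 100")
    d <- azAV - azV
    set.seed(seed)
    null <- .maxClusterNullCpp(d, nPerm, nBoot, (1 - conf) / 2)
    ## smallest m with P_null(max cluster >= m) <= 1 - quantile
    m <- 0L
    while (mean(null >= m) > 1 - quantile) m <- m + 1L
    list(minClusterSize = max(1L, m), null = as.integer(null))
}

#' Find significant temporal clusters
#'
#' Maximal runs of significant samples with length at least
#' `minClusterSize`, reported as time intervals.
#'
#' @param significant per-sample logical vector.
#' @param minClusterSize minimum run length.
#' @param times per-sample times (s); defaults to sample indices.
#' @return matrix with columns `start`, `end` (one row per cluster).
#' @export
findSignificantClusters <- function(significant, minClusterSize,
                                    times = seq_along(significant)) {
    r <- rle(as.logical(significant))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths >= minClusterSize
    out <- cbind(start = times[starts[keep]], end = times[ends[keep]])
    rownames(out) <- NULL
    out
}

#' Fraction of participants consistent with the group-level effect
#'
#' Per sample, the fraction of participants whose AV - V sign matches the
#' sign of the group mean difference.
#'
#' @inheritParams bootstrapAzDifference
#' @return per-sample fractions in `[0, 1]`.
#' @export
participantConsistency <- function(azV, azAV) {
    azV <- as.matrix(azV); azAV <- as.matrix(azAV)
    if (!all(dim(azV) == dim(azAV)))
        stop("azV and azAV must have matching dimensions")
    d <- azAV - azV
    g <- sign(colMeans(d))
    colMeans(sweep(sign(d), 2, g, "*") > 0)
}

#' Robust percentage-bend correlation
#'
#' Correlation that down-weights the `bend` fraction of the most extreme
#' points per margin via the bounded psi function of the percentage-bend
#' M-estimator, with a t-approximation p-value on n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors (n >= 5).
#' @param bend bending fraction in (0, 0.5); 0.2 down-weights 20% of points.
#' @return list with `r`, `p`, `n`.
#' @export
percentileBendCorrelation <- function(x, y, bend = 0.2) {
    n <- length(x)
    stopifnot(length(y) == n)
    if (n < 5) stop("need at least 5 pairs")
    if (bend <= 0 || bend >= 0.5) stop("bend must be in (0, 0.5)")
    bendOne <- function(v) {
        m <- sort(abs(v - median(v)))[floor((1 - bend) * n)]
        if (m <= 0) stop("zero robust scale in one margin")
        psi <- (v - median(v)) / m
        i1 <- sum(psi < -1); i2 <- sum(psi > 1)
        s <- v
        s[psi < -1 | psi > 1] <- 0
        pbos <- (sum(s) + m * (i2 - i1)) / (n - i1 - i2)
        a <- (v - pbos) / m
        pmin(pmax(a, -1), 1)
    }
    a <- bendOne(x)
    b <- bendOne(y)
    r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), n - 2)
    list(r = r, p = p, n = n)
}
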