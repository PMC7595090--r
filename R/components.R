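## Partitioning the significant decoding period into temporally distinct
## spatiotemporal components by k-means clustering of forward-model
## topographies, and window bookkeeping around the resulting transition.

.meanSilhouette <- function(x, labels) {
    mean(cluster::silhouette(labels, dist(x))[, "sil_width"])
}

## 3-window majority filter enforcing temporal contiguity of labels
.majoritySmooth <- function(labels) {
    n <- length(labels)
    if (n < 3L) return(labels)
    out <- labels
    for (i in 2:(n - 1)) {
        tri <- labels[(i - 1):(i + 1)]
        tab <- table(tri)
        if (max(tab) >= 2) out[i] <- as.integer(names(tab)[which.max(tab)])
    }
    out
}

#' Cluster window topographies and locate the component transition
#'
#' Runs seeded k-means (Euclidean metric, 20 restarts) on the per-window
#' forward models for each candidate number of clusters and selects `k*` by
#' the mean silhouette value. If even the best candidate shows no
#' substantial structure (mean silhouette below `silThreshold`) or all
#' topographies are identical, a single component (`k* = 1`) is reported
#' with no transition. Raw labels are made temporally contiguous by a
#' 3-window majority filter; the transition is the midpoint between the
#' last window of the first temporal cluster and the first window of the
#' next.
#'
#' @param forward windows x channels matrix of forward models (temporal
#'   order in rows).
#' @param centers per-window center times (s).
#' @param kCandidates candidate cluster numbers (>= 2; k = 1 is reached via
#'   the silhouette threshold).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart number of k-means restarts.
#' @param silThreshold minimum mean silhouette needed to accept k > 1.
#' @return list with `k`, `labels` (per window), `transition` (s, NA when
#'   k = 1), `silhouette` (named per candidate k).
#' @export
clusterTopographies <- function(forward, centers, kCandidates = 2:4,
                                seed = 1, nstart = 20, silThreshold = 0.25) {
    stopifnot(nrow(forward) >= 2L, nrow(forward) == length(centers))
    if (max(dist(forward)) < 1e-12)
        return(list(k = 1L, labels = rep(1L, nrow(forward)),
                    transition = NA_real_, silhouette = NULL))
    kCandidates <- kCandidates[kCandidates >= 2 &
                               kCandidates < nrow(forward)]
    if (!length(kCandidates)) stop("no usable candidate cluster numbers")
    set.seed(seed)
    fits <- lapply(kCandidates, function(k)
        kmeans(forward, centers = k, nstart = nstart, iter.max = 50))
    sil <- vapply(fits, function(f) .meanSilhouette(forward, f$cluster),
                  numeric(1))
    names(sil) <- kCandidates
    best <- which.max(sil)
    if (sil[best] < silThreshold)
        return(list(k = 1L, labels = rep(1L, nrow(forward)),
                    transition = NA_real_, silhouette = sil))
    labels <- .majoritySmooth(fits[[best]]$cluster)
    ## transition between the first temporal cluster and the next
    change <- which(diff(labels) != 0)
    transition <- if (length(change))
        (centers[change[1]] + centers[change[1] + 1]) / 2 else NA_real_
    list(k = as.integer(kCandidates[best]), labels = as.integer(labels),
         transition = transition, silhouette = sil)
}

#' Define the Early and Late component windows around a transition
#'
#' Places a guard gap centred on the transition time: the Early window runs
#' from the start of the significant range to `transition - gap/2`, the Late
#' window from `transition + gap/2` to the end of the range.
#'
#' @param transition transition time (s), inside `fullRange`.
#' @param gap guard gap (s), default 40 ms.
#' @param fullRange c(start, end) of the significant discrimination period.
#' @param k number of clusters the transition came from (stored).
#' @return a [ComponentWindows-class] object.
#' @examples
#' defineComponentWindows(0.38, 0.04, c(0.18, 0.60))  # 180-360 / 400-600 ms
#' @export
defineComponentWindows <- function(transition, gap = 0.040, fullRange,
                                   k = 2L) {
    if (transition <= fullRange[1] || transition >= fullRange[2])
        stop("transition must lie inside the full range")
    early <- c(fullRange[1], transition - gap / 2)
    late <- c(transition + gap / 2, fullRange[2])
    if (early[1] >= early[2] || late[1] >= late[2])
        stop("degenerate component window (start >= end)")
    new("ComponentWindows", transition = transition, gap = gap,
        early = early, late = late, k = as.integer(k))
}

#' Gaussian-mixture comparison by BIC
#'
#' Fits maximum-likelihood Gaussian mixtures with unequal variances for each
#' candidate number of components and compares them by
#' `BIC = -2 logLik + p log(n)` with `p = 3k - 1` free parameters
#' (k means, k variances, k - 1 weights); the lower BIC wins.
#'
#' @param values numeric vector (>= 10 values).
#' @param kCandidates candidate component counts, typically `c(1, 2)`.
#' @param seed RNG seed (the ML fit itself is deterministic; the seed guards
#'   any stochastic restart).
#' @return list with `bic` (named per k), `bestK`, `means` (per-component
#'   means of the winning fit), `fits` (the underlying model objects).
#' @export
fitGaussianMixtureBIC <- function(values, kCandidates = c(1, 2), seed = 1) {
    if (length(values) < 10) stop("need at least 10 values")
    set.seed(seed)
    fits <- lapply(kCandidates, function(k) {
        mn <- if (k == 1) "E" else "V"
        ## Mclust resolves helpers in the calling frame, so evaluate the
        ## call in an environment parented by the mclust namespace
        env <- new.env(parent = asNamespace("mclust"))
        assign(".values", values, envir = env)
        assign(".k", k, envir = env)
        assign(".mn", mn, envir = env)
        f <- tryCatch(
            eval(quote(Mclust(.values, G = .k, modelNames = .mn,
                              verbose = FALSE)), env),
            error = function(e) NULL)
        if (is.null(f) || is.null(f$loglik) || !is.finite(f$loglik))
            stop(sprintf("mixture fit with k = %d did not converge", k))
        f
    })
    n <- length(values)
    bic <- vapply(seq_along(kCandidates), function(i)
        -2 * fits[[i]]$loglik + (3 * kCandidates[i] - 1) * log(n),
        numeric(1))
    names(bic) <- kCandidates
    best <- which.min(bic)
    list(bic = bic, bestK = as.integer(kCandidates[best]),
         means = as.numeric(fits[[best]]$parameters$mean), fits = fits)
}
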