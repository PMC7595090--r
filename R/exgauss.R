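## Exponentially modified Gaussian (ex-Gaussian) density and mixtures for
## reaction-time bimodality testing.

#' Ex-Gaussian density
#'
#' Density of the sum of a Gaussian (mu, sigma) and an independent
#' exponential (mean tau). Evaluated on the log scale with an asymptotic
#' (Mills-ratio) branch for `sigma/tau` large, so the Gaussian limit
#' `tau -> 0` is reached without catastrophic cancellation.
#'
#' @param x quantiles.
#' @param mu,sigma Gaussian component mean and SD (`sigma > 0`).
#' @param tau exponential component mean (`tau > 0`).
#' @param log return log-density.
#' @return densities (or log-densities).
#' @export
dexgauss <- function(x, mu = 0, sigma = 1, tau = 1, log = FALSE) {
    stopifnot(sigma > 0, tau > 0)
    m <- (x - mu) / sigma
    r <- sigma / tau
    u <- r - m
    out <- numeric(length(x))
    asym <- u > 10
    if (any(asym)) {
        ua <- u[asym]
        s <- 1 - 1 / ua^2 + 3 / ua^4 - 15 / ua^6 + 105 / ua^8
        out[asym] <- dnorm(m[asym], log = TRUE) - log(sigma) -
            log(ua / r) + log(s)
    }
    if (any(!asym)) {
        md <- m[!asym]
        out[!asym] <- -log(tau) + r^2 / 2 - md * r +
            pnorm(md - r, log.p = TRUE)
    }
    if (log) out else exp(out)
}

.exgaussStart <- function(x, w = NULL) {
    if (is.null(w)) w <- rep(1, length(x))
    mw <- sum(w * x) / sum(w)
    sw <- sqrt(sum(w * (x - mw)^2) / sum(w))
    skw <- sum(w * (x - mw)^3) / sum(w) / sw^3
    tau <- sw * (max(skw, 0.01) / 2)^(1/3)
    tau <- min(max(tau, 0.05 * sw), 2 * sw)
    c(mu = mw - tau, sigma = max(sqrt(max(sw^2 - tau^2, (0.1 * sw)^2)),
                                 1e-3), tau = tau)
}

## weighted ML ex-Gaussian fit (partial M-step: bounded Nelder-Mead)
.exgaussFit <- function(x, w, start, maxit = 40) {
    nll <- function(p) {
        if (p[2] <= 0 || p[3] <= 0) return(1e10)
        -sum(w * dexgauss(x, p[1], p[2], p[3], log = TRUE))
    }
    fit <- optim(start, nll, method = "Nelder-Mead",
                 control = list(maxit = maxit))
    fit$par
}

#' Ex-Gaussian mixture comparison by BIC
#'
#' Fits 1- and 2-component ex-Gaussian mixtures by maximum likelihood
#' (expectation-maximization with quantile-split initialization and up to
#' `maxRestarts` seeded restarts on non-convergence) and compares them by
#' `BIC = -2 logLik + p log(n)` with `p = 4k - 1` free parameters per
#' k-component mixture (mu, sigma, tau per component plus k - 1 weights).
#' Intended for per-participant standardized (z-scored) RTs.
#'
#' @param rts standardized reaction times.
#' @param kCandidates candidate component counts, typically `c(1, 2)`.
#' @param seed RNG seed for restart jitter.
#' @param maxRestarts maximum EM restarts before giving up.
#' @param maxIter EM iteration cap per restart.
#' @return list with `bic` (named per k), `bestK`, `loglik` (named per k),
#'   `params` (winning parameter list).
#' @export
fitExGaussianMixtureBIC <- function(rts, kCandidates = c(1, 2), seed = 1,
                                    maxRestarts = 10, maxIter = 60) {
    x <- as.numeric(rts)
    n <- length(x)
    if (n < 20) stop("need at least 20 values")
    set.seed(seed)
    fitK <- function(k, attempt) {
        if (k == 1) {
            p <- .exgaussFit(x, rep(1, n), .exgaussStart(x), maxit = 200)
            p <- .exgaussFit(x, rep(1, n), p, maxit = 200)
            ll <- sum(dexgauss(x, p[1], p[2], p[3], log = TRUE))
            return(list(loglik = ll, pars = list(p), weights = 1,
                        converged = is.finite(ll)))
        }
        ## split at a jittered quantile for initialization
        q <- 0.5 + (attempt - 1) * runif(1, -0.15, 0.15)
        cut <- quantile(x, min(max(q, 0.2), 0.8))
        grp <- x > cut
        pars <- list(.exgaussStart(x[!grp]), .exgaussStart(x[grp]))
        wts <- c(mean(!grp), mean(grp))
        ll0 <- -Inf
        converged <- FALSE
        for (it in seq_len(maxIter)) {
            ld <- vapply(1:2, function(j)
                log(wts[j]) + dexgauss(x, pars[[j]][1], pars[[j]][2],
                                       pars[[j]][3], log = TRUE),
                numeric(n))
            mx <- pmax(ld[, 1], ld[, 2])
            lse <- mx + log(exp(ld[, 1] - mx) + exp(ld[, 2] - mx))
            resp <- exp(ld - lse)
            ll <- sum(lse)
            if (is.finite(ll) && abs(ll - ll0) < 1e-5 * (1 + abs(ll))) {
                converged <- TRUE
                break
            }
            ll0 <- ll
            wts <- pmax(colMeans(resp), 1e-4)
            wts <- wts / sum(wts)
            for (j in 1:2)
                pars[[j]] <- .exgaussFit(x, resp[, j], pars[[j]])
        }
        list(loglik = ll0, pars = pars, weights = wts, converged = converged)
    }
    fits <- lapply(kCandidates, function(k) {
        for (attempt in seq_len(maxRestarts)) {
            f <- fitK(k, attempt)
            if (f$converged || (k == 1 && is.finite(f$loglik))) return(f)
        }
        stop(sprintf(
            "ex-Gaussian mixture with k = %d failed to converge after %d restarts",
            k, maxRestarts))
    })
    ll <- vapply(fits, `[[`, numeric(1), "loglik")
    bic <- -2 * ll + (4 * kCandidates - 1) * log(n)
    names(bic) <- names(ll) <- kCandidates
    best <- which.min(bic)
    list(bic = bic, bestK = as.integer(kCandidates[best]), loglik = ll,
         params = fits[[best]])
}
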