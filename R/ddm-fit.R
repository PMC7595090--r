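## Hierarchical Bayesian estimation of the (neurally informed) DDM.
##
## Participant-level parameters are nested in group-level Gaussians per
## condition; hyperpriors follow the prior specification: group means
## nDT ~ U(0.01, 1), alpha ~ U(0.01, 3), beta ~ U(0.1, 0.9), regression
## coefficients ~ N(0, variance 3), all group SDs ~ U(0.01, 2).
##
## The sampler is adaptive Metropolis-within-Gibbs: componentwise Gaussian
## random-walk updates of each participant-condition parameter block
## (compiled sweep), plus a joint update of the drift-regression
## coefficients whose proposal is preconditioned by the inverse Gram matrix
## of the trial-level drift regressors (the coefficients are strongly
## correlated because both amplitude regressors carry the category sign),
## and exact conjugate/inverse-CDF Gibbs draws for the group means
## (truncated normal) and group SDs (truncated inverse-gamma). Proposal
## scales adapt toward ~35% acceptance during burn-in only.

.priorBounds <- list(g0 = NULL, g1 = NULL, g2 = NULL,
                     alpha = c(0.01, 3), beta = c(0.1, 0.9),
                     ndt = c(0.01, 1))
.gammaPriorVar <- 3
.sigmaBounds <- c(0.01, 2)

## truncated normal draw via inverse CDF
.rtnorm1 <- function(m, s, lo, hi) {
    plo <- pnorm(lo, m, s)
    phi <- pnorm(hi, m, s)
    if (phi - plo < 1e-12) return(min(max(m, lo), hi))
    qnorm(runif(1, plo, phi), m, s)
}

## group-SD draw: sigma^2 | theta, mu is truncated inverse-gamma
.rsigma1 <- function(th, mu) {
    n <- length(th)
    S2 <- sum((th - mu)^2)
    if (S2 < 1e-12) return(.sigmaBounds[1])
    shape <- (n - 1) / 2
    rate <- S2 / 2
    tlo <- 1 / .sigmaBounds[2]^2
    thi <- 1 / .sigmaBounds[1]^2
    plo <- pgamma(tlo, shape, rate)
    phi <- pgamma(thi, shape, rate)
    if (!is.finite(plo) || !is.finite(phi) || phi - plo < 1e-12) {
        s <- sqrt(S2 / max(n - 1, 1))
        return(min(max(s, .sigmaBounds[1]), .sigmaBounds[2]))
    }
    tau <- qgamma(runif(1, plo, phi), shape, rate)
    1 / sqrt(tau)
}

## drift-regressor design of one cell and the gamma indices it identifies
.gammaDesign <- function(cell, variant) {
    n <- length(cell$rt)
    one <- rep(1, n)
    switch(variant,
        scale_late = list(X = cbind(one, cell$yE, cell$yL * cell$coh),
                          idx = 1:3),
        scale_early = list(X = cbind(one, cell$yE * cell$coh, cell$yL),
                           idx = 1:3),
        scale_both = list(X = cbind(one, cell$yE * cell$coh,
                                    cell$yL * cell$coh), idx = 1:3),
        early_on_ndt = list(X = cbind(one, cell$yL * cell$coh),
                            idx = c(1L, 3L)),
        behavior_only = list(X = cbind(one, cell$sgn * cell$coh),
                             idx = c(1L, 2L)))
}

## crude per-cell MAP-ish starting values (Nelder-Mead on the penalized
## likelihood); deterministic given the data
.cellStart <- function(cell, code, active) {
    minRT <- min(cell$rt)
    g1start <- if (code == 4L) 0 else 0.5   # g1 shifts nDT in early_on_ndt
    start <- c(g0 = 0, g1 = g1start, g2 = 0.5, alpha = 1.2, beta = 0.5,
               ndt = 0.5 * minRT)
    obj <- function(p) {
        th <- start
        th[active] <- p
        ll <- .ddmLoglikCpp(cell$rt, cell$choice, cell$coh, cell$yE,
                            cell$yL, cell$sgn, code, as.numeric(th))
        if (!is.finite(ll)) return(1e10)
        -(ll + sum(dnorm(th[1:3], 0, 3, log = TRUE)))
    }
    fit <- tryCatch(optim(start[active], obj, method = "Nelder-Mead",
                          control = list(maxit = 300)),
                    error = function(e) NULL)
    th <- start
    if (!is.null(fit) && fit$value < 1e9) th[active] <- fit$par
    th["alpha"] <- min(max(th["alpha"], 0.2), 4)
    th["beta"] <- min(max(th["beta"], 0.15), 0.85)
    th["ndt"] <- min(max(th["ndt"], 0.05), 0.95 * minRT)
    th
}

#' Sample the hierarchical DDM posterior
#'
#' Draws from the posterior of the hierarchical drift-diffusion model with
#' the requested drift-regression variant by adaptive
#' Metropolis-within-Gibbs MCMC. Defaults mirror the conventional sampling
#' protocol (5 chains of 5500 samples, 500 burn-in, thinning 50); reduced
#' settings are appropriate for tests and model screening.
#'
#' @param table trial table (see [generateSessionDesign()]) carrying
#'   `y_early`/`y_late` columns for neural variants.
#' @param amplitudes optional data.frame supplying the amplitude columns.
#' @param variant drift-regression variant (see [nhddmLogLik()]).
#' @param nChains number of chains (>= 2 for convergence diagnostics).
#' @param nSamples total MCMC samples per chain.
#' @param burnIn samples discarded from the start of each chain.
#' @param thin retain every `thin`-th post-burn-in sample.
#' @param seed RNG seed; chain seeds are derived deterministically.
#' @param standardize z-score amplitudes within participant and condition
#'   so regression weights are comparable across participants.
#' @param shareHyperpriors if `TRUE` the regression-coefficient hyperpriors
#'   are pooled across conditions (default: separate per condition).
#' @param adaptInterval proposal-scale adaptation interval (burn-in only).
#' @return a [PosteriorSamples-class] object.
#' @export
samplePosterior <- function(table, amplitudes = NULL,
                            variant = "scale_late", nChains = 5,
                            nSamples = 5500, burnIn = 500, thin = 50,
                            seed = 1, standardize = TRUE,
                            shareHyperpriors = FALSE, adaptInterval = 25) {
    if (nChains < 2) stop("need at least 2 chains for convergence checks")
    if (burnIn >= nSamples) stop("burnIn must be smaller than nSamples")
    prep <- .prepNhddmData(table, amplitudes, variant, standardize)
    variant <- prep$variant
    code <- prep$code
    active <- .variantActive(variant)
    parts <- prep$participants
    conds <- prep$conditions
    P <- length(parts); K <- length(conds)
    cellIdx <- matrix(NA_integer_, P, K)
    for (i in seq_along(prep$cells)) {
        cell <- prep$cells[[i]]
        cellIdx[match(cell$participant, parts),
                match(cell$condition, conds)] <- i
    }
    if (anyNA(cellIdx))
        stop("every participant must contribute trials to every condition")
    ## data-driven starting center, shared across chains (jittered per chain)
    startTheta <- array(0, c(P, K, 6))
    for (s in seq_len(P)) for (k in seq_len(K))
        startTheta[s, k, ] <- .cellStart(prep$cells[[cellIdx[s, k]]],
                                         code, active)
    ## gamma-block proposal geometry per cell (deterministic, data-based)
    gammaGeom <- lapply(prep$cells, function(cell) {
        gd <- .gammaDesign(cell, variant)
        k <- ncol(gd$X)
        Sg <- solve(crossprod(gd$X) / nrow(gd$X) + diag(1e-8, k))
        list(Lt = t(chol(Sg)), idx = gd$idx, k = k)
    })
    nRet <- floor((nSamples - burnIn) / thin)
    if (nRet < 2) stop("settings leave fewer than 2 retained samples")
    groupCols <- as.vector(outer(.paramNames6[active], conds,
        function(p, k) paste0("mu_", p, "_", k)))
    groupCols <- c(groupCols, sub("^mu_", "sigma_", groupCols))
    partCols <- unlist(lapply(seq_len(K), function(k)
        unlist(lapply(seq_len(P), function(s)
            paste0(.paramNames6[active], "_s", parts[s], "_", conds[k])))))
    allCols <- c(groupCols, partCols)
    gammaIdx <- intersect(active, 1:3)

    runChain <- function(chain) {
        set.seed((seed * 7L + chain * 104729L) %% 2147483647L)
        theta <- startTheta
        for (s in seq_len(P)) for (k in seq_len(K)) {
            jit <- c(0.1, 0.1, 0.15, 0.1, 0.03, 0.02)
            theta[s, k, active] <- theta[s, k, active] +
                rnorm(length(active), 0, jit[active])
            theta[s, k, 4] <- max(theta[s, k, 4], 0.2)
            theta[s, k, 5] <- min(max(theta[s, k, 5], 0.12), 0.88)
            cell <- prep$cells[[cellIdx[s, k]]]
            theta[s, k, 6] <- min(max(theta[s, k, 6], 0.05),
                                  0.95 * min(cell$rt))
        }
        mu <- apply(theta, c(2, 3), mean)          # K x 6
        sigma <- apply(theta, c(2, 3), sd)
        sigma[!is.finite(sigma) | sigma < 0.05] <- 0.05
        sigma <- pmin(pmax(sigma, .sigmaBounds[1]), .sigmaBounds[2])
        for (p in intersect(active, 4:6)) {
            b <- .priorBounds[[.paramNames6[p]]]
            mu[, p] <- pmin(pmax(mu[, p], b[1]), b[2])
        }
        ll <- matrix(NA_real_, P, K)
        for (s in seq_len(P)) for (k in seq_len(K)) {
            cell <- prep$cells[[cellIdx[s, k]]]
            ll[s, k] <- .cellLoglik(cell, code, theta[s, k, ])
            if (!is.finite(ll[s, k])) {
                ## conservative fallback starting point
                theta[s, k, ] <- c(0, 0, 0, 1.2, 0.5, 0.4 * min(cell$rt))
                ll[s, k] <- .cellLoglik(cell, code, theta[s, k, ])
            }
        }
        if (any(!is.finite(ll)))
            stop("invalid starting state (non-finite likelihood)")
        scales <- array(rep(c(0.15, 0.15, 0.3, 0.15, 0.05, 0.02),
                            each = P * K), c(P, K, 6))
        acc <- array(0L, c(P, K, 6))
        tauJ <- matrix(0.3, P, K)        # joint gamma proposal scale
        accJ <- matrix(0L, P, K)
        tauT <- matrix(0.1, K, 6)        # group translation proposal scale
        accT <- matrix(0L, K, 6)
        tauS <- matrix(0.1, K, 6)        # group scale-expansion proposal
        accS <- matrix(0L, K, 6)
        draws <- matrix(NA_real_, nRet, length(allCols),
                        dimnames = list(NULL, allCols))
        row <- 0L
        for (it in seq_len(nSamples)) {
            for (s in seq_len(P)) for (k in seq_len(K)) {
                cell <- prep$cells[[cellIdx[s, k]]]
                res <- .mhSweepCpp(cell$rt, cell$choice, cell$coh, cell$yE,
                                   cell$yL, cell$sgn, code, theta[s, k, ],
                                   mu[k, ], sigma[k, ], scales[s, k, ],
                                   active, ll[s, k])
                theta[s, k, ] <- res$theta
                ll[s, k] <- res$ll
                acc[s, k, ] <- acc[s, k, ] + res$acc
                ## joint preconditioned update of the drift coefficients
                geom <- gammaGeom[[cellIdx[s, k]]]
                gi <- geom$idx
                g <- theta[s, k, gi]
                gProp <- g + tauJ[s, k] *
                    drop(geom$Lt %*% rnorm(geom$k)) / sqrt(length(cell$rt))
                th2 <- theta[s, k, ]
                th2[gi] <- gProp
                newll <- .cellLoglik(cell, code, th2)
                if (is.finite(newll)) {
                    logr <- newll - ll[s, k] +
                        sum(dnorm(gProp, mu[k, gi], sigma[k, gi],
                                  log = TRUE)) -
                        sum(dnorm(g, mu[k, gi], sigma[k, gi], log = TRUE))
                    if (log(runif(1)) < logr) {
                        theta[s, k, gi] <- gProp
                        ll[s, k] <- newll
                        accJ[s, k] <- accJ[s, k] + 1L
                    }
                }
            }
            ## group-level Gibbs updates
            for (p in active) {
                pn <- .paramNames6[p]
                if (shareHyperpriors && p %in% gammaIdx) {
                    th <- as.vector(theta[, , p])
                    pv <- 1 / (length(th) / sigma[1, p]^2 +
                               1 / .gammaPriorVar)
                    m <- rnorm(1, pv * sum(th) / sigma[1, p]^2, sqrt(pv))
                    sg <- .rsigma1(th, m)
                    mu[, p] <- m
                    sigma[, p] <- sg
                } else {
                    for (k in seq_len(K)) {
                        th <- theta[, k, p]
                        b <- .priorBounds[[pn]]
                        if (is.null(b)) {
                            pv <- 1 / (P / sigma[k, p]^2 + 1 / .gammaPriorVar)
                            mu[k, p] <- rnorm(1, pv * sum(th) / sigma[k, p]^2,
                                              sqrt(pv))
                        } else {
                            mu[k, p] <- .rtnorm1(mean(th),
                                                 sigma[k, p] / sqrt(P),
                                                 b[1], b[2])
                        }
                        sigma[k, p] <- .rsigma1(th, mu[k, p])
                    }
                }
            }
            ## translation moves: shift a whole participant column and its
            ## group mean together (group-prior invariant), defeating the
            ## slow random walk of correlated group locations
            for (p in gammaIdx) {
                pn <- .paramNames6[p]
                for (k in seq_len(K)) {
                    del <- tauT[k, p] * rnorm(1)
                    muNew <- mu[k, p] + del
                    logr <- dnorm(muNew, 0, sqrt(.gammaPriorVar), log = TRUE) -
                        dnorm(mu[k, p], 0, sqrt(.gammaPriorVar), log = TRUE)
                    llNew <- numeric(P)
                    ok <- TRUE
                    for (s in seq_len(P)) {
                        th2 <- theta[s, k, ]
                        th2[p] <- th2[p] + del
                        llNew[s] <- .cellLoglik(
                            prep$cells[[cellIdx[s, k]]], code, th2)
                        if (!is.finite(llNew[s])) { ok <- FALSE; break }
                    }
                    if (ok && log(runif(1)) <
                        logr + sum(llNew) - sum(ll[, k])) {
                        theta[, k, p] <- theta[, k, p] + del
                        mu[k, p] <- muNew
                        ll[, k] <- llNew
                        accT[k, p] <- accT[k, p] + 1L
                    }
                }
            }
            ## scale-expansion moves: multiply a participant column's spread
            ## around its group mean and the group SD by a common factor
            ## (participant-prior terms cancel against the Jacobian up to a
            ## single log c), releasing the scale-direction funnel
            for (p in gammaIdx) {
                for (k in seq_len(K)) {
                    cf <- exp(tauS[k, p] * rnorm(1))
                    sigNew <- sigma[k, p] * cf
                    if (sigNew < .sigmaBounds[1] ||
                        sigNew > .sigmaBounds[2]) next
                    thNew <- mu[k, p] + cf * (theta[, k, p] - mu[k, p])
                    llNew <- numeric(P)
                    ok <- TRUE
                    for (s in seq_len(P)) {
                        th2 <- theta[s, k, ]
                        th2[p] <- thNew[s]
                        llNew[s] <- .cellLoglik(
                            prep$cells[[cellIdx[s, k]]], code, th2)
                        if (!is.finite(llNew[s])) { ok <- FALSE; break }
                    }
                    if (ok && log(runif(1)) <
                        sum(llNew) - sum(ll[, k]) + log(cf)) {
                        theta[, k, p] <- thNew
                        sigma[k, p] <- sigNew
                        ll[, k] <- llNew
                        accS[k, p] <- accS[k, p] + 1L
                    }
                }
            }
            if (it <= burnIn && it %% adaptInterval == 0) {
                rate <- acc / adaptInterval
                scales <- scales * exp(0.8 * (rate - 0.35))
                scales <- pmin(pmax(scales, 1e-4), 5)
                acc[] <- 0L
                tauJ <- pmin(pmax(
                    tauJ * exp(0.8 * (accJ / adaptInterval - 0.3)),
                    1e-3), 20)
                accJ[] <- 0L
                tauT <- pmin(pmax(
                    tauT * exp(0.8 * (accT / adaptInterval - 0.3)),
                    1e-3), 5)
                accT[] <- 0L
                tauS <- pmin(pmax(
                    tauS * exp(0.8 * (accS / adaptInterval - 0.3)),
                    1e-3), 3)
                accS[] <- 0L
            }
            if (it > burnIn && (it - burnIn) %% thin == 0) {
                row <- row + 1L
                g <- c(t(mu[, active, drop = FALSE]),
                       t(sigma[, active, drop = FALSE]))
                pp <- unlist(lapply(seq_len(K), function(k)
                    as.vector(t(matrix(theta[, k, active], nrow = P)))))
                draws[row, ] <- c(g, pp)
            }
        }
        draws[seq_len(row), , drop = FALSE]
    }
    chains <- lapply(seq_len(nChains), runChain)
    obj <- new("PosteriorSamples", draws = chains, paramNames = allCols,
               groupNames = groupCols, rhat = numeric(0),
               dicValue = NA_real_,
               settings = list(variant = variant, nChains = nChains,
                               nSamples = nSamples, burnIn = burnIn,
                               thin = thin, seed = seed,
                               standardize = standardize),
               model = list(prep = prep, cellIdx = cellIdx,
                            active = active, parts = parts, conds = conds))
    obj@rhat <- gelmanRubin(obj)
    obj
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor comparing within-chain and between-chain
#' variance, per parameter. Parameters with zero within-chain variance are
#' flagged as `NA` with a warning.
#'
#' @param samples a [PosteriorSamples-class] object.
#' @param parameters parameter names to diagnose (default: all group-level
#'   means and SDs).
#' @return named vector of R-hat values.
#' @export
gelmanRubin <- function(samples, parameters = groupParameterNames(samples)) {
    chains <- samples@draws
    if (length(chains) < 2) stop("need at least 2 chains")
    n <- nrow(chains[[1]])
    if (n < 10) stop("need at least 10 retained draws per chain")
    out <- vapply(parameters, function(p) {
        x <- vapply(chains, function(ch) ch[, p], numeric(n))
        W <- mean(apply(x, 2, var))
        B <- n * var(colMeans(x))
        if (W <= 0) return(NA_real_)
        sqrt(((n - 1) / n * W + B / n) / W)
    }, numeric(1))
    if (anyNA(out))
        warning("zero within-chain variance for: ",
                paste(names(out)[is.na(out)], collapse = ", "))
    out
}

## total log-likelihood of one stacked-draw row (participant-level params)
.drawLoglik <- function(samples, drawRow) {
    m <- samples@model
    total <- 0
    for (i in seq_along(m$prep$cells)) {
        cell <- m$prep$cells[[i]]
        th <- numeric(6)
        for (p in m$active) {
            cn <- paste0(.paramNames6[p], "_s", cell$participant, "_",
                         cell$condition)
            th[p] <- drawRow[[cn]]
        }
        total <- total + .cellLoglik(cell, m$prep$code, th)
    }
    total
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with deviance `D = -2 logLik`, `Dbar` the posterior
#' mean deviance and `pD = Dbar - D(thetaHat)` the effective number of
#' parameters at the posterior-mean (plug-in) participant parameters.
#' Lower values favour the better fit/complexity trade-off.
#'
#' @param samples a [PosteriorSamples-class] object.
#' @param loglikFn optional override: a function mapping one named draw row
#'   to a total log-likelihood.
#' @return list with `dic`, `pD`, `Dbar`, `Dhat`.
#' @export
dic <- function(samples, loglikFn = NULL) {
    if (is.null(loglikFn)) loglikFn <- function(row) .drawLoglik(samples, row)
    draws <- posteriorDraws(samples)
    rows <- lapply(seq_len(nrow(draws)), function(i)
        as.list(draws[i, , drop = TRUE]))
    ll <- vapply(rows, loglikFn, numeric(1))
    if (any(!is.finite(ll)))
        stop("non-finite deviance for draw(s): ",
             paste(head(which(!is.finite(ll)), 10), collapse = ", "))
    Dbar <- mean(-2 * ll)
    mean_row <- as.list(colMeans(draws))
    Dhat <- -2 * loglikFn(mean_row)
    if (!is.finite(Dhat))
        stop("non-finite deviance at the posterior-mean plug-in")
    pD <- Dbar - Dhat
    list(dic = Dbar + pD, pD = pD, Dbar = Dbar, Dhat = Dhat)
}

#' Compare a group-level parameter between conditions
#'
#' Reports the posterior distribution of the group-level AV - V difference
#' of a parameter, its two-sided posterior tail probability, and a t
#' statistic computed on the population-level draws (a "hierarchical" t
#' test honouring the model's group structure).
#'
#' @param samples a [PosteriorSamples-class] object.
#' @param parameter base parameter name: one of `"g0"`, `"g1"`, `"g2"`,
#'   `"alpha"`, `"beta"`, `"ndt"`.
#' @param conditions length-2 condition labels, difference is
#'   `conditions[2] - conditions[1]`.
#' @return list with `mean`, `ci` (2.5-97.5%), `pTail` (posterior
#'   probability that the difference is positive; ~0.5 for identical
#'   posteriors), `pTwoSided` (two-sided tail probability), `tStat`,
#'   `draws`.
#' @export
compareConditions <- function(samples, parameter,
                              conditions = c("V", "AV")) {
    cols <- paste0("mu_", parameter, "_", conditions)
    missing <- setdiff(cols, samples@paramNames)
    if (length(missing))
        stop("parameter not estimated in condition(s): ",
             paste(missing, collapse = ", "))
    draws <- posteriorDraws(samples)
    d <- draws[, cols[2]] - draws[, cols[1]]
    p <- mean(d > 0)
    list(mean = mean(d),
         ci = unname(quantile(d, c(0.025, 0.975))),
         pTail = p,
         pTwoSided = 2 * min(p, 1 - p),
         tStat = mean(d) / sd(d),
         draws = d)
}

#' Posterior predictive fit of choices and RTs
#'
#' Simulates choices and RTs from a subsample of posterior draws, summarizes
#' observed and predicted data as quantile-probability vectors (per
#' condition: choice fractions per coherence level and RT quantiles per
#' choice) and reports the squared correlation between them.
#'
#' @param samples a [PosteriorSamples-class] object.
#' @param table the trial table the model was fitted to.
#' @param nSim number of posterior draws to simulate from.
#' @param seed RNG seed.
#' @param dt Euler step for the predictive simulations (s).
#' @param deadline response deadline applied to simulations (s).
#' @return list with `ok`, `r2`, `observed`, `predicted` (named vectors),
#'   or `ok = FALSE` with a `message` for degenerate input.
#' @export
posteriorPredictiveFit <- function(samples, table, nSim = 30, seed = 1,
                                   dt = 1e-3, deadline = 1.5) {
    m <- samples@model
    qs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
    summarize <- function(cellsData) {
        out <- c()
        for (k in m$conds) {
            sub <- cellsData[cellsData$condition == k, , drop = FALSE]
            for (cv in sort(unique(cellsData$coh)))
                out <- c(out, mean(sub$choice[sub$coh == cv] == 1))
            for (ch in c(1, 0)) {
                r <- sub$rt[sub$choice == ch]
                if (length(r) < 5 || sd(r) == 0) return(NULL)
                out <- c(out, quantile(r, qs))
            }
        }
        out
    }
    obs <- do.call(rbind, lapply(m$prep$cells, function(cell)
        data.frame(condition = cell$condition, coh = cell$coh,
                   choice = cell$choice, rt = cell$rt)))
    obsVec <- summarize(obs)
    if (is.null(obsVec))
        return(list(ok = FALSE,
                    message = "degenerate observed data: too few RTs or zero RT variance in a cell"))
    set.seed(seed)
    draws <- posteriorDraws(samples)
    pick <- sample.int(nrow(draws), min(nSim, nrow(draws)))
    sims <- list()
    for (d in pick) {
        row <- as.list(draws[d, , drop = TRUE])
        for (i in seq_along(m$prep$cells)) {
            cell <- m$prep$cells[[i]]
            th <- numeric(6)
            for (p in m$active)
                th[p] <- row[[paste0(.paramNames6[p], "_s",
                                     cell$participant, "_", cell$condition)]]
            code <- m$prep$code
            drift <- switch(code,
                th[1] + th[2] * cell$yE + th[3] * cell$yL * cell$coh,
                th[1] + th[2] * cell$yE * cell$coh + th[3] * cell$yL,
                th[1] + th[2] * cell$yE * cell$coh + th[3] * cell$yL * cell$coh,
                th[1] + th[3] * cell$yL * cell$coh,
                th[1] + th[2] * cell$sgn * cell$coh)
            ndt <- if (code == 4L) th[6] + th[2] * cell$yE else th[6]
            sim <- .simWienerCpp(drift, th[4], th[5], mean(pmax(ndt, 0.01)),
                                 dt, deadline)
            keep <- !is.na(sim$choice)
            if (any(keep))
                sims[[length(sims) + 1L]] <- data.frame(
                    condition = cell$condition, coh = cell$coh[keep],
                    choice = sim$choice[keep], rt = sim$rt[keep])
        }
    }
    predVec <- summarize(do.call(rbind, sims))
    if (is.null(predVec))
        return(list(ok = FALSE,
                    message = "degenerate predictive simulations"))
    list(ok = TRUE, r2 = cor(obsVec, predVec)^2,
         observed = obsVec, predicted = predVec)
}
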