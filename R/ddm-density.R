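## Wiener first-passage-time density and simulator.

.checkDDMParams <- function(delta, alpha, beta, ndt) {
    if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
    if (!is.finite(beta) || beta <= 0 || beta >= 1)
        stop("beta must lie in (0, 1)")
    if (!is.finite(ndt) || ndt < 0) stop("ndt must be non-negative")
    if (!is.finite(delta)) stop("delta must be finite")
    invisible(TRUE)
}

#' Wiener first-passage-time density
#'
#' Density of the time at which a Wiener diffusion with drift `delta`,
#' absorbing boundaries 0 and `alpha` and relative starting point `beta`
#' (start `beta * alpha`) first hits the named boundary, shifted by the
#' nondecision time `ndt`. Positive drift favours the upper boundary (the
#' "face" choice). Evaluated by a truncated series with the standard
#' small-time / large-time switching rule at absolute tolerance `eps`;
#' `t <= ndt` yields density 0.
#'
#' @param t times (s), RT scale (including `ndt`).
#' @param delta drift rate (evidence/s, signed).
#' @param alpha boundary separation (> 0).
#' @param beta relative starting point in (0, 1).
#' @param ndt nondecision time (s, >= 0).
#' @param boundary `"upper"` or `"lower"`.
#' @param eps series truncation tolerance.
#' @return densities (1/s), non-negative.
#' @export
wienerFPTDensity <- function(t, delta, alpha, beta = 0.5, ndt = 0,
                             boundary = c("upper", "lower"), eps = 1e-10) {
    boundary <- match.arg(boundary)
    .checkDDMParams(delta, alpha, beta, ndt)
    .wfptDensityCpp(as.numeric(t), delta, alpha, beta, ndt,
                    boundary == "upper", eps)
}

#' Simulate Wiener first-passage times
#'
#' Euler-Maruyama simulation (unit diffusion coefficient) with a
#' within-step Brownian-bridge boundary-crossing check. Trials not absorbed
#' before `deadline` return `NA` RT and choice.
#'
#' @param n number of trials (ignored when `delta` has length > 1).
#' @param delta drift rate; scalar or per-trial vector.
#' @param alpha,beta,ndt diffusion parameters as in [wienerFPTDensity()].
#' @param dt Euler step (s).
#' @param deadline response deadline (s), `Inf` for none.
#' @param seed optional RNG seed.
#' @return data.frame with columns `rt` (s) and `boundary`
#'   ("upper"/"lower"/NA).
#' @export
simulateWienerFPT <- function(n, delta, alpha, beta = 0.5, ndt = 0,
                              dt = 1e-4, deadline = Inf, seed = NULL) {
    .checkDDMParams(delta[1], alpha, beta, ndt)
    if (!is.null(seed)) set.seed(seed)
    drift <- if (length(delta) > 1) as.numeric(delta) else rep(delta, n)
    sim <- .simWienerCpp(drift, alpha, beta, ndt, dt, deadline)
    data.frame(rt = sim$rt,
               boundary = ifelse(is.na(sim$choice), NA,
                                 ifelse(sim$choice == 1, "upper", "lower")),
               stringsAsFactors = FALSE)
}
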