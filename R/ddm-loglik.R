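## Trial-level likelihood of the neurally informed hierarchical DDM and its
## comparison variants.
##
## Drift-rate regressions (C = phase coherence as a proportion, y_E / y_L =
## single-trial Early / Late component amplitudes):
##   scale_late    delta = g0 + g1*yE + g2*yL*C
##   scale_early   delta = g0 + g1*yE*C + g2*yL
##   scale_both    delta = g0 + g1*yE*C + g2*yL*C
##   early_on_ndt  delta = g0 + g2*yL*C and nDT_i = ndt + g1*yE
##   behavior_only delta = g0 + g1*s*C with s = +1 face / -1 car stimuli
##                 (condition-level parameters, drift linear in coherence)

.ddmVariants <- c(scale_late = 1L, scale_early = 2L, scale_both = 3L,
                  early_on_ndt = 4L, behavior_only = 5L)

.variantCode <- function(variant) {
    variant <- match.arg(variant, names(.ddmVariants))
    .ddmVariants[[variant]]
}

.variantActive <- function(variant) {
    if (variant == "behavior_only") c(1L, 2L, 4L, 5L, 6L) else 1:6
}

.paramNames6 <- c("g0", "g1", "g2", "alpha", "beta", "ndt")

## Prepare per-(participant, condition) cells from a trial table.
## Requires columns participant_id, modality, category, coherence, choice,
## rt and (for neural variants) y_early / y_late. Excluded trials and
## non-responses are dropped.
.prepNhddmData <- function(table, amplitudes = NULL,
                           variant = "scale_late", standardize = TRUE) {
    variant <- match.arg(variant, names(.ddmVariants))
    tab <- table
    if (!is.null(amplitudes)) {
        if (is.data.frame(amplitudes)) {
            tab$y_early <- amplitudes$y_early
            tab$y_late <- amplitudes$y_late
        } else stop("amplitudes must be NULL or a data.frame with y_early/y_late")
    }
    if ("excluded" %in% names(tab)) tab <- tab[!tab$excluded, , drop = FALSE]
    tab <- tab[tab$choice != "none" & !is.na(tab$rt), , drop = FALSE]
    neural <- variant != "behavior_only"
    if (neural && !all(c("y_early", "y_late") %in% names(tab)))
        stop("neural variants need y_early / y_late amplitudes")
    keys <- unique(tab[, c("participant_id", "modality")])
    keys <- keys[order(keys$participant_id, keys$modality), ]
    cells <- lapply(seq_len(nrow(keys)), function(i) {
        sub <- tab[tab$participant_id == keys$participant_id[i] &
                   tab$modality == keys$modality[i], , drop = FALSE]
        yE <- if (neural) sub$y_early else numeric(nrow(sub))
        yL <- if (neural) sub$y_late else numeric(nrow(sub))
        if (neural && standardize) {
            yE <- as.numeric(scale(yE))
            yL <- as.numeric(scale(yL))
        }
        list(participant = keys$participant_id[i],
             condition = keys$modality[i],
             rt = as.numeric(sub$rt),
             choice = as.integer(sub$choice == "face"),
             coh = as.numeric(sub$coherence) / 100,
             yE = as.numeric(yE), yL = as.numeric(yL),
             sgn = as.integer(ifelse(sub$category == "face", 1L, -1L)))
    })
    list(cells = cells,
         participants = sort(unique(keys$participant_id)),
         conditions = sort(unique(keys$modality), decreasing = TRUE),
         variant = variant, code = .ddmVariants[[variant]])
}

.cellLoglik <- function(cell, code, theta)
    .ddmLoglikCpp(cell$rt, cell$choice, cell$coh, cell$yE, cell$yL,
                  cell$sgn, code, as.numeric(theta))

#' Log-likelihood of the neurally informed DDM
#'
#' Sum over non-excluded trials of the log Wiener first-passage density at
#' the chosen boundary, with the trial drift rate given by the active
#' regression variant (see the variant table in the package vignette).
#' Trials with `RT <= nDT` contribute `-Inf` (returned, not raised).
#'
#' @param table trial table with behavioural columns and, for neural
#'   variants, `y_early`/`y_late` amplitude columns.
#' @param params named list (or data.frame) of per-participant-condition
#'   parameter vectors: either a single numeric vector
#'   `c(g0, g1, g2, alpha, beta, ndt)` applied to every cell, or a
#'   data.frame with columns `participant_id`, `condition` and those six
#'   parameters.
#' @param variant one of `"scale_late"`, `"scale_early"`, `"scale_both"`,
#'   `"early_on_ndt"`, `"behavior_only"`.
#' @param amplitudes optional data.frame supplying `y_early`/`y_late`.
#' @param standardize z-score amplitudes within participant and condition.
#' @return the total log-likelihood (may be `-Inf`).
#' @export
nhddmLogLik <- function(table, params, variant = "scale_late",
                        amplitudes = NULL, standardize = FALSE) {
    prep <- .prepNhddmData(table, amplitudes, variant, standardize)
    total <- 0
    for (cell in prep$cells) {
        th <- if (is.data.frame(params)) {
            r <- params[params$participant_id == cell$participant &
                        params$condition == cell$condition, ]
            if (nrow(r) != 1L)
                stop(sprintf("missing parameters for participant %s / %s",
                             cell$participant, cell$condition))
            as.numeric(r[, .paramNames6])
        } else as.numeric(params)
        total <- total + .cellLoglik(cell, prep$code, th)
    }
    total
}
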