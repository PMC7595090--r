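# Shared fixtures, generated in code: small synthetic studies at sizes that
# keep the suite fast while preserving the generative structure.

smallTruth <- function(nParticipants = 2, nChannels = 6, seed = 3,
                       noiseSD = 2, ...)
    makeSyntheticTruth(nParticipants = nParticipants,
                       nChannels = nChannels, seed = seed,
                       noiseSD = noiseSD, ...)

smallSession <- function(truth, nTrials = 64, seed = 1, participant = 1) {
    d <- generateSessionDesign(nTrials, nTrials / 4, seed = seed,
                               participant = participant)
    simulateDDMDataset(d, truth, seed = seed + 100)
}

smallEpochs <- function(table, truth, fs = 100, seed = 5)
    synthesizeEEGEpochs(table, truth, fs = fs,
                        epochWindow = c(-0.1, 0.8), seed = seed)

# multi-participant behavioural dataset for hierarchical fits
behavDataset <- function(nParticipants = 6, nTrials = 160, seed = 11,
                         truth = NULL) {
    if (is.null(truth))
        truth <- makeSyntheticTruth(nParticipants = nParticipants,
                                    nChannels = 4, seed = seed)
    tab <- do.call(rbind, lapply(seq_len(nParticipants), function(p) {
        d <- generateSessionDesign(nTrials, nTrials / 4, seed = seed + p,
                                   participant = p)
        simulateDDMDataset(d, truth, seed = seed + 100 + p)
    }))
    list(table = tab, truth = truth)
}
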