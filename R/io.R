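## Plain-text serialization of the pipeline's containers: trial tables as
## CSV with a documented header, EEG epochs as a JSON metadata file plus a
## long-format CSV matrix, and ground truth as JSON.

.trialTableColumns <- c("trial_id", "participant_id", "block", "modality",
                        "category", "coherence", "choice", "accuracy",
                        "rt", "excluded", "exclusion_reason")

#' Read / write a trial table as CSV
#'
#' The CSV header carries the documented trial-table columns (see
#' [generateSessionDesign()]); extra columns such as the generative latents
#' `y_early`/`y_late` round-trip untouched.
#'
#' @param path file path.
#' @return `readTrialTable` returns the trial table `data.frame`.
#' @export
readTrialTable <- function(path) {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(.trialTableColumns, names(tab))
    if (length(missing))
        stop("not a trial table; missing columns: ",
             paste(missing, collapse = ", "))
    tab
}

#' @rdname readTrialTable
#' @param table trial table to write.
#' @export
writeTrialTable <- function(table, path) {
    write.csv(table, path, row.names = FALSE)
    invisible(path)
}

#' Read / write epoched EEG as a text container
#'
#' An `EEGEpochs` object is stored as `<stem>.json` (fs, lock, t0, channel
#' labels, dimensions) plus `<stem>.csv` holding the tensor flattened to
#' (trials * channels) rows x samples columns, channels fastest.
#'
#' @param stem path stem without extension.
#' @return `readEEGEpochs` returns an [EEGEpochs-class] object.
#' @export
readEEGEpochs <- function(stem) {
    meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
    m <- as.matrix(read.csv(paste0(stem, ".csv"), header = FALSE))
    d <- as.integer(meta$dim)
    data <- aperm(array(t(m), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
    EEGEpochs(data, fs = meta$fs, lock = meta$lock, t0 = meta$t0,
              channels = as.character(meta$channels))
}

#' @rdname readEEGEpochs
#' @param epochs an [EEGEpochs-class] object.
#' @export
writeEEGEpochs <- function(epochs, stem) {
    d <- dim(epochs@data)
    jsonlite::write_json(
        list(fs = epochs@fs, lock = epochs@lock, t0 = epochs@t0,
             channels = epochs@channels, dim = d),
        paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
    m <- matrix(aperm(epochs@data, c(3, 2, 1)), nrow = d[3])
    write.table(t(m), paste0(stem, ".csv"), sep = ",", row.names = FALSE,
                col.names = FALSE)
    invisible(stem)
}

#' Read / write synthetic ground truth as JSON
#'
#' @param path file path.
#' @return `readSyntheticTruth` returns a [SyntheticTruth-class] object.
#' @export
readSyntheticTruth <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("SyntheticTruth", params = as.data.frame(x$params),
        aEarly = as.numeric(x$aEarly), aLate = as.numeric(x$aLate),
        timing = as.list(x$timing), noise = as.list(x$noise),
        seed = as.integer(x$seed))
}

#' @rdname readSyntheticTruth
#' @param truth a [SyntheticTruth-class] object.
#' @export
writeSyntheticTruth <- function(truth, path) {
    jsonlite::write_json(
        list(params = truth@params, aEarly = truth@aEarly,
             aLate = truth@aLate, timing = truth@timing,
             noise = truth@noise, seed = truth@seed),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
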