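## Preprocessing of the continuous recording and fixation-locked epoching.
## Deliberately minimal: causal filters only (the chain must be usable
## online), no high-pass anywhere in the feature path, no artifact
## rejection — epochs exceeding the amplitude bound are only counted.

#' Re-reference the recording to linked earlobes
#'
#' Subtracts the average of the two earlobe electrodes (A1, A2) from every
#' EEG channel. EOG and reference channels are left untouched. Can only be
#' applied once; the recording's reference state tracks this.
#'
#' @param rec an [EegRecording-class] with `reference == "raw"`.
#' @return the re-referenced [EegRecording-class].
#' @export
rereferenceLinkedEarlobes <- function(rec) {
  if (referenceState(rec) != "raw")
    stop("recording is already re-referenced")
  labs <- recordingLabels(rec)
  if (!all(c("A1", "A2") %in% labs))
    stop("earlobe channels A1/A2 are missing")
  data <- recordingData(rec)
  ref <- (data["A1", ] + data["A2", ]) / 2
  eeg <- intersect(eegLabels(), labs)
  data[eeg, ] <- sweep(data[eeg, , drop = FALSE], 2, ref)
  new("EegRecording", data = data, labels = labs,
      sampleRate = sampleRate(rec), reference = "linked_earlobes")
}

#' Bipolar electrooculogram
#'
#' Horizontal EOG is the right minus the left canthus electrode; vertical
#' EOG is the upper (Fp2-site) minus the lower (infraorbital) electrode.
#'
#' @param rec an [EegRecording-class] containing the four EOG electrodes.
#' @return numeric matrix with rows `hEOG` and `vEOG`.
#' @export
bipolarEOG <- function(rec) {
  labs <- recordingLabels(rec)
  need <- eogLabels()
  if (!all(need %in% labs))
    stop("EOG electrodes missing: ",
         paste(setdiff(need, labs), collapse = ", "))
  data <- recordingData(rec)
  rbind(hEOG = data["hEOG-right", ] - data["hEOG-left", ],
        vEOG = data["vEOG-upper", ] - data["vEOG-lower", ])
}

applyChannelFilter <- function(x, flt) {
  runFilter <- function(v) as.numeric(signal::filter(flt, v))
  if (is(x, "EegRecording")) {
    data <- recordingData(x)
    keep <- setdiff(recordingLabels(x), c("A1", "A2"))
    for (lb in keep) data[lb, ] <- runFilter(data[lb, ])
    return(new("EegRecording", data = data, labels = recordingLabels(x),
               sampleRate = sampleRate(x), reference = referenceState(x)))
  }
  if (is.matrix(x)) return(t(apply(x, 1, runFilter)))
  runFilter(x)
}

#' 50 Hz notch filter
#'
#' Causal 2nd-order Butterworth band-stop with a 48-52 Hz stop band,
#' applied to EEG and EOG before any epoching (line-noise reduction).
#' Forward-only filtering keeps the chain usable online.
#'
#' @param x numeric vector, channels-by-time matrix, or
#'   [EegRecording-class].
#' @param sampleRate Hz (ignored for recordings, which carry their own).
#' @return the filtered object, same shape as the input.
#' @export
notch50 <- function(x, sampleRate = 500) {
  if (is(x, "EegRecording")) sampleRate <- sampleRate(x)
  flt <- signal::butter(2, c(48, 52) / (sampleRate / 2), type = "stop")
  applyChannelFilter(x, flt)
}

#' 7 Hz low-pass display filter
#'
#' Causal 2nd-order Butterworth low-pass with -3 dB at 7 Hz. Used only for
#' waveform display (grand averages); never applied before feature
#' extraction.
#'
#' @inheritParams notch50
#' @return the filtered object, same shape as the input.
#' @export
lowpass7 <- function(x, sampleRate = 500) {
  if (is(x, "EegRecording")) sampleRate <- sampleRate(x)
  flt <- signal::butter(2, 7 / (sampleRate / 2), type = "low")
  applyChannelFilter(x, flt)
}

#' Extract fixation-locked epochs
#'
#' Cuts [-500, +1500) ms epochs (1000 samples at 500 Hz) around each event
#' onset, onset aligned to sample 251. Event onsets are rounded to the
#' nearest 2-ms sample. Events whose window does not fit inside the
#' recording are skipped, with the count reported via a message.
#'
#' @param rec an [EegRecording-class] (re-referenced and notch-filtered).
#' @param events data.frame with `onset_ms` plus any metadata columns
#'   (e.g. `fixation_type`, `condition_ms`), carried into the result.
#' @return a [FixationEpochs-class] with `baselineApplied = FALSE`.
#' @export
extractEpochs <- function(rec, events) {
  data <- recordingData(rec)
  nSamp <- ncol(data)
  dtMs <- 1000 / sampleRate(rec)
  n0 <- round(events$onset_ms / dtMs) + 1L      # sample of t = 0
  lo <- n0 - 250L
  hi <- n0 + 749L
  ok <- lo >= 1L & hi <= nSamp
  if (any(!ok))
    message(sum(!ok), " event(s) out of recording bounds, skipped")
  keep <- which(ok)
  arr <- array(0, dim = c(nrow(data), 1000L, length(keep)),
               dimnames = list(recordingLabels(rec), NULL, NULL))
  for (j in seq_along(keep)) {
    arr[, , j] <- data[, lo[keep[j]]:hi[keep[j]]]
  }
  new("FixationEpochs", data = arr, channels = recordingLabels(rec),
      events = droplevels(events[keep, , drop = FALSE]),
      sampleRate = sampleRate(rec), baselineApplied = FALSE)
}

#' Baseline-correct epochs
#'
#' Subtracts, per channel and epoch, the mean over the 200-300 ms interval
#' after fixation onset (50 samples). The baseline sits inside the
#' fixation, after the lambda wave and before the EOG-contaminated late
#' interval, so eye-movement potentials around the saccade cannot leak into
#' the analysed window. Double application is an error.
#'
#' @param epochs a [FixationEpochs-class] with `baselineApplied = FALSE`.
#' @return the corrected [FixationEpochs-class].
#' @export
baselineCorrect <- function(epochs) {
  if (baselineApplied(epochs))
    stop("baseline already applied")
  idx <- epochSampleIndex(200, 300)
  arr <- epochArray(epochs)
  base <- apply(arr[, idx, , drop = FALSE], c(1, 3), mean)
  for (e in seq_len(dim(arr)[3])) arr[, , e] <- arr[, , e] - base[, e]
  new("FixationEpochs", data = arr, channels = epochs@channels,
      events = eventInfo(epochs), sampleRate = sampleRate(epochs),
      baselineApplied = TRUE)
}

#' Census of high-amplitude epochs
#'
#' Counts baseline-corrected epochs whose absolute amplitude exceeds the
#' bound at any sample of the 200-500 ms interval in any EEG channel.
#' This is a report only: no epochs are removed (the paradigm's epochs are
#' EOG-safe by interval selection, and high-amplitude epochs proved rare,
#' so no rejection step is part of the pipeline).
#'
#' @param epochs a baseline-corrected [FixationEpochs-class].
#' @param limitUv amplitude bound in muV (default 70).
#' @return integer count of flagged epochs.
#' @export
countArtifactEpochs <- function(epochs, limitUv = 70) {
  if (!baselineApplied(epochs))
    stop("epochs must be baseline-corrected before the artifact census")
  idx <- epochSampleIndex(200, 500)
  eeg <- intersect(eegLabels(), epochs@channels)
  arr <- epochArray(epochs)[eeg, idx, , drop = FALSE]
  sum(apply(abs(arr) > limitUv, 3, any))
}
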