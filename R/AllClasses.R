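#' @import methods
NULL

## Channel layout used throughout: 19 EEG sites (posterior-weighted montage),
## four EOG electrodes, two earlobe references. Order is fixed so that
## recordings, epochs and spatial profiles always agree.

#' EEG channel labels of the recording montage
#'
#' The 19 scalp sites, the four EOG electrodes (outer canthi left/right,
#' below the right eye, and an upper electrode at the Fp2 site) and the two
#' earlobe reference electrodes, in the canonical order used by every
#' recording and epoch container in the package.
#'
#' @return Character vector of 25 channel labels.
#' @export
channelLabels <- function() {
  c(eegLabels(), eogLabels(), c("A1", "A2"))
}

eegLabels <- function() {
  c("Fz", "F3", "F4", "Cz", "C3", "C4",
    "Pz", "P1", "P2", "P3", "P4",
    "POz", "PO3", "PO4", "PO7", "PO8",
    "Oz", "O1", "O2")
}

eogLabels <- function() {
  c("hEOG-left", "hEOG-right", "vEOG-upper", "vEOG-lower")
}

#' Posterior channels used for feature extraction
#'
#' The 13 parieto-occipital channels from which windowed-amplitude features
#' are taken, in the fixed order that defines the feature-vector layout.
#'
#' @return Character vector of 13 labels.
#' @export
posteriorChannels <- function() {
  c("P1", "P2", "P3", "P4", "Pz",
    "PO3", "PO4", "PO7", "PO8", "POz",
    "O1", "O2", "Oz")
}

fixationTypes <- function() c("BUTTON", "BALL", "FREECELL", "NONCONTROL")

#' @title Simulation configuration
#'
#' @description S4 container for all parameters of the synthetic gaze+EEG
#' session generator. Defaults encode the study conditions the analysis
#' assumes: 500 Hz sampling, four 5-minute games per dwell-threshold
#' condition, roughly 7.5 moves per minute, spontaneous fixation durations
#' calibrated so that a 4-game 500-ms block yields about 160 spontaneous
#' dwells of 500 ms or longer, and posterior slow-wave amplitudes anchored
#' at the grand-mean values reported for this paradigm.
#'
#' @slot seed integer default RNG seed (overridable per call).
#' @slot samplingRate sampling rate in Hz (fixed at 500).
#' @slot nGamesPerCondition games per dwell-threshold block.
#' @slot gameDurationS duration of one game in seconds.
#' @slot dwellThresholdsMs dwell-time thresholds in ms (subset of 500, 1000).
#' @slot moveRatePerMin target move rate (button-ball-freecell triplets).
#' @slot spontaneousMeanlog,spontaneousSdlog log-normal parameters (seconds)
#'   of spontaneous fixation durations.
#' @slot spontaneousGapS mean gap between spontaneous fixations (saccade plus
#'   latency), seconds.
#' @slot spnAmpUv named numeric: expected baseline-corrected POz mean over
#'   400-500 ms per fixation type (muV, all <= 0).
#' @slot spnOnsetMs ramp onset of the anticipatory negativity, ms after
#'   fixation onset.
#' @slot lateralityDeltaUv named numeric (left/right): expected PO4-PO3
#'   difference for button fixations by button side (muV).
#' @slot lambdaAmpUv amplitude of the positive occipital lambda wave (muV).
#' @slot noiseSdUv per-channel pink-noise standard deviation (muV).
#' @slot eogGainUvPerDeg bipolar EOG gain per degree of gaze displacement.
#' @slot eogPosteriorLeak fraction of bipolar EOG leaking into posterior
#'   channels (0 = clean posterior signal).
#' @slot eogFrontalLeak fraction of bipolar EOG leaking into frontal channels.
#' @slot channelLabels full channel list (EEG + EOG + earlobes).
#'
#' @seealso [simConfig()] for the validated constructor.
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  samplingRate = "numeric",
  nGamesPerCondition = "integer",
  gameDurationS = "numeric",
  dwellThresholdsMs = "numeric",
  moveRatePerMin = "numeric",
  spontaneousMeanlog = "numeric",
  spontaneousSdlog = "numeric",
  spontaneousGapS = "numeric",
  spnAmpUv = "numeric",
  spnOnsetMs = "numeric",
  lateralityDeltaUv = "numeric",
  lambdaAmpUv = "numeric",
  noiseSdUv = "numeric",
  eogGainUvPerDeg = "numeric",
  eogPosteriorLeak = "numeric",
  eogFrontalLeak = "numeric",
  channelLabels = "character"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@samplingRate != 500)
    msg <- c(msg, "samplingRate must be 500 Hz")
  if (object@nGamesPerCondition < 0)
    msg <- c(msg, "nGamesPerCondition must be >= 0")
  if (object@gameDurationS < 0)
    msg <- c(msg, "gameDurationS must be >= 0")
  if (object@moveRatePerMin < 0)
    msg <- c(msg, "moveRatePerMin must be >= 0")
  if (!all(object@dwellThresholdsMs %in% c(500, 1000)))
    msg <- c(msg, "dwellThresholdsMs must be a subset of {500, 1000}")
  if (!all(fixationTypes() %in% names(object@spnAmpUv)))
    msg <- c(msg, "spnAmpUv must name all four fixation types")
  if (any(object@spnAmpUv > 0))
    msg <- c(msg, "spnAmpUv values must be <= 0 (negativity)")
  if (!all(c("left", "right") %in% names(object@lateralityDeltaUv)))
    msg <- c(msg, "lateralityDeltaUv must name sides 'left' and 'right'")
  if (object@spnOnsetMs < 0 || object@spnOnsetMs >= 449)
    msg <- c(msg, "spnOnsetMs must lie in [0, 449) for the ramp normalization")
  if (object@spontaneousSdlog <= 0 || object@spontaneousGapS <= 0)
    msg <- c(msg, "spontaneous duration/gap parameters must be positive")
  if (object@noiseSdUv < 0)
    msg <- c(msg, "noiseSdUv must be >= 0")
  if (object@eogPosteriorLeak < 0 || object@eogFrontalLeak < 0)
    msg <- c(msg, "EOG leak fractions must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @title Continuous multichannel recording
#'
#' @description A channels-by-time matrix of DC-coupled potentials in
#' microvolts with its channel labels, sampling rate and reference state.
#' Re-referencing to linked earlobes flips `reference` from `"raw"` to
#' `"linked_earlobes"` so the contract "re-reference exactly once, before
#' epoching" is machine-checkable.
#'
#' @slot data numeric matrix, channels x time (muV).
#' @slot labels character channel labels (rownames of `data`).
#' @slot sampleRate numeric, Hz.
#' @slot reference `"raw"` or `"linked_earlobes"`.
#' @export
setClass("EegRecording", representation(
  data = "matrix",
  labels = "character",
  sampleRate = "numeric",
  reference = "character"
))

setValidity("EegRecording", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@labels))
    msg <- c(msg, "row count of data must equal number of labels")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "channel labels must be unique")
  if (!object@reference %in% c("raw", "linked_earlobes"))
    msg <- c(msg, "reference must be 'raw' or 'linked_earlobes'")
  if (length(msg)) msg else TRUE
})

#' @title Synthetic gaze+EEG session
#'
#' @description One simulated experimental session: the gaze trace, the
#' multichannel recording on the same time base, the ground-truth event
#' schedule, the static board map used for fixation labeling, and an echo
#' of the generating configuration.
#'
#' @slot gaze data.frame with `t_ms`, `x_deg`, `y_deg`, `blink`.
#' @slot recording an [EegRecording-class] sharing the gaze time base.
#' @slot truth data.frame of ground-truth events (onset_ms, click_time_ms,
#'   fixation_type, button_side, condition_ms, target_x_deg, target_y_deg,
#'   duration_ms, game).
#' @slot board data.frame of screen regions (kind, x_deg, y_deg, side).
#' @slot config the generating [SimConfig-class].
#' @slot seed integer seed actually used.
#' @export
setClass("EyeSession", representation(
  gaze = "data.frame",
  recording = "EegRecording",
  truth = "data.frame",
  board = "data.frame",
  config = "SimConfig",
  seed = "integer"
))

setValidity("EyeSession", function(object) {
  msg <- character()
  if (nrow(object@gaze) != ncol(object@recording@data))
    msg <- c(msg, "gaze trace and recording must share one time base")
  if (length(msg)) msg else TRUE
})

#' @title Fixation-locked epochs
#'
#' @description Epochs of [-500, +1500) ms around fixation onsets at 500 Hz:
#' a channels x 1000 x events array. Sample n (1-based) maps to time
#' t = -500 + 2*(n-1) ms, so fixation onset sits at sample 251 (t = 0).
#' `baselineApplied` tracks whether the 200-300 ms baseline has been
#' subtracted; feature extraction refuses epochs without it.
#'
#' @slot data numeric array channels x 1000 x nEvents (muV).
#' @slot channels character channel labels (first dimnames).
#' @slot events data.frame of per-epoch event metadata.
#' @slot sampleRate numeric, Hz.
#' @slot baselineApplied logical.
#' @export
setClass("FixationEpochs", representation(
  data = "array",
  channels = "character",
  events = "data.frame",
  sampleRate = "numeric",
  baselineApplied = "logical"
))

setValidity("FixationEpochs", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array (channels x samples x events)")
  else {
    if (d[2] != 1000L) msg <- c(msg, "epochs must contain exactly 1000 samples")
    if (d[1] != length(object@channels))
      msg <- c(msg, "first dimension must match channel labels")
    if (d[3] != nrow(object@events))
      msg <- c(msg, "third dimension must match the event table")
  }
  if (length(msg)) msg else TRUE
})

#' @title Committee of greedy threshold classifiers
#'
#' @description An ordered set of one-dimensional threshold ("stump")
#' classifiers selected by forward greedy search, deciding by vote count.
#' Each member predicts the target (controlling) class iff
#' `polarity * x >= polarity * threshold` on its feature. The operational
#' decision threshold on the vote count is calibrated separately (see
#' [calibrateThreshold()]); `voteThreshold` is `NA` until calibrated.
#'
#' @slot members data.frame with `feature` (1-based column), `threshold`,
#'   `polarity`, `trainError`.
#' @slot voteThreshold numeric; predict target iff votes >= voteThreshold.
#' @slot errorType `"balanced"` or `"plain"` selection error.
#' @export
setClass("Committee", representation(
  members = "data.frame",
  voteThreshold = "numeric",
  errorType = "character"
))

setValidity("Committee", function(object) {
  msg <- character()
  if (anyDuplicated(object@members$feature))
    msg <- c(msg, "member features must be distinct")
  if (!object@errorType %in% c("balanced", "plain"))
    msg <- c(msg, "errorType must be 'balanced' or 'plain'")
  if (!is.na(object@voteThreshold) &&
      (object@voteThreshold < 1 || object@voteThreshold > nrow(object@members)))
    msg <- c(msg, "voteThreshold must lie in 1..size")
  if (length(msg)) msg else TRUE
})

#' @title Shrinkage-regularized linear discriminant model
#'
#' @description LDA whose pooled within-class covariance is shrunk toward a
#' scaled identity, `(1-gamma) S + gamma nu I` with `nu = trace(S)/d`, the
#' shrinkage intensity `gamma` estimated analytically (Ledoit-Wolf) unless
#' overridden. Guarantees a finite weight vector even when trials are fewer
#' than features. The decision score is `w'x + b`; the operational score
#' threshold is calibrated separately and is `NA` until then.
#'
#' @slot w numeric weight vector (length = number of features).
#' @slot b numeric bias, `-w'(mu0+mu1)/2`.
#' @slot gamma shrinkage intensity in [0, 1].
#' @slot nu trace(S)/d scaling of the identity target.
#' @slot mu0,mu1 class mean vectors (non-target, target).
#' @slot scoreThreshold calibrated decision threshold (NA until calibrated).
#' @export
setClass("ShrinkageLDA", representation(
  w = "numeric",
  b = "numeric",
  gamma = "numeric",
  nu = "numeric",
  mu0 = "numeric",
  mu1 = "numeric",
  scoreThreshold = "numeric"
))

setValidity("ShrinkageLDA", function(object) {
  msg <- character()
  if (object@gamma < 0 || object@gamma > 1)
    msg <- c(msg, "gamma must lie in [0, 1]")
  if (!all(is.finite(object@w)))
    msg <- c(msg, "weights must be finite")
  if (length(msg)) msg else TRUE
})
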