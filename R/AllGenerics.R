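#' Accessor generics
#'
#' Small accessor layer over the S4 containers so user code never touches
#' slots directly.
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gazeData", function(object) standardGeneric("gazeData"))

#' @rdname accessors
#' @export
setGeneric("recording", function(object) standardGeneric("recording"))

#' @rdname accessors
#' @export
setGeneric("truthEvents", function(object) standardGeneric("truthEvents"))

#' @rdname accessors
#' @export
setGeneric("boardMap", function(object) standardGeneric("boardMap"))

#' @rdname accessors
#' @export
setGeneric("simulationConfig",
           function(object) standardGeneric("simulationConfig"))

#' @rdname accessors
#' @export
setGeneric("recordingData", function(object) standardGeneric("recordingData"))

#' @rdname accessors
#' @export
setGeneric("recordingLabels",
           function(object) standardGeneric("recordingLabels"))

#' @rdname accessors
#' @export
setGeneric("referenceState", function(object) standardGeneric("referenceState"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("epochArray", function(object) standardGeneric("epochArray"))

#' @rdname accessors
#' @export
setGeneric("eventInfo", function(object) standardGeneric("eventInfo"))

#' @rdname accessors
#' @export
setGeneric("baselineApplied", function(object) standardGeneric("baselineApplied"))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))

#' @rdname accessors
#' @export
setGeneric("committeeMembers",
           function(object) standardGeneric("committeeMembers"))

#' @rdname accessors
#' @export
setGeneric("decisionThreshold",
           function(object) standardGeneric("decisionThreshold"))

#' Set the calibrated decision threshold of a classifier
#'
#' @param object a [Committee-class] or [ShrinkageLDA-class] model.
#' @param value the calibrated threshold (vote count or LDA score).
#' @return the model with its operational threshold set.
#' @export
setGeneric("decisionThreshold<-",
           function(object, value) standardGeneric("decisionThreshold<-"))

#' Score feature vectors with a trained classifier
#'
#' For a [Committee-class] the score is the integer number of members voting
#' target; for a [ShrinkageLDA-class] it is the projection `w'x + b`.
#'
#' @param object a trained classifier.
#' @param X numeric matrix (rows = epochs) or a single feature vector.
#' @return numeric vector of scores, one per row.
#' @export
setGeneric("classifierScore",
           function(object, X) standardGeneric("classifierScore"))

## -- accessor methods -------------------------------------------------------

#' @rdname accessors
setMethod("gazeData", "EyeSession", function(object) object@gaze)

#' @rdname accessors
setMethod("recording", "EyeSession", function(object) object@recording)

#' @rdname accessors
setMethod("truthEvents", "EyeSession", function(object) object@truth)

#' @rdname accessors
setMethod("boardMap", "EyeSession", function(object) object@board)

#' @rdname accessors
setMethod("simulationConfig", "EyeSession", function(object) object@config)

#' @rdname accessors
setMethod("recordingData", "EegRecording", function(object) object@data)

#' @rdname accessors
setMethod("recordingLabels", "EegRecording", function(object) object@labels)

#' @rdname accessors
setMethod("referenceState", "EegRecording", function(object) object@reference)

#' @rdname accessors
setMethod("sampleRate", "EegRecording", function(object) object@sampleRate)

#' @rdname accessors
setMethod("sampleRate", "FixationEpochs", function(object) object@sampleRate)

#' @rdname accessors
setMethod("epochArray", "FixationEpochs", function(object) object@data)

#' @rdname accessors
setMethod("eventInfo", "FixationEpochs", function(object) object@events)

#' @rdname accessors
setMethod("baselineApplied", "FixationEpochs",
          function(object) object@baselineApplied)

#' @rdname accessors
setMethod("nEpochs", "FixationEpochs", function(object) dim(object@data)[3])

#' @rdname accessors
setMethod("committeeMembers", "Committee", function(object) object@members)

#' @rdname accessors
setMethod("decisionThreshold", "Committee",
          function(object) object@voteThreshold)

#' @rdname accessors
setMethod("decisionThreshold", "ShrinkageLDA",
          function(object) object@scoreThreshold)

#' @rdname decisionThreshold-set
#' @aliases decisionThreshold<-,Committee-method
setReplaceMethod("decisionThreshold", "Committee", function(object, value) {
  object@voteThreshold <- value
  validObject(object)
  object
})

#' @rdname decisionThreshold-set
#' @aliases decisionThreshold<-,ShrinkageLDA-method
setReplaceMethod("decisionThreshold", "ShrinkageLDA", function(object, value) {
  object@scoreThreshold <- value
  object
})

## -- subsetting epochs ------------------------------------------------------

#' Subset fixation epochs by event
#'
#' @param x a [FixationEpochs-class] object.
#' @param i event indices or a logical vector over events.
#' @param j,...,drop ignored.
#' @return a [FixationEpochs-class] with the selected events.
#' @export
setMethod("[", "FixationEpochs", function(x, i, j, ..., drop = FALSE) {
  new("FixationEpochs",
      data = x@data[, , i, drop = FALSE],
      channels = x@channels,
      events = x@events[i, , drop = FALSE],
      sampleRate = x@sampleRate,
      baselineApplied = x@baselineApplied)
})

## -- show methods -----------------------------------------------------------

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:",
      object@nGamesPerCondition, "game(s) x",
      object@gameDurationS, "s per condition;",
      "thresholds", paste(object@dwellThresholdsMs, collapse = "/"), "ms\n")
  cat("  SPN amplitudes (muV):",
      paste(names(object@spnAmpUv), round(object@spnAmpUv, 2),
            sep = "=", collapse = ", "), "\n")
  cat("  noise sd:", object@noiseSdUv, "muV; EOG gain:",
      object@eogGainUvPerDeg, "muV/deg\n")
})

setMethod("show", "EegRecording", function(object) {
  cat("EegRecording:", nrow(object@data), "channels x",
      ncol(object@data), "samples @", object@sampleRate, "Hz;",
      "reference:", object@reference, "\n")
})

setMethod("show", "EyeSession", function(object) {
  cat("EyeSession:", round(nrow(object@gaze) / object@recording@sampleRate),
      "s,", nrow(object@truth), "ground-truth events\n")
  print(object@recording)
  tab <- table(object@truth$fixation_type)
  cat("  events:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "FixationEpochs", function(object) {
  cat("FixationEpochs:", dim(object@data)[3], "epochs x",
      length(object@channels), "channels, [-500, 1500) ms @",
      object@sampleRate, "Hz; baseline",
      if (object@baselineApplied) "applied" else "not applied", "\n")
})

setMethod("show", "Committee", function(object) {
  cat("Committee of", nrow(object@members), "threshold classifiers (",
      object@errorType, " error); vote threshold: ",
      ifelse(is.na(object@voteThreshold), "uncalibrated",
             object@voteThreshold), "\n", sep = "")
})

setMethod("show", "ShrinkageLDA", function(object) {
  cat("ShrinkageLDA:", length(object@w), "features, gamma =",
      signif(object@gamma, 3), ", nu =", signif(object@nu, 3), "\n")
})
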