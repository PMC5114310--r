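## Trainset assembly, specificity-calibrated cross-validation, metrics,
## false-alarm arithmetic and the amplitude statistics of the paradigm.

#' Assemble a trainset
#'
#' Variant 1 uses button fixations only as the target class (their
#' potentials differ most strongly from spontaneous fixations, giving an
#' upper performance estimate); variant 2 uses all controlling fixations.
#' Non-targets are the spontaneous (non-controlling) ball fixations in both
#' variants. Under variant 1, ball and free-cell rows are retained as
#' held-out test strata, never entering training folds.
#'
#' @param X feature matrix, epochs x 169 (see [extractFeatures()]).
#' @param info data.frame with one row per epoch, containing
#'   `fixation_type`.
#' @param variant 1 or 2.
#' @return list of class `"Trainset"` with elements `X`, `y`, `info`,
#'   `heldout` (variant 1: list with `X`, `info`), `variant`.
#' @export
buildTrainset <- function(X, info, variant = 1) {
  stopifnot(variant %in% c(1, 2), nrow(X) == nrow(info))
  targetTypes <- if (variant == 1) "BUTTON"
                 else c("BUTTON", "BALL", "FREECELL")
  keep <- info$fixation_type %in% c(targetTypes, "NONCONTROL")
  if (!any(info$fixation_type == "NONCONTROL"))
    stop("no non-controlling epochs: cannot form a trainset")
  heldout <- NULL
  if (variant == 1) {
    ho <- info$fixation_type %in% c("BALL", "FREECELL")
    heldout <- list(X = X[ho, , drop = FALSE],
                    info = info[ho, , drop = FALSE])
  }
  structure(list(
    X = X[keep, , drop = FALSE],
    y = as.integer(info$fixation_type[keep] %in% targetTypes),
    info = info[keep, , drop = FALSE],
    heldout = heldout,
    variant = variant), class = "Trainset")
}

#' Specificity and sensitivity of predictions
#'
#' Specificity = TN/(TN+FP) over true non-targets; sensitivity =
#' TP/(TP+FN) over true targets. An absent class yields `NA` with a
#' warning rather than a silent 0.
#'
#' @param yTrue,yPred integer 0/1 vectors.
#' @return named numeric `c(specificity, sensitivity)`.
#' @export
confusionMetrics <- function(yTrue, yPred) {
  spec <- if (any(yTrue == 0)) mean(yPred[yTrue == 0] == 0) else {
    warning("no non-target rows: specificity undefined"); NA_real_
  }
  sens <- if (any(yTrue == 1)) mean(yPred[yTrue == 1] == 1) else {
    warning("no target rows: sensitivity undefined"); NA_real_
  }
  c(specificity = spec, sensitivity = sens)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random target
#' outscores a random non-target, ties counting one half.
#'
#' @param scores numeric classifier scores.
#' @param y labels 0/1, both present.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n0 == 0 || n1 == 0) stop("both classes needed for AUC")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' False alarms per minute
#'
#' Converts a specificity into an interface-level false-activation rate:
#' `(nNoncontrol / totalMinutes) * (1 - specificity)`. With about 160
#' spontaneous threshold-exceeding fixations over 4 five-minute games
#' (8 per minute), a specificity of 0.9 corresponds to 0.8 false alarms
#' per minute.
#'
#' @param nNoncontrol count of threshold-exceeding non-controlling
#'   fixations.
#' @param totalMinutes observation time in minutes.
#' @param specificity classifier specificity in [0, 1].
#' @return false alarms per minute.
#' @export
falseAlarmRate <- function(nNoncontrol, totalMinutes, specificity) {
  if (totalMinutes <= 0) stop("totalMinutes must be positive")
  if (specificity < 0 || specificity > 1)
    stop("specificity must lie in [0, 1]")
  (nNoncontrol / totalMinutes) * (1 - specificity)
}

stratifiedFolds <- function(y, type, nFolds, seed) {
  if (min(table(y)) < nFolds)
    stop("too few rows in a class for ", nFolds, "-fold stratification")
  fold <- integer(length(y))
  withr::with_seed(substreamSeed(seed, 99L), {
    for (s in split(seq_along(y), interaction(y, type, drop = TRUE))) {
      fold[sample(s)] <- rep_len(seq_len(nFolds), length(s))
    }
  })
  fold
}

typeSensitivity <- function(pred, info) {
  vapply(c("BUTTON", "BALL", "FREECELL"), function(tp) {
    i <- info$fixation_type == tp
    if (any(i)) mean(pred[i] == 1) else NA_real_
  }, numeric(1))
}

#' Cross-validated, specificity-calibrated evaluation
#'
#' Stratified k-fold rotation: in each rotation one fold is the test set,
#' the next fold is the validation set used solely to calibrate the
#' decision threshold at the target specificity, and the remaining folds
#' train the classifier. Per rotation the report records test specificity,
#' per-fixation-type sensitivity, AUC and the calibrated threshold; under
#' trainset variant 1 the held-out ball/free-cell strata are scored with
#' every rotation's model. A transfer set (features from the other
#' dwell-threshold condition) is scored with each rotation's trained,
#' calibrated model to estimate cross-condition sensitivity.
#'
#' @param ts a `"Trainset"` from [buildTrainset()].
#' @param classifier `"committee"` or `"lda"`.
#' @param nFolds folds (default 5).
#' @param seed integer seed for the stratified fold assignment.
#' @param transfer optional list with `X` and `info` of other-condition
#'   epochs.
#' @param targetSpecificity calibration target (default 0.90).
#' @param k committee size (default 15).
#' @param errorType committee selection error, `"balanced"` or `"plain"`.
#' @param gamma optional fixed LDA shrinkage intensity.
#' @return list of class `"EvalReport"`: `folds` (per-rotation metrics),
#'   `mean`, `sd`, `classifier`, `variant`.
#' @export
runCV <- function(ts, classifier = c("committee", "lda"), nFolds = 5,
                  seed = 1, transfer = NULL, targetSpecificity = 0.90,
                  k = 15, errorType = "balanced", gamma = NULL) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(ts, "Trainset"))
  fold <- stratifiedFolds(ts$y, ts$info$fixation_type, nFolds, seed)
  rows <- list()
  for (r in seq_len(nFolds)) {
    valFold <- r %% nFolds + 1
    testIdx <- fold == r
    valIdx <- fold == valFold
    trainIdx <- !(testIdx | valIdx)
    model <- if (classifier == "committee")
      buildCommittee(ts$X[trainIdx, , drop = FALSE], ts$y[trainIdx],
                     k = k, errorType = errorType)
    else
      fitShrinkageLDA(ts$X[trainIdx, , drop = FALSE], ts$y[trainIdx],
                      gamma = gamma)
    valScores <- classifierScore(model, ts$X[valIdx, , drop = FALSE])
    th <- calibrateThreshold(valScores[ts$y[valIdx] == 0],
                             targetSpecificity)
    decisionThreshold(model) <- th
    testScores <- classifierScore(model, ts$X[testIdx, , drop = FALSE])
    pred <- as.integer(testScores >= th)
    cm <- confusionMetrics(ts$y[testIdx], pred)
    sens <- typeSensitivity(pred, ts$info[testIdx, , drop = FALSE])
    if (!is.null(ts$heldout) && nrow(ts$heldout$X)) {
      hoPred <- predictLabels(model, ts$heldout$X)
      hoSens <- typeSensitivity(hoPred, ts$heldout$info)
      sens[is.na(sens)] <- hoSens[is.na(sens)]
    }
    auc <- aucScore(testScores, ts$y[testIdx])
    row <- data.frame(fold = r, specificity = cm[["specificity"]],
                      sens_button = sens[["BUTTON"]],
                      sens_ball = sens[["BALL"]],
                      sens_freecell = sens[["FREECELL"]],
                      auc = auc, threshold = th)
    if (!is.null(transfer) && nrow(transfer$X)) {
      trPred <- predictLabels(model, transfer$X)
      trSens <- typeSensitivity(trPred, transfer$info)
      row$transfer_sens_button <- trSens[["BUTTON"]]
      row$transfer_sens_ball <- trSens[["BALL"]]
      row$transfer_sens_freecell <- trSens[["FREECELL"]]
    }
    rows[[r]] <- row
  }
  folds <- do.call(rbind, rows)
  metricCols <- setdiff(names(folds), "fold")
  structure(list(
    folds = folds,
    mean = colMeans(folds[metricCols], na.rm = TRUE),
    sd = apply(folds[metricCols], 2, stats::sd, na.rm = TRUE),
    classifier = classifier,
    variant = ts$variant), class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat("EvalReport:", x$classifier, "classifier, trainset variant",
      x$variant, "\n")
  cat(sprintf("  specificity %.2f +- %.2f, button sensitivity %.2f +- %.2f, AUC %.2f\n",
              x$mean[["specificity"]], x$sd[["specificity"]],
              x$mean[["sens_button"]], x$sd[["sens_button"]],
              x$mean[["auc"]]))
  invisible(x)
}

#' Per-epoch amplitude summary
#'
#' For each baseline-corrected epoch: the POz mean over the 400-500 ms
#' window (the robust estimate of the anticipatory negativity) and the
#' PO4 minus PO3 mean over the same window (the laterality index).
#'
#' @param epochs a baseline-corrected [FixationEpochs-class].
#' @param participant optional participant id stored alongside.
#' @return data.frame: event metadata plus `poz_uv` and `po4_po3_uv`.
#' @export
epochAmplitudeSummary <- function(epochs, participant = NA) {
  if (!baselineApplied(epochs))
    stop("epochs must be baseline-corrected")
  idx <- epochSampleIndex(400, 500)
  arr <- epochArray(epochs)
  out <- eventInfo(epochs)
  out$participant <- participant
  out$poz_uv <- apply(arr["POz", idx, , drop = FALSE], 3, mean)
  out$po4_po3_uv <- apply(arr["PO4", idx, , drop = FALSE], 3, mean) -
    apply(arr["PO3", idx, , drop = FALSE], 3, mean)
  out
}

#' Group amplitude statistics
#'
#' Aggregates per-epoch amplitude summaries into per-participant group
#' means by fixation type, dwell-threshold condition and button side, and
#' tests the button-fixation laterality (PO4 - PO3) between left- and
#' right-button conditions with a paired t-test across participants.
#'
#' @param summary data.frame from [epochAmplitudeSummary()] (rows from all
#'   participants), with columns `participant`, `fixation_type`,
#'   `condition_ms`, `button_side`, `poz_uv`, `po4_po3_uv`.
#' @return list of class `"AmplitudeStats"`: `groupMeans` (per participant
#'   x type x condition x side), `laterality` (per-side means), and
#'   `lateralityTest` (paired t, df, two-sided p; `NA` when fewer than two
#'   participants contribute both sides).
#' @export
amplitudeStats <- function(summary) {
  gm <- stats::aggregate(
    cbind(poz_uv, po4_po3_uv) ~ participant + fixation_type +
      condition_ms + button_side,
    data = summary, FUN = mean)
  but <- gm[gm$fixation_type == "BUTTON", ]
  lat <- stats::aggregate(po4_po3_uv ~ button_side, data = but, FUN = mean)
  wide <- stats::reshape(
    stats::aggregate(po4_po3_uv ~ participant + button_side, data = but,
                     FUN = mean),
    idvar = "participant", timevar = "button_side", direction = "wide")
  test <- list(t = NA_real_, df = NA_real_, p = NA_real_)
  if (all(c("po4_po3_uv.left", "po4_po3_uv.right") %in% names(wide))) {
    paired <- stats::na.omit(wide[c("po4_po3_uv.left", "po4_po3_uv.right")])
    if (nrow(paired) >= 2 &&
        stats::sd(paired[[1]] - paired[[2]]) > 0) {
      tt <- stats::t.test(paired[[1]], paired[[2]], paired = TRUE)
      test <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
    }
  }
  structure(list(groupMeans = gm, laterality = lat, lateralityTest = test),
            class = "AmplitudeStats")
}

#' Grand-average waveforms by fixation type
#'
#' Arithmetic mean of baseline-corrected epochs per fixation type, with an
#' optional 7 Hz low-pass for display. Empty types are skipped with a
#' message.
#'
#' @param epochs a baseline-corrected [FixationEpochs-class].
#' @param types fixation types to average (default: all present).
#' @param displayFilter apply [lowpass7()] to the averages (display only).
#' @return named list of channels x 1000 matrices.
#' @export
grandAverage <- function(epochs, types = NULL, displayFilter = FALSE) {
  info <- eventInfo(epochs)
  if (is.null(types)) types <- unique(info$fixation_type)
  out <- list()
  for (tp in types) {
    i <- which(info$fixation_type == tp)
    if (!length(i)) {
      message("no epochs of type ", tp, ", skipped")
      next
    }
    avg <- apply(epochArray(epochs)[, , i, drop = FALSE], c(1, 2), mean)
    if (displayFilter)
      avg <- lowpass7(avg, sampleRate(epochs))
    out[[tp]] <- avg
  }
  out
}
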