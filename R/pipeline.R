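## End-to-end driver: from a raw session to labeled, baseline-corrected
## epochs and feature matrices, per dwell-threshold condition.

#' Games belonging to one dwell-threshold condition
#'
#' @param config a [SimConfig-class].
#' @param conditionMs 500 or 1000.
#' @return integer vector of game numbers.
#' @keywords internal
conditionGames <- function(config, conditionMs) {
  block <- match(conditionMs, config@dwellThresholdsMs)
  if (is.na(block)) stop("condition ", conditionMs, " not simulated")
  (block - 1L) * config@nGamesPerCondition + seq_len(config@nGamesPerCondition)
}

#' Run the full offline pipeline on a session
#'
#' For each dwell-threshold condition of the session: detects dwells on
#' that condition's games with the matching threshold, labels them from
#' the board map and control state, re-references the recording to linked
#' earlobes, applies the 50 Hz notch, extracts [-500, 1500) ms epochs
#' around the labeled fixation onsets, baseline-corrects them (200-300
#' ms), and builds the 169-dimensional feature matrix. Fixations labeled
#' `EXCLUDED` are dropped before epoching.
#'
#' @param session an [EyeSession-class].
#' @param applyNotch apply the 50 Hz notch to the continuous recording
#'   (default TRUE; the simulator injects no line noise, so tests may skip
#'   it for speed).
#' @return named list, one element per condition (`"500"`, `"1000"`),
#'   each a list with `epochs` (baseline-corrected
#'   [FixationEpochs-class]), `X` (features), `info` (per-epoch event
#'   metadata) and `dwells` (all detected dwells).
#' @export
processSession <- function(session, applyNotch = TRUE) {
  config <- simulationConfig(session)
  rec <- rereferenceLinkedEarlobes(recording(session))
  if (applyNotch) rec <- notch50(rec)
  gaze <- gazeData(session)
  gameDurMs <- config@gameDurationS * 1000
  out <- list()
  for (cond in config@dwellThresholdsMs) {
    games <- conditionGames(config, cond)
    t0 <- (min(games) - 1) * gameDurMs
    t1 <- max(games) * gameDurMs
    seg <- gaze[gaze$t_ms >= t0 & gaze$t_ms < t1, , drop = FALSE]
    dwells <- detectDwells(seg, cond)
    board <- boardMap(session)
    dwells <- labelFixations(dwells,
                             board[board$game %in% games, , drop = FALSE],
                             gameDurationMs = gameDurMs)
    keep <- dwells[dwells$fixation_type != "EXCLUDED", , drop = FALSE]
    epochs <- extractEpochs(rec, keep)
    epochs <- baselineCorrect(epochs)
    X <- extractFeatures(epochs)
    out[[as.character(cond)]] <- list(epochs = epochs, X = X,
                                      info = eventInfo(epochs),
                                      dwells = dwells)
  }
  out
}
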