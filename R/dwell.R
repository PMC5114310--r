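## Dispersion-based dwell detection with the online refractory rules, click
## positioning, and game-state fixation labeling.

#' Detect threshold-exceeding gaze dwells
#'
#' Scans the gaze trace with the online selection criterion: a dwell
#' ("click") is reported at the earliest sample t such that over the
#' trailing window [t - threshold, t] the range of x and of y (blink
#' samples excluded) does not exceed the dispersion bound. Two refractory
#' rules are enforced: the candidate window must not overlap the previous
#' dwell's window, and no click is produced within a 3 x 3 degree square
#' centred on any click of the preceding 3000 ms. The dwell onset is
#' click time minus threshold; the click position is the coordinate-wise
#' median of the non-blink window samples (see [clickPosition()]).
#'
#' @param gaze data.frame with `t_ms`, `x_deg`, `y_deg`, `blink`,
#'   uniformly sampled.
#' @param thresholdMs dwell-time threshold, 500 or 1000 ms.
#' @param dispersionDeg maximal within-window range per axis (default 2).
#' @param refractoryMs duration of the same-position refractory (default
#'   3000 ms).
#' @return data.frame with `click_time_ms`, `onset_ms`, `click_x_deg`,
#'   `click_y_deg`, `condition_ms`.
#' @examples
#' g <- data.frame(t_ms = seq(0, 700, 2), x_deg = 0, y_deg = 0,
#'                 blink = FALSE)
#' detectDwells(g, 500)   # one dwell: click at 500 ms, onset at 0
#' @export
detectDwells <- function(gaze, thresholdMs, dispersionDeg = 2,
                         refractoryMs = 3000) {
  stopifnot(thresholdMs %in% c(500, 1000))
  if (nrow(gaze) == 0) stop("gaze trace is empty")
  dt <- diff(gaze$t_ms)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6)
    stop("gaze trace must be uniformly sampled")
  if (nrow(gaze) < 2 || gaze$t_ms[nrow(gaze)] - gaze$t_ms[1] < thresholdMs) {
    out <- data.frame(click_time_ms = numeric(), onset_ms = numeric(),
                      click_x_deg = numeric(), click_y_deg = numeric())
    out$condition_ms <- numeric()
    return(out)
  }
  out <- cpp_detect_dwells(gaze$t_ms, gaze$x_deg, gaze$y_deg,
                           as.logical(gaze$blink), thresholdMs,
                           dispersionDeg, refractoryMs, 1.5)
  out$condition_ms <- rep(thresholdMs, nrow(out))
  out
}

#' Click position of a dwell
#'
#' Coordinate-wise median of the gaze samples within the dwell interval,
#' excluding blink samples.
#'
#' @param samples data.frame with `x_deg`, `y_deg` and `blink`.
#' @return named numeric `c(x_deg, y_deg)`.
#' @export
clickPosition <- function(samples) {
  keep <- !samples$blink
  if (!any(keep)) stop("dwell has no non-blink samples: position undefined")
  c(x_deg = stats::median(samples$x_deg[keep]),
    y_deg = stats::median(samples$y_deg[keep]))
}

#' Label detected dwells by game state
#'
#' Replays the game's control state over the detected dwell sequence:
#' a dwell on the switch-on button turns control on (type `BUTTON`); with
#' control on, a dwell on a ball selects it (`BALL`) and the next dwell on
#' a free cell completes the move (`FREECELL`) and turns control off. A
#' ball dwell with control off is a spontaneous `NONCONTROL` fixation; a
#' free-cell dwell with control off — and any dwell outside the button and
#' board regions — is `EXCLUDED` (such fixations are too rare to analyse).
#'
#' @param dwells data.frame of detected dwells (see [detectDwells()]),
#'   sorted by time.
#' @param board data.frame of screen regions with `game`, `kind`
#'   (`"button"`, `"ball"`, `"free"`), `x_deg`, `y_deg` (see
#'   [boardMap()]).
#' @param gameDurationMs length of one game in ms; required when `board`
#'   spans several games (control state resets at game boundaries).
#' @param tolDeg matching radius (per axis) between a click position and a
#'   region centre.
#' @return `dwells` with `fixation_type`, `button_side` (the game's button
#'   position) and `game` columns added.
#' @export
labelFixations <- function(dwells, board, gameDurationMs = NA,
                           tolDeg = 1.25) {
  games <- unique(board$game)
  if (length(games) > 1 && is.na(gameDurationMs))
    stop("board spans several games: gameDurationMs is required")
  type <- character(nrow(dwells))
  side <- rep(NA_character_, nrow(dwells))
  if (nrow(dwells) && is.unsorted(dwells$click_time_ms))
    stop("dwells must be sorted by click time")
  game <- if (length(games) > 1)
    games[pmin(length(games),
               floor(dwells$click_time_ms / gameDurationMs) + 1)]
  else rep(games, length.out = nrow(dwells))
  controlOn <- FALSE
  ballSelected <- FALSE
  curGame <- NA
  for (k in seq_len(nrow(dwells))) {
    if (!identical(curGame, game[k])) {      # control resets between games
      controlOn <- FALSE
      ballSelected <- FALSE
      curGame <- game[k]
    }
    b <- board[board$game == game[k], ]
    side[k] <- if ("side" %in% names(b) && nrow(b)) b$side[1] else NA
    hit <- which(abs(b$x_deg - dwells$click_x_deg[k]) <= tolDeg &
                   abs(b$y_deg - dwells$click_y_deg[k]) <= tolDeg)
    kind <- if (length(hit)) b$kind[hit[1]] else "outside"
    if (kind == "button") {
      type[k] <- "BUTTON"
      controlOn <- TRUE
      ballSelected <- FALSE
    } else if (kind == "ball") {
      if (controlOn) {
        type[k] <- "BALL"
        ballSelected <- TRUE
      } else type[k] <- "NONCONTROL"
    } else if (kind == "free") {
      if (controlOn && ballSelected) {
        type[k] <- "FREECELL"
        controlOn <- FALSE
        ballSelected <- FALSE
      } else type[k] <- "EXCLUDED"
    } else type[k] <- "EXCLUDED"
  }
  dwells$fixation_type <- type
  dwells$button_side <- side
  dwells$game <- game
  dwells
}
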