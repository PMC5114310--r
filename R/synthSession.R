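## Synthetic gaze+EEG session generator.
##
## The forward model assembles, per dwell-threshold block: a schedule of
## controlling fixation triplets (button -> ball -> free cell) interleaved
## with spontaneous ball fixations and 10-s planning pauses; a 500 Hz gaze
## trace with within-fixation jitter, linear saccades and blink gaps; and a
## multichannel DC-coupled recording = pink noise + lambda wave at each
## fixation onset + an anticipatory negative ramp scaled by a posterior
## spatial profile (plus a PO4/PO3 asymmetry for button fixations) + EOG
## saccade steps with configurable leakage.

## Spatial profile of the slow negativity, normalized to 1 at POz so the
## configured amplitude is exactly the expected POz measurement.
spnProfile <- function(labels) {
  w <- c(POz = 1, PO3 = 0.85, PO4 = 0.85, Pz = 0.8, Oz = 0.75,
         P1 = 0.7, P2 = 0.7, O1 = 0.7, O2 = 0.7,
         P3 = 0.6, P4 = 0.6, PO7 = 0.5, PO8 = 0.5,
         Cz = 0.3, C3 = 0.2, C4 = 0.2, Fz = 0.15, F3 = 0.1, F4 = 0.1)
  out <- stats::setNames(numeric(length(labels)), labels)
  out[intersect(names(w), labels)] <- w[intersect(names(w), labels)]
  out
}

## Lambda wave: positive occipital component at saccade landing.
lambdaProfile <- function(labels) {
  w <- c(Oz = 1, O1 = 0.8, O2 = 0.8, POz = 0.6)
  out <- stats::setNames(numeric(length(labels)), labels)
  out[intersect(names(w), labels)] <- w[intersect(names(w), labels)]
  out
}

#' Anticipatory negative ramp of a controlling fixation
#'
#' Time course of the slow negativity that builds up during a fixation used
#' for gaze control, expressed relative to fixation onset. The wave is a
#' linear ramp starting at `onsetMs` and normalized so that, with the
#' default onset of 300 ms, the discrete mean over the 2-ms sample grid
#' t = 400, 402, ..., 498 ms equals `ampUv` exactly (the mean of that grid
#' is 449 ms): the configured amplitude is therefore exactly the expected
#' baseline-corrected 400-500 ms measurement.
#'
#' @param tMs numeric vector of times relative to fixation onset, ms.
#' @param ampUv target mean amplitude over the 400-500 ms window, muV.
#' @param onsetMs ramp onset, ms; must lie in [0, 449).
#' @return numeric vector of amplitudes (muV), 0 before `onsetMs`.
#' @examples
#' spnComponent(250, -5.3)                      # before onset: 0
#' mean(spnComponent(seq(400, 498, 2), -5.3))   # exactly -5.3
#' @export
spnComponent <- function(tMs, ampUv, onsetMs = 300) {
  if (onsetMs < 0 || onsetMs >= 449)
    stop("invalid config: onsetMs must lie in [0, 449)")
  ifelse(tMs < onsetMs, 0, ampUv * (tMs - onsetMs) / (449 - onsetMs))
}

## Static board of one game: 7x7 cell grid spanning 18 x 18 degrees plus the
## switch-on button left or right of it.
makeBoard <- function(game, side, rng = TRUE) {
  pitch <- 18 / 7
  centers <- (seq_len(7) - 4) * pitch
  cells <- expand.grid(x_deg = centers, y_deg = centers)
  ballIdx <- sample(nrow(cells), 16)
  kind <- rep("free", nrow(cells))
  kind[ballIdx] <- "ball"
  rbind(
    data.frame(game = game, kind = "button",
               x_deg = ifelse(side == "left", -10.5, 10.5), y_deg = 0,
               side = side, stringsAsFactors = FALSE),
    data.frame(game = game, kind = kind,
               x_deg = cells$x_deg, y_deg = cells$y_deg,
               side = side, stringsAsFactors = FALSE))
}

## TRUE when p is within the 3 x 3 degree square centred on q.
withinSquare <- function(px, py, qx, qy, half = 1.5) {
  abs(px - qx) <= half & abs(py - qy) <= half
}

emptySchedule <- function() {
  data.frame(onset_ms = numeric(), click_time_ms = numeric(),
             fixation_type = character(), button_side = character(),
             condition_ms = numeric(), target_x_deg = numeric(),
             target_y_deg = numeric(), duration_ms = numeric(),
             game = integer(), stringsAsFactors = FALSE)
}

## One game's event schedule (times in seconds, game-local).
scheduleGame <- function(config, game, side, conditionMs) {
  thr <- conditionMs / 1000
  dur <- config@gameDurationS
  if (dur <= 0) return(emptySchedule())
  ## move pacing: triplet duration + inter-move viewing interval + the
  ## amortized share of one 10-s pause per 4-8 moves
  moveDur <- 3 * (0.04 + thr + 0.25)
  rate <- config@moveRatePerMin * ifelse(conditionMs == 1000, 0.8, 1)
  meanGap <- if (rate > 0) max(0.5, 60 / rate - moveDur - 10 / 6) else Inf

  ev <- list()
  recentClicks <- matrix(numeric(0), ncol = 3)  # t, x, y of scheduled clicks

  pushClick <- function(t, x, y) {
    recentClicks <<- rbind(recentClicks, c(t, x, y))
  }
  clearOld <- function(t) {
    if (nrow(recentClicks))
      recentClicks <<- recentClicks[recentClicks[, 1] > t - 3.5, ,
                                    drop = FALSE]
  }
  clashes <- function(t, x, y) {
    nrow(recentClicks) > 0 &&
      any(withinSquare(x, y, recentClicks[, 2], recentClicks[, 3]))
  }

  board <- makeBoard(game, side)
  balls <- board[board$kind == "ball", ]
  frees <- board[board$kind == "free", ]
  button <- board[board$kind == "button", ]

  addEvent <- function(onset, durS, type, x, y) {
    onset <- round(onset * 500) / 500       # snap to the 2-ms sample grid
    click <- if (durS >= thr) onset + thr else NA_real_
    ev[[length(ev) + 1]] <<- data.frame(
      onset_ms = onset * 1000, click_time_ms = click * 1000,
      fixation_type = type, button_side = side,
      condition_ms = conditionMs, target_x_deg = x, target_y_deg = y,
      duration_ms = durS * 1000, game = game, stringsAsFactors = FALSE)
    if (!is.na(click)) pushClick(click, x, y)
  }

  ## fill [from, to) with back-to-back spontaneous ball fixations separated
  ## by 40-ms saccades; the eye is never parked between fixations, so the
  ## dwell detector sees the scheduled durations, not inflated ones
  lastSpont <- -1L
  fillSpontaneous <- function(from, to) {
    if (!is.finite(config@spontaneousGapS)) return(to)
    t <- from
    hardEnd <- dur - 1.9
    while (t < to) {
      on <- t + config@spontaneousGapS
      d <- stats::rlnorm(1, config@spontaneousMeanlog, config@spontaneousSdlog)
      if (on + d > hardEnd) break
      for (i in seq_len(20)) {
        ci <- sample(nrow(balls), 1)
        if (ci == lastSpont) next          # same-cell runs would merge dwells
        cell <- balls[ci, ]
        clearOld(on)
        if (d >= thr && clashes(on + thr, cell$x_deg, cell$y_deg)) next
        break
      }
      lastSpont <<- ci
      addEvent(on, d, "NONCONTROL", cell$x_deg, cell$y_deg)
      t <- on + d
    }
    max(t, min(to, hardEnd))
  }

  pickTarget <- function(pool, tClick) {
    for (i in seq_len(20)) {
      cell <- pool[sample(nrow(pool), 1), ]
      clearOld(tClick)
      if (!clashes(tClick, cell$x_deg, cell$y_deg)) return(cell)
    }
    cell
  }

  t <- 0.5
  if (rate == 0) {
    fillSpontaneous(t, dur - 2)
  } else {
    movesUntilPause <- sample(4:8, 1)
    repeat {
      gap <- stats::runif(1, 0.5, 1.5) * meanGap
      if (t + gap + moveDur > dur - 2) {
        fillSpontaneous(t, dur - 2)
        break
      }
      t <- fillSpontaneous(t, t + gap)
      for (type in c("BUTTON", "BALL", "FREECELL")) {
        t <- t + 0.04
        linger <- stats::runif(1, 0.2, 0.3)
        tgt <- switch(type,
                      BUTTON = button,
                      BALL = pickTarget(balls, t + thr),
                      FREECELL = pickTarget(frees, t + thr))
        addEvent(t, thr + linger, type, tgt$x_deg, tgt$y_deg)
        t <- t + thr + linger
      }
      movesUntilPause <- movesUntilPause - 1
      if (movesUntilPause == 0) {
        if (t + 10 > dur - 2) break
        t <- fillSpontaneous(t, t + 10)
        movesUntilPause <- sample(4:8, 1)
      }
    }
  }
  out <- if (length(ev)) do.call(rbind, ev) else emptySchedule()
  attr(out, "board") <- board
  out
}

#' Generate a ground-truth fixation schedule
#'
#' Builds the event schedule of a full session: for each dwell-threshold
#' condition in the configuration, `nGamesPerCondition` games of
#' button-ball-freecell controlling triplets, spontaneous ball fixations
#' between moves, and 10-s planning pauses (spontaneous fixations only)
#' after every 4-8 moves. The switch-on button side alternates every game.
#' Scheduled click positions respect the online refractory rule (no two
#' clicks within 1.5 degrees on both axes within 3 s), so every controlling
#' event is recoverable by the dwell detector.
#'
#' @param config a [SimConfig-class].
#' @param seed integer; games use independent substreams derived from it.
#' @return data.frame of events sorted by onset (`onset_ms`,
#'   `click_time_ms` (NA for sub-threshold spontaneous fixations),
#'   `fixation_type`, `button_side`, `condition_ms`, `target_x_deg`,
#'   `target_y_deg`, `duration_ms`, `game`), with the per-game board map in
#'   `attr(, "board")`. Times are session-global ms; games are contiguous.
#' @export
makeFixationSchedule <- function(config, seed = config@seed) {
  validObject(config)
  conds <- config@dwellThresholdsMs
  nGames <- config@nGamesPerCondition
  if (nGames == 0 || config@gameDurationS == 0 || length(conds) == 0)
    return(emptySchedule())
  sides <- rep(c("left", "right"), length.out = nGames * length(conds))
  out <- list()
  boards <- list()
  g <- 0L
  for (cond in conds) {
    for (i in seq_len(nGames)) {
      g <- g + 1L
      rngState <- substreamSeed(seed, g)
      ev <- withr::with_seed(rngState, scheduleGame(config, g, sides[g], cond))
      boards[[g]] <- attr(ev, "board")
      offset <- (g - 1) * config@gameDurationS * 1000
      ev$onset_ms <- ev$onset_ms + offset
      ev$click_time_ms <- ev$click_time_ms + offset
      out[[g]] <- ev
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$onset_ms), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "board") <- do.call(rbind, boards)
  res
}

#' Simulate a full gaze+EEG session
#'
#' Runs the forward model: schedules events with [makeFixationSchedule()],
#' renders the 500 Hz gaze trace (fixations at target positions with
#' Gaussian jitter well under the dispersion criterion, 40-ms linear
#' saccades, blink gaps outside controlling dwells) and the multichannel
#' recording (per-channel pink noise, lambda wave at each fixation onset,
#' type-specific anticipatory negativity scaled by a posterior spatial
#' profile with a button-side PO4/PO3 asymmetry, and EOG saccade steps with
#' configurable frontal/posterior leakage).
#'
#' @param config a [SimConfig-class].
#' @param seed integer seed; identical (config, seed) pairs give
#'   bit-identical sessions.
#' @return an [EyeSession-class].
#' @examples
#' cfg <- simConfig(nGamesPerCondition = 1, gameDurationS = 20,
#'                  dwellThresholdsMs = 500)
#' ses <- simulateSession(cfg, seed = 7)
#' ses
#' @export
simulateSession <- function(config, seed = config@seed) {
  validObject(config)
  truth <- makeFixationSchedule(config, seed)
  board <- attr(truth, "board")
  nGamesTotal <- config@nGamesPerCondition * length(config@dwellThresholdsMs)
  n <- round(nGamesTotal * config@gameDurationS * config@samplingRate)
  dtMs <- 1000 / config@samplingRate
  tMs <- seq(0, length.out = n, by = dtMs)

  labels <- config@channelLabels
  nCh <- length(labels)

  withr::with_seed(substreamSeed(seed, 0L), {
    ## ---- gaze path ---------------------------------------------------
    x <- numeric(n); y <- numeric(n); blink <- logical(n)
    jx <- stats::rnorm(n, 0, 0.15); jy <- stats::rnorm(n, 0, 0.15)
    curX <- 0; curY <- 0; cursor <- 1L
    if (nrow(truth)) {
      for (k in seq_len(nrow(truth))) {
        on <- truth$onset_ms[k]; durMs <- truth$duration_ms[k]
        ## main-sequence saccade duration: short saccades are fast, so the
        ## in-flight samples near the target cannot pre-trigger the
        ## dispersion criterion by more than a few ms
        amp <- sqrt((truth$target_x_deg[k] - curX)^2 +
                      (truth$target_y_deg[k] - curY)^2)
        sacMs <- min(40, 14 + 2.2 * amp)
        iSacStart <- max(cursor, floor((on - sacMs) / dtMs) + 1L)
        iOn <- min(n, floor(on / dtMs) + 1L)
        iEnd <- min(n, floor((on + durMs) / dtMs))
        if (iSacStart > n) break
        if (iSacStart > cursor) {
          x[cursor:(iSacStart - 1L)] <- curX
          y[cursor:(iSacStart - 1L)] <- curY
        }
        tx <- truth$target_x_deg[k]; ty <- truth$target_y_deg[k]
        if (iOn > iSacStart) {
          frac <- seq_len(iOn - iSacStart) / (iOn - iSacStart)
          x[iSacStart:(iOn - 1L)] <- curX + frac * (tx - curX)
          y[iSacStart:(iOn - 1L)] <- curY + frac * (ty - curY)
        }
        if (iEnd >= iOn) {
          x[iOn:iEnd] <- tx
          y[iOn:iEnd] <- ty
        }
        curX <- tx; curY <- ty; cursor <- max(cursor, iEnd + 1L)
      }
    }
    if (cursor <= n) { x[cursor:n] <- curX; y[cursor:n] <- curY }
    xs <- x; ys <- y              # saccade path without jitter (for EOG)
    x <- x + jx; y <- y + jy

    ## ---- blinks: 150-ms gaps inside long spontaneous fixations, never
    ## inside controlling dwells (online control succeeded, so controlling
    ## dwells were blink-free)
    blinkPulse <- numeric(n)
    if (nrow(truth)) {
      ok <- which(truth$fixation_type == "NONCONTROL" &
                    truth$duration_ms > 400)
      nBlinks <- min(length(ok), round(n / config@samplingRate / 60 * 8))
      if (nBlinks > 0) {
        pick <- sample(ok, nBlinks)
        for (k in pick) {
          i0 <- floor((truth$onset_ms[k] + 100) / dtMs) + 1L
          i1 <- min(n, i0 + 74L)          # 150 ms
          if (i1 <= n && i0 >= 1L) {
            blink[i0:i1] <- TRUE
            hold <- max(1L, i0 - 1L)
            x[i0:i1] <- x[hold]; y[i0:i1] <- y[hold]
            ph <- seq(0, pi, length.out = i1 - i0 + 1L)
            ## the ocular potential excursion belongs to the EOG model;
            ## disabling the model (gain 0) also silences blink pulses
            if (config@eogGainUvPerDeg > 0)
              blinkPulse[i0:i1] <- blinkPulse[i0:i1] + 100 * sin(ph)
          }
        }
      }
    }

    ## ---- EEG component time series ------------------------------------
    spnAll <- numeric(n)    # amplitude-weighted negativity, POz scale
    latAll <- numeric(n)    # button-side asymmetry, added to PO4, minus PO3
    lamAll <- numeric(n)    # unit lambda shape times amplitude
    onsetIdx <- floor(truth$onset_ms / dtMs) + 1L
    for (k in seq_len(nrow(truth))) {
      iOn <- onsetIdx[k]
      iEnd <- min(n, floor((truth$onset_ms[k] + truth$duration_ms[k]) / dtMs))
      ## lambda wave, 50 ms half-cosine peaking 100 ms after onset
      iLam <- (iOn + 38L):(iOn + 62L)     # 76..124 ms
      iLam <- iLam[iLam >= 1L & iLam <= n]
      if (length(iLam)) {
        tRel <- (iLam - iOn) * dtMs
        lamAll[iLam] <- lamAll[iLam] +
          config@lambdaAmpUv * cos(pi * (tRel - 100) / 50)
      }
      ## anticipatory ramp from spnOnsetMs to fixation end
      iRamp0 <- iOn + ceiling(config@spnOnsetMs / dtMs)
      if (iRamp0 <= iEnd) {
        idx <- iRamp0:iEnd
        tRel <- (idx - iOn) * dtMs
        ramp <- (tRel - config@spnOnsetMs) / (449 - config@spnOnsetMs)
        amp <- config@spnAmpUv[[truth$fixation_type[k]]]
        spnAll[idx] <- spnAll[idx] + amp * ramp
        if (truth$fixation_type[k] == "BUTTON") {
          delta <- config@lateralityDeltaUv[[truth$button_side[k]]]
          latAll[idx] <- latAll[idx] + (delta / 2) * ramp
        }
      }
    }

    ## ---- assemble channels --------------------------------------------
    hBip <- config@eogGainUvPerDeg * xs          # bipolar hEOG signal
    vBip <- config@eogGainUvPerDeg * ys + blinkPulse
    spnW <- spnProfile(labels)
    lamW <- lambdaProfile(labels)
    data <- matrix(0, nrow = nCh, ncol = n, dimnames = list(labels, NULL))
    for (c in seq_len(nCh)) {
      lb <- labels[c]
      sdc <- if (lb %in% c("A1", "A2")) config@noiseSdUv * 0.3
             else config@noiseSdUv
      ch <- pinkNoise(n, sdc)
      if (spnW[lb] != 0) ch <- ch + spnW[lb] * spnAll
      if (lamW[lb] != 0) ch <- ch + lamW[lb] * lamAll
      if (lb == "PO4") ch <- ch + latAll
      if (lb == "PO3") ch <- ch - latAll
      ch <- ch + switch(lb,
        "hEOG-right" = hBip / 2, "hEOG-left" = -hBip / 2,
        "vEOG-upper" = vBip / 2, "vEOG-lower" = -vBip / 2,
        "Fz" = config@eogFrontalLeak * vBip,
        "F3" = config@eogFrontalLeak * (vBip - hBip / 2),
        "F4" = config@eogFrontalLeak * (vBip + hBip / 2),
        0)
      if (config@eogPosteriorLeak != 0 && lb %in% posteriorChannels())
        ch <- ch + config@eogPosteriorLeak * (hBip + vBip) / 2
      data[c, ] <- ch
    }

    gaze <- data.frame(t_ms = tMs, x_deg = x, y_deg = y, blink = blink)
    rec <- new("EegRecording", data = data, labels = labels,
               sampleRate = config@samplingRate, reference = "raw")
    attr(truth, "board") <- NULL
    new("EyeSession", gaze = gaze, recording = rec, truth = truth,
        board = if (is.null(board)) data.frame() else board,
        config = config, seed = as.integer(seed))
  })
}

#' Export a session to plain-text files
#'
#' Writes the gaze trace, the recording (wide TSV: `time_ms` plus one
#' column per channel, muV), the ground-truth events and a YAML echo of the
#' configuration into a directory.
#'
#' @param session an [EyeSession-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
exportSession <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("gaze.tsv", "recording.tsv", "truth.tsv",
                            "config.yaml"))
  utils::write.table(gazeData(session), paths[1], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  rec <- recording(session)
  wide <- data.frame(time_ms = gazeData(session)$t_ms,
                     t(recordingData(rec)), check.names = FALSE)
  utils::write.table(wide, paths[2], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(truthEvents(session), paths[3], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg <- simulationConfig(session)
  echo <- list(seed = cfg@seed, samplingRate = cfg@samplingRate,
               nGamesPerCondition = cfg@nGamesPerCondition,
               gameDurationS = cfg@gameDurationS,
               dwellThresholdsMs = as.numeric(cfg@dwellThresholdsMs),
               moveRatePerMin = cfg@moveRatePerMin,
               spnAmpUv = as.list(cfg@spnAmpUv),
               spnOnsetMs = cfg@spnOnsetMs,
               lateralityDeltaUv = as.list(cfg@lateralityDeltaUv),
               lambdaAmpUv = cfg@lambdaAmpUv,
               noiseSdUv = cfg@noiseSdUv,
               eogGainUvPerDeg = cfg@eogGainUvPerDeg,
               eogPosteriorLeak = cfg@eogPosteriorLeak)
  writeLines(yaml::as.yaml(echo), paths[4])
  invisible(paths)
}
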