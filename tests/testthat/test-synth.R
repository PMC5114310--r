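test_that("spnComponent is a normalized ramp starting at onset", {
  expect_equal(spnComponent(250, -5.3, 300), 0)
  expect_equal(spnComponent(seq(0, 1400, 2), 0, 300),
               rep(0, length(seq(0, 1400, 2))))
  ## discrete mean over the 400-500 ms sample grid equals the amplitude
  grid <- seq(400, 498, 2)
  expect_equal(mean(spnComponent(grid, -5.3, 300)), -5.3)
  expect_equal(mean(spnComponent(grid, -2.0, 300)), -2.0)
  ## onset at/after 449 leaves the normalization undefined
  expect_error(spnComponent(400, -5, 449), "onset")
})

test_that("degenerate configurations give empty schedules or errors", {
  cfg <- simConfig(moveRatePerMin = 0, spontaneousGapS = Inf,
                   nGamesPerCondition = 1, gameDurationS = 60)
  expect_equal(nrow(makeFixationSchedule(cfg, 1)), 0)
  cfg0 <- simConfig(gameDurationS = 0)
  expect_equal(nrow(makeFixationSchedule(cfg0, 1)), 0)
  expect_error(simConfig(moveRatePerMin = -1), "invalid config")
  expect_error(simConfig(gameDurationS = -5), "invalid config")
  expect_error(simConfig(spnAmpUv = c(BUTTON = 1, BALL = -1, FREECELL = -1,
                                      NONCONTROL = -1)))
})

test_that("schedules have the move-triplet and pause structure", {
  cfg <- simConfig(nGamesPerCondition = 2, gameDurationS = 120)
  sch <- makeFixationSchedule(cfg, seed = 4)
  expect_false(is.unsorted(sch$onset_ms))
  ## events do not overlap
  expect_true(all(diff(sch$onset_ms) >=
                    sch$duration_ms[-nrow(sch)] - 1e-9))
  ## controlling clicks sit exactly one threshold after onset
  ctrl <- sch[sch$fixation_type != "NONCONTROL", ]
  expect_equal(ctrl$click_time_ms - ctrl$onset_ms, ctrl$condition_ms)
  ## every ball is preceded by a button, every free cell by a ball,
  ## within its move (triplet structure)
  prevCtrl <- c(NA, ctrl$fixation_type[-nrow(ctrl)])
  expect_true(all(prevCtrl[ctrl$fixation_type == "BALL"] == "BUTTON"))
  expect_true(all(prevCtrl[ctrl$fixation_type == "FREECELL"] == "BALL"))
  ## no spontaneous fixation between a button click and move completion
  for (i in which(sch$fixation_type == "BUTTON")) {
    j <- i
    while (j < nrow(sch) && sch$fixation_type[j] != "FREECELL") {
      j <- j + 1
    }
    expect_false(any(sch$fixation_type[i:j] == "NONCONTROL"))
  }
  ## button side alternates every game
  sides <- tapply(sch$button_side, sch$game, function(s) unique(s))
  expect_true(all(vapply(sides, length, 1L) == 1))
  expect_true(all(sides[-1] != sides[-length(sides)]))
})

test_that("spontaneous fixation counts match the behavioral anchors", {
  ## per 4-game 500-ms block: spontaneous fixations of >= 500 ms; and per
  ## 4-game 1000-ms block: >= 1000 ms (a heavy-tailed, much rarer event)
  n500 <- n1000 <- numeric(12)
  for (s in seq_len(12)) {
    cfg <- simConfig(dwellThresholdsMs = 500)
    sch <- makeFixationSchedule(cfg, seed = 100 + s)
    n500[s] <- sum(sch$fixation_type == "NONCONTROL" &
                     sch$duration_ms >= 500)
    cfg2 <- simConfig(dwellThresholdsMs = 1000)
    sch2 <- makeFixationSchedule(cfg2, seed = 300 + s)
    n1000[s] <- sum(sch2$fixation_type == "NONCONTROL" &
                      sch2$duration_ms >= 1000)
  }
  expect_gt(mean(n500), 158.6 * 0.8)
  expect_lt(mean(n500), 158.6 * 1.2)
  expect_gt(mean(n1000), 10.8 * 0.5)
  expect_lt(mean(n1000), 10.8 * 1.5)
})

test_that("simulation is deterministic in (config, seed)", {
  cfg <- simConfig(nGamesPerCondition = 1, gameDurationS = 20,
                   dwellThresholdsMs = 500)
  a <- simulateSession(cfg, seed = 9)
  b <- simulateSession(cfg, seed = 9)
  expect_identical(recordingData(recording(a)), recordingData(recording(b)))
  expect_identical(gazeData(a), gazeData(b))
  expect_identical(truthEvents(a), truthEvents(b))
  c <- simulateSession(cfg, seed = 10)
  expect_false(identical(recordingData(recording(a)),
                         recordingData(recording(c))))
})

test_that("recording is zero when all components are disabled", {
  cfg <- simConfig(nGamesPerCondition = 1, gameDurationS = 15,
                   dwellThresholdsMs = 500, noiseSdUv = 0,
                   lambdaAmpUv = 0, eogGainUvPerDeg = 0,
                   eogFrontalLeak = 0,
                   lateralityDeltaUv = c(left = 0, right = 0),
                   spnAmpUv = c(BUTTON = 0, BALL = 0, FREECELL = 0,
                                NONCONTROL = 0))
  ses <- simulateSession(cfg, seed = 3)
  dat <- recordingData(recording(ses))
  expect_true(all(dat == 0))
})

test_that("noise-free sessions recover configured amplitudes exactly", {
  cfg <- simConfig(nGamesPerCondition = 1, gameDurationS = 90,
                   dwellThresholdsMs = 500, noiseSdUv = 0)
  ses <- simulateSession(cfg, seed = 2)
  rec <- rereferenceLinkedEarlobes(recording(ses))
  tr <- truthEvents(ses)
  tr <- tr[!is.na(tr$click_time_ms) & tr$onset_ms > 600, ]
  ep <- baselineCorrect(extractEpochs(rec, tr))
  s <- epochAmplitudeSummary(ep)
  m <- tapply(s$poz_uv, s$fixation_type, mean)
  expect_equal(m[["BUTTON"]], -5.3, tolerance = 1e-6)
  expect_equal(m[["BALL"]], -3.5, tolerance = 1e-6)
  expect_equal(m[["FREECELL"]], -1.5, tolerance = 1e-6)
  ## spontaneous ramps truncate at fixation end; tiny grid effect allowed
  expect_equal(m[["NONCONTROL"]], -2.0, tolerance = 0.01)
  ## button-side PO4-PO3 asymmetry equals the configured laterality
  but <- s[s$fixation_type == "BUTTON", ]
  lat <- tapply(but$po4_po3_uv, but$button_side, mean)
  delta <- simulationConfig(ses)@lateralityDeltaUv
  expect_equal(lat[["left"]], delta[["left"]], tolerance = 1e-6)
})

test_that("posterior channels are EOG-free when the leak is zero", {
  cfg1 <- simConfig(nGamesPerCondition = 1, gameDurationS = 15,
                    dwellThresholdsMs = 500, noiseSdUv = 0)
  cfg2 <- simConfig(nGamesPerCondition = 1, gameDurationS = 15,
                    dwellThresholdsMs = 500, noiseSdUv = 0,
                    eogGainUvPerDeg = 32)
  a <- recordingData(recording(simulateSession(cfg1, seed = 6)))
  b <- recordingData(recording(simulateSession(cfg2, seed = 6)))
  expect_identical(a[posteriorChannels(), ], b[posteriorChannels(), ])
  expect_false(identical(a["hEOG-right", ], b["hEOG-right", ]))
})

test_that("bipolar hEOG is quiet in the analysis window of button epochs", {
  ## mirrors the butterfly-plot check: on the grand average over button
  ## epochs (baseline-corrected), the saccade-dominated [-100, 100) ms
  ## interval dwarfs the residual in the 200-500 ms analysis window
  blk <- cachedBlock()
  ses <- blk$session
  rec <- recording(ses)
  heog <- bipolarEOG(rec)["hEOG", ]
  labs <- c("hEOG", "dummy")
  hrec <- new("EegRecording",
              data = rbind(heog, 0), labels = labs,
              sampleRate = 500, reference = "linked_earlobes")
  for (side in c("left", "right")) {
    tr <- truthEvents(ses)
    tr <- tr[tr$fixation_type == "BUTTON" & tr$button_side == side &
               tr$onset_ms > 600, ]
    ep <- baselineCorrect(extractEpochs(hrec, tr))
    avg <- apply(epochArray(ep)["hEOG", , , drop = FALSE], 2, mean)
    mid <- mean(abs(avg[epochSampleIndexForTest(200, 500)]))
    sacc <- mean(abs(avg[epochSampleIndexForTest(-100, 100)]))
    expect_lt(mid, 0.05 * sacc)
  }
})

test_that("grand averages recover configured amplitudes under noise", {
  blk <- cachedBlock()
  ses <- blk$session
  rec <- rereferenceLinkedEarlobes(recording(ses))
  tr <- truthEvents(ses)
  tr <- tr[!is.na(tr$click_time_ms) & tr$onset_ms > 600, ]
  ep <- baselineCorrect(extractEpochs(rec, tr))
  s <- epochAmplitudeSummary(ep)
  cfg <- simulationConfig(ses)
  for (tp in c("BUTTON", "BALL", "NONCONTROL")) {
    v <- s$poz_uv[s$fixation_type == tp]
    expect_gte(length(v), 140)
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - cfg@spnAmpUv[[tp]]), 2 * se)
  }
})
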