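## Independent brute-force oracles used to validate the optimized
## implementations. Written deliberately as naive per-sample / per-candidate
## loops, sharing no code with the package internals.

## Sliding-window dwell oracle: checks the dispersion range and both
## refractory rules at every sample.
oracleDwells <- function(gaze, thresholdMs, dispersionDeg = 2,
                         refractoryMs = 3000, half = 1.5) {
  t <- gaze$t_ms
  dt <- t[2] - t[1]
  w <- round(thresholdMs / dt)
  clicks <- data.frame(click_time_ms = numeric(), onset_ms = numeric(),
                       click_x_deg = numeric(), click_y_deg = numeric())
  lastClick <- -Inf
  for (i in seq(w + 1, length(t))) {
    if (t[i] - thresholdMs < lastClick) next
    idx <- (i - w):i
    keep <- idx[!gaze$blink[idx]]
    if (!length(keep)) next
    xs <- gaze$x_deg[keep]
    ys <- gaze$y_deg[keep]
    if (max(xs) - min(xs) > dispersionDeg) next
    if (max(ys) - min(ys) > dispersionDeg) next
    cx <- stats::median(xs)
    cy <- stats::median(ys)
    recent <- clicks[clicks$click_time_ms >= t[i] - refractoryMs, ,
                     drop = FALSE]
    if (nrow(recent) &&
        any(abs(cx - recent$click_x_deg) <= half &
              abs(cy - recent$click_y_deg) <= half)) next
    clicks[nrow(clicks) + 1, ] <- c(t[i], t[i] - thresholdMs, cx, cy)
    lastClick <- t[i]
  }
  clicks
}

## Random gaze trace: fixation-like holds at random positions interleaved
## with drift segments and occasional blinks; exercises dwells, the
## dispersion bound and both refractory rules.
randomTrace <- function(durationS, seed) {
  withr::with_seed(seed, {
    n <- durationS * 500
    x <- numeric(n)
    y <- numeric(n)
    blink <- logical(n)
    i <- 1L
    px <- 0
    py <- 0
    while (i <= n) {
      mode <- sample(c("hold", "drift"), 1, prob = c(0.7, 0.3))
      len <- min(n - i + 1L, sample(100:500, 1))
      idx <- i:(i + len - 1L)
      if (mode == "hold") {
        px <- stats::runif(1, -10, 10)
        py <- stats::runif(1, -10, 10)
        jit <- stats::runif(1, 0.05, 0.4)
        x[idx] <- px + stats::rnorm(len, 0, jit)
        y[idx] <- py + stats::rnorm(len, 0, jit)
      } else {
        x[idx] <- px + cumsum(stats::rnorm(len, 0, 0.15))
        y[idx] <- py + cumsum(stats::rnorm(len, 0, 0.15))
        px <- x[idx[len]]
        py <- y[idx[len]]
      }
      if (stats::runif(1) < 0.15) {
        b <- idx[seq_len(min(len, 60))]
        blink[b] <- TRUE
        x[b] <- x[b] + stats::runif(1, -5, 5)   # tracker noise during blink
      }
      i <- i + len
    }
    data.frame(t_ms = seq(0, by = 2, length.out = n), x_deg = x,
               y_deg = y, blink = blink)
  })
}

## O(n^2) exhaustive threshold-classifier oracle with the same tie-break
## order (error, then smaller threshold, then polarity +1).
oracleWeak <- function(x, y, errorType = "balanced") {
  xs <- sort(unique(x))
  cands <- c(-Inf, (xs[-length(xs)] + xs[-1]) / 2, Inf)
  best <- NULL
  for (p in c(1, -1)) {
    for (th in cands) {
      pred <- if (p == 1) as.integer(x >= th) else as.integer(x <= th)
      e0 <- mean(pred[y == 0] == 1)
      e1 <- mean(pred[y == 1] == 0)
      err <- if (errorType == "balanced") (e0 + e1) / 2
             else mean(pred != y)
      if (is.null(best) || err < best$err - 1e-12 ||
          (abs(err - best$err) <= 1e-12 &&
             (th < best$th || (th == best$th && p > best$p)))) {
        best <- list(err = err, th = th, p = p)
      }
    }
  }
  best
}

## Naive vote-counting committee error for the greedy-selection oracle.
oracleVoteError <- function(X, y, members, pool) {
  votes <- rep(0, nrow(X))
  for (j in members) {
    pr <- if (pool$polarity[j] == 1) X[, j] >= pool$threshold[j]
          else X[, j] <= pool$threshold[j]
    votes <- votes + pr
  }
  pred <- as.integer(votes > length(members) / 2)
  (mean(pred[y == 0] == 1) + mean(pred[y == 1] == 0)) / 2
}

## Epoch time grid helper: 1-based sample indices of [from, to) ms.
epochSampleIndexForTest <- function(from, to) {
  t <- seq(-500, 1498, by = 2)
  which(t >= from & t < to)
}

## Shared simulated participant block (expensive; built once per test run).
.sessionCache <- new.env(parent = emptyenv())
cachedBlock <- function() {
  if (is.null(.sessionCache$block)) {
    cfg <- simConfig(dwellThresholdsMs = 500)
    ses <- simulateSession(cfg, seed = 101)
    .sessionCache$block <- list(session = ses,
                                processed = processSession(ses,
                                                           applyNotch = FALSE))
  }
  .sessionCache$block
}
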