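## synthetic feature sets with a controllable effect size
synthFeatures <- function(n0 = 60, n1 = 60, effect = 1, d = 169, seed = 1,
                          types = NULL) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n0 * d), ncol = d),
               matrix(rnorm(n1 * d), ncol = d))
    X[(n0 + 1):(n0 + n1), 1:20] <- X[(n0 + 1):(n0 + n1), 1:20] + effect
    if (is.null(types)) types <- rep("BUTTON", n1)
    info <- data.frame(fixation_type = c(rep("NONCONTROL", n0), types))
    list(X = X, info = info)
  })
}

test_that("trainset variants define targets per the protocol", {
  sf <- synthFeatures(10, 30, types = rep(c("BUTTON", "BALL", "FREECELL"),
                                          each = 10))
  t1 <- buildTrainset(sf$X, sf$info, variant = 1)
  expect_equal(nrow(t1$X), 20)                    # 10 button + 10 noncontrol
  expect_equal(sum(t1$y), 10)
  expect_true(all(t1$info$fixation_type %in% c("BUTTON", "NONCONTROL")))
  expect_equal(nrow(t1$heldout$X), 20)            # ball + free cell held out
  t2 <- buildTrainset(sf$X, sf$info, variant = 2)
  expect_equal(nrow(t2$X), 40)
  expect_equal(sum(t2$y), 30)
  expect_null(t2$heldout)
  noNon <- list(X = sf$X[11:40, ], info = sf$info[11:40, , drop = FALSE])
  expect_error(buildTrainset(noNon$X, noNon$info, 1), "non-controlling")
})

test_that("confusion metrics count the negative class as non-controlling", {
  expect_equal(confusionMetrics(c(0, 0, 1, 1), c(0, 0, 1, 1)),
               c(specificity = 1, sensitivity = 1))
  yt <- c(rep(1, 10), rep(0, 10))
  yp <- c(rep(1, 3), rep(0, 7), rep(0, 9), 1)
  expect_equal(confusionMetrics(yt, yp),
               c(specificity = 0.9, sensitivity = 0.3))
  expect_equal(confusionMetrics(c(0, 1), c(0, 0)),
               c(specificity = 1, sensitivity = 0))
  expect_warning(m <- confusionMetrics(c(1, 1), c(1, 0)), "specificity")
  expect_true(is.na(m[["specificity"]]))
})

test_that("AUC follows the rank formulation with half-credit ties", {
  expect_equal(aucScore(c(1, 2, 10, 20), c(0, 0, 1, 1)), 1)
  expect_equal(aucScore(rep(3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(aucScore(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_error(aucScore(1:3, c(1, 1, 1)), "classes")
  ## cross-check against an independent implementation
  sc <- withr::with_seed(5, rnorm(200))
  y <- withr::with_seed(6, rbinom(200, 1, 0.4))
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(aucScore(sc, y), ref, tolerance = 1e-12)
})

test_that("false-alarm arithmetic matches the reported example", {
  expect_equal(falseAlarmRate(160, 20, 0.9), 0.8)
  expect_equal(falseAlarmRate(123, 20, 1.0), 0)
  expect_equal(falseAlarmRate(120, 20, 0.85), 0.9)
  expect_error(falseAlarmRate(100, 0, 0.9), "positive")
  expect_error(falseAlarmRate(100, 10, 1.2), "0, 1")
})

test_that("cross-validation is a partition with per-fold calibration", {
  sf <- synthFeatures(n0 = 60, n1 = 60, effect = 8, seed = 3)
  ts <- buildTrainset(sf$X, sf$info, variant = 1)
  ## effect size 8 on 20 features is linearly separable in practice;
  ## sensitivity and AUC are perfect for both classifiers
  for (cls in c("lda", "committee")) {
    rp <- runCV(ts, cls, seed = 7)
    expect_equal(nrow(rp$folds), 5)
    expect_true(all(rp$folds$sens_button == 1))
    expect_true(all(rp$folds$auc == 1))
    if (cls == "committee") {
      ## integer votes of a separable committee leave the calibrated
      ## threshold above every non-target vote count
      expect_true(all(rp$folds$specificity == 1))
    } else {
      ## continuous scores: the smallest feasible threshold sits inside
      ## the non-target score distribution, so fresh non-targets exceed it
      ## at roughly the (1 - target) rate even under perfect separation;
      ## with 12 non-targets per test fold the per-fold estimate is coarse
      expect_true(all(rp$folds$specificity >= 0.5))
      expect_gte(mean(rp$folds$specificity), 0.75)
    }
  }
})

test_that("variant-1 held-out strata are scored with every fold's model", {
  sf <- synthFeatures(60, 60, effect = 8, seed = 4,
                      types = rep(c("BUTTON", "BALL"), each = 30))
  ts <- buildTrainset(sf$X, sf$info, variant = 1)
  expect_equal(sum(ts$info$fixation_type == "BALL"), 0)
  rep <- runCV(ts, "lda", seed = 2)
  expect_true(all(is.finite(rep$folds$sens_ball)))
  ## ball rows carry the same effect here, so the button-trained model
  ## transfers to them
  expect_gt(rep$mean[["sens_ball"]], 0.8)
})

test_that("transfer sets mirror same-condition sensitivity when identical", {
  sf <- synthFeatures(80, 80, effect = 1.2, seed = 5)
  ts <- buildTrainset(sf$X, sf$info, variant = 1)
  tfr <- synthFeatures(80, 80, effect = 1.2, seed = 6)
  rep <- runCV(ts, "lda", seed = 8, transfer = tfr)
  sameSens <- rep$mean[["sens_button"]]
  transSens <- rep$mean[["transfer_sens_button"]]
  n <- 80
  se <- sqrt(max(sameSens * (1 - sameSens), 0.05) / n)
  expect_lt(abs(sameSens - transSens), 4 * se + 0.1)
})

test_that("null features yield calibrated specificity and chance AUC", {
  sf <- synthFeatures(100, 100, effect = 0, seed = 9)
  ts <- buildTrainset(sf$X, sf$info, variant = 1)
  rep <- runCV(ts, "lda", seed = 10)
  expect_gt(rep$mean[["specificity"]], 0.8)
  expect_lt(rep$mean[["sens_button"]], 0.3)
  expect_lt(abs(rep$mean[["auc"]] - 0.5), 0.2)
})

test_that("paired amplitude statistics use the textbook paired t", {
  ## participants' laterality means: left = a, right = b
  df <- data.frame(
    participant = rep(1:4, each = 2),
    fixation_type = "BUTTON",
    condition_ms = 500,
    button_side = rep(c("left", "right"), 4),
    poz_uv = 0,
    po4_po3_uv = c(1, 2, 2, 3, 3, 5, 4, 6))
  st <- amplitudeStats(df)
  expect_equal(st$lateralityTest$t, -5.196152, tolerance = 1e-6)
  expect_equal(st$lateralityTest$df, 3)
  expect_equal(st$laterality$po4_po3_uv[st$laterality$button_side == "left"],
               mean(c(1, 2, 3, 4)))
  ## degenerate input: identical sides -> test flagged unavailable
  df0 <- df
  df0$po4_po3_uv <- 1
  expect_true(is.na(amplitudeStats(df0)$lateralityTest$t))
})

test_that("grand averages behave like arithmetic means", {
  labs <- channelLabels()
  arr <- array(0, dim = c(length(labs), 1000, 4),
               dimnames = list(labs, NULL, NULL))
  arr["POz", 300, ] <- c(2, 2, 1, -1)
  ep <- new("FixationEpochs", data = arr, channels = labs,
            events = data.frame(fixation_type = c("BUTTON", "BUTTON",
                                                  "BALL", "BALL")),
            sampleRate = 500, baselineApplied = TRUE)
  ga <- grandAverage(ep)
  expect_equal(unname(ga$BUTTON["POz", 300]), 2)  # identical epochs
  expect_equal(unname(ga$BALL["POz", 300]), 0)    # +x and -x cancel
  expect_message(grandAverage(ep, types = "FREECELL"), "skipped")
  ## averaging n noisy epochs shrinks noise like 1/sqrt(n)
  resid <- replicate(20, {
    nz <- array(rnorm(length(labs) * 1000 * 25, sd = 3),
                dim = c(length(labs), 1000, 25),
                dimnames = list(labs, NULL, NULL))
    epn <- new("FixationEpochs", data = nz, channels = labs,
               events = data.frame(fixation_type = rep("BUTTON", 25)),
               sampleRate = 500, baselineApplied = TRUE)
    grandAverage(epn)$BUTTON["POz", 500]
  })
  expect_equal(sd(resid), 3 / sqrt(25), tolerance = 0.3)
})
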