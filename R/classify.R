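## The two classifiers: a committee of greedily selected one-dimensional
## threshold classifiers, and LDA with analytic shrinkage of the pooled
## covariance. Labels are 0 = non-controlling (negative class) and
## 1 = controlling (target). Decision thresholds are calibrated separately
## on validation data (see calibrateThreshold).

#' Train a one-dimensional threshold classifier
#'
#' Exhaustive search over candidate thresholds (the midpoints of adjacent
#' distinct sorted values, plus -Inf and +Inf) and both polarities
#' (predict target iff `polarity * x >= polarity * threshold`), minimizing
#' the balanced error `(FP/n0 + FN/n1)/2` (or the plain error rate when
#' `errorType = "plain"`). Ties are broken toward the smaller threshold,
#' then toward polarity +1, so the fit is deterministic.
#'
#' @param x numeric values of one feature.
#' @param y labels, 0 (non-controlling) or 1 (controlling); both classes
#'   must be present.
#' @param errorType `"balanced"` (default) or `"plain"`.
#' @return one-row data.frame with `threshold`, `polarity`, `trainError`.
#' @export
fitWeakClassifier <- function(x, y, errorType = c("balanced", "plain")) {
  errorType <- match.arg(errorType)
  y <- as.integer(y)
  n0 <- sum(y == 0)
  n1 <- sum(y == 1)
  if (n0 == 0 || n1 == 0) stop("both classes must be present")
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  n <- length(xs)
  ## candidate cut after position k: threshold between xs[k] and xs[k+1];
  ## k = 0 -> -Inf, k = n -> +Inf; only distinct-value boundaries
  cum1 <- cumsum(ys)            # targets among the k smallest
  cum0 <- seq_len(n) - cum1
  bounds <- which(diff(xs) > 0)
  ks <- c(0L, bounds, n)
  theta <- c(-Inf, (xs[bounds] + xs[bounds + 1]) / 2, Inf)
  n1k <- c(0, cum1)[ks + 1]     # targets among bottom k
  n0k <- c(0, cum0)[ks + 1]
  ## error numerators in exact integer arithmetic (balanced error has the
  ## common denominator 2 n0 n1), so equal errors tie exactly and the
  ## threshold/polarity tie-breaks are reproducible
  ## polarity +1: predict 1 iff x >= theta -> FN = n1k, FP = n0 - n0k
  ## polarity -1: predict 1 iff x <= theta -> FP = n0k, FN = n1 - n1k
  errNumPos <- if (errorType == "balanced")
    (n0 - n0k) * n1 + n1k * n0 else (n0 - n0k) + n1k
  errNumNeg <- if (errorType == "balanced")
    n0k * n1 + (n1 - n1k) * n0 else n0k + (n1 - n1k)
  denom <- if (errorType == "balanced") 2 * n0 * n1 else n
  cand <- data.frame(
    threshold = c(theta, theta),
    polarity = rep(c(1, -1), each = length(theta)),
    errNum = c(errNumPos, errNumNeg))
  best <- cand[order(cand$errNum, cand$threshold, -cand$polarity), ][1, ]
  data.frame(threshold = best$threshold, polarity = best$polarity,
             trainError = best$errNum / denom)
}

weakPredict <- function(x, threshold, polarity) {
  if (polarity >= 0) x >= threshold else x <= threshold
}

#' Build a committee of greedy threshold classifiers
#'
#' Trains one weak threshold classifier per feature ([fitWeakClassifier()]),
#' then selects `k` of them by forward greedy search without replacement:
#' the first member is the pool minimum; each further iteration adds the
#' classifier that minimizes the committee's voting error, where a
#' provisional committee of size m predicts target iff more than m/2
#' members vote target (an exact half votes non-target). Ties are broken
#' toward the lowest feature index. The operational vote threshold is
#' calibrated afterwards ([calibrateThreshold()]), not fixed at majority.
#'
#' @param X numeric matrix, epochs x features.
#' @param y labels 0/1, both classes present.
#' @param k committee size (default 15).
#' @param errorType `"balanced"` (default) or `"plain"` selection error.
#' @return an uncalibrated [Committee-class].
#' @export
buildCommittee <- function(X, y, k = 15, errorType = c("balanced", "plain")) {
  errorType <- match.arg(errorType)
  y <- as.integer(y)
  d <- ncol(X)
  if (k > d) stop("committee size exceeds the number of features")
  if (length(unique(y)) < 2) stop("both classes must be present")
  pool <- do.call(rbind, lapply(seq_len(d), function(j)
    fitWeakClassifier(X[, j], y, errorType)))
  pool$feature <- seq_len(d)
  P <- matrix(FALSE, nrow = nrow(X), ncol = d)
  for (j in seq_len(d))
    P[, j] <- weakPredict(X[, j], pool$threshold[j], pool$polarity[j])
  n0 <- sum(y == 0)
  n1 <- sum(y == 1)
  selected <- integer(0)
  votes <- numeric(nrow(X))
  for (m in seq_len(k)) {
    candidates <- setdiff(seq_len(d), selected)
    ## integer error numerators (common denominator) so ties are exact and
    ## the lowest-feature-index tie-break is reproducible
    errs <- vapply(candidates, function(j) {
      pred <- (votes + P[, j]) > m / 2
      fp <- sum(pred & y == 0)
      fn <- sum(!pred & y == 1)
      if (errorType == "balanced") fp * n1 + fn * n0 else fp + fn
    }, numeric(1))
    j <- candidates[order(errs, candidates)[1]]
    selected <- c(selected, j)
    votes <- votes + P[, j]
  }
  new("Committee",
      members = data.frame(feature = selected,
                           threshold = pool$threshold[selected],
                           polarity = pool$polarity[selected],
                           trainError = pool$trainError[selected]),
      voteThreshold = NA_real_, errorType = errorType)
}

#' Fit shrinkage-regularized LDA
#'
#' Linear discriminant with the pooled within-class covariance shrunk
#' toward a scaled identity: `Sigma = (1 - gamma) S + gamma nu I` with
#' `nu = trace(S)/d`. The shrinkage intensity `gamma` is estimated by the
#' analytic (Ledoit-Wolf type) estimator from the sample variances of the
#' centred cross products, clipped to [0, 1], unless overridden. The
#' weight vector is `w = Sigma^{-1} (mu1 - mu0)` and the bias
#' `b = -w'(mu0 + mu1)/2`, so the score of the class-mean midpoint is 0.
#' Shrinkage guarantees a finite solution even with fewer trials than
#' features.
#'
#' @param X numeric matrix, epochs x features.
#' @param y labels 0/1, both classes present; at least 3 rows.
#' @param gamma optional fixed shrinkage intensity in [0, 1]; `NULL`
#'   (default) estimates it from the training data.
#' @return an uncalibrated [ShrinkageLDA-class].
#' @export
fitShrinkageLDA <- function(X, y, gamma = NULL) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- nrow(X)
  if (n < 3) stop("need at least 3 training epochs")
  d <- ncol(X)
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  Xc <- X
  Xc[y == 0, ] <- sweep(X[y == 0, , drop = FALSE], 2, mu0)
  Xc[y == 1, ] <- sweep(X[y == 1, , drop = FALSE], 2, mu1)
  S <- crossprod(Xc) / (n - 1)
  nu <- sum(diag(S)) / d
  if (is.null(gamma)) {
    ## analytic shrinkage: gamma* = n/(n-1)^2 sum_ij Var(z_ij) /
    ##   sum_ij (S_ij - nu delta_ij)^2, z_ij(k) = xc_ki xc_kj
    ## sum_ij Var(z_ij) without forming the d^2 cross products:
    ## sum_ijk z_ijk^2 = sum_k (sum_i xc_ki^2)^2 and
    ## mean_k z_ij = (n-1)/n S_ij
    r <- rowSums(Xc^2)
    varZ <- (sum(r^2) - n * ((n - 1) / n)^2 * sum(S^2)) / (n - 1)
    target <- S
    diag(target) <- diag(target) - nu
    denom <- sum(target^2)
    gamma <- if (denom <= 0) 1 else
      min(1, max(0, (n / (n - 1)^2) * varZ / denom))
  }
  Sigma <- (1 - gamma) * S
  diag(Sigma) <- diag(Sigma) + gamma * nu
  w <- drop(solve(Sigma, mu1 - mu0))
  b <- -sum(w * (mu0 + mu1)) / 2
  new("ShrinkageLDA", w = w, b = b, gamma = gamma, nu = nu,
      mu0 = mu0, mu1 = mu1, scoreThreshold = NA_real_)
}

#' @describeIn classifierScore integer vote counts of the committee members.
#' @export
setMethod("classifierScore", "Committee", function(object, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  m <- committeeMembers(object)
  votes <- numeric(nrow(X))
  for (j in seq_len(nrow(m)))
    votes <- votes + weakPredict(X[, m$feature[j]], m$threshold[j],
                                 m$polarity[j])
  as.integer(votes)
})

#' @describeIn classifierScore LDA projection `w'x + b`.
#' @export
setMethod("classifierScore", "ShrinkageLDA", function(object, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  drop(X %*% object@w) + object@b
})

#' Score a feature matrix with an LDA model
#'
#' Convenience wrapper around [classifierScore()] for the LDA model.
#'
#' @param model a [ShrinkageLDA-class].
#' @param X feature matrix or single feature vector.
#' @return numeric scores `w'x + b`.
#' @export
ldaScore <- function(model, X) classifierScore(model, X)

#' Calibrate a specificity-targeted decision threshold
#'
#' Returns the smallest threshold theta such that the fraction of
#' validation non-target scores strictly below theta is at least the
#' target specificity, under the decision rule "predict target iff
#' score >= theta". The smallest feasible theta maximizes sensitivity
#' subject to the specificity bound. If no observed score satisfies the
#' bound (e.g. target specificity 1), the threshold is placed just above
#' the largest observed score.
#'
#' @param nontargetScores scores of validation non-target (non-controlling)
#'   epochs; integer votes or real LDA scores.
#' @param targetSpecificity required specificity on validation non-targets
#'   (default 0.90).
#' @return the calibrated threshold.
#' @examples
#' calibrateThreshold(1:10, 0.9)   # 10: nine of ten scores lie below
#' @export
calibrateThreshold <- function(nontargetScores, targetSpecificity = 0.90) {
  if (length(nontargetScores) == 0)
    stop("no validation scores supplied")
  if (length(nontargetScores) < 5)
    warning("fewer than 5 validation scores: calibration is unreliable")
  cand <- sort(unique(nontargetScores))
  frac <- vapply(cand, function(th) mean(nontargetScores < th), numeric(1))
  ok <- which(frac >= targetSpecificity)
  if (length(ok)) return(cand[ok[1]])
  mx <- max(nontargetScores)
  if (all(nontargetScores == round(nontargetScores))) mx + 1
  else mx + max(1e-9, abs(mx) * 1e-9)
}

#' Predict target/non-target labels with a calibrated classifier
#'
#' @param model a [Committee-class] or [ShrinkageLDA-class] whose
#'   [decisionThreshold()] has been set.
#' @param X feature matrix.
#' @return integer vector of 0/1 predictions.
#' @export
predictLabels <- function(model, X) {
  th <- decisionThreshold(model)
  if (is.na(th))
    stop("decision threshold not calibrated; see calibrateThreshold()")
  as.integer(classifierScore(model, X) >= th)
}
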