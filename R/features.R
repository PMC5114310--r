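## Windowed-amplitude features: 13 overlapping 50-ms windows stepping
## 20 ms across 200-490 ms, in each of the 13 posterior channels, giving a
## 169-dimensional mean-amplitude vector per epoch. All windows end before
## the 500 ms online-classification bound.

#' Feature window table
#'
#' The 13 overlapping windows of 50 ms length and 20 ms step used for
#' feature extraction: 200-250, 220-270, ..., 440-490 ms relative to
#' fixation onset. Windows are half-open `[start, end)` on the 2-ms sample
#' grid, 25 samples each.
#'
#' @return data.frame with `window`, `start_ms`, `end_ms`.
#' @export
windowTable <- function() {
  start <- 200 + 20 * (0:12)
  data.frame(window = 1:13, start_ms = start, end_ms = start + 50)
}

#' Feature slot of a channel/window pair
#'
#' The fixed layout of the 169-dimensional feature vector: feature
#' `(c-1)*13 + (i-1)` (0-based) holds window `i` of posterior channel `c`,
#' channels in the order given by [posteriorChannels()]. The corresponding
#' matrix column is the slot plus one.
#'
#' @param channelLabel one of the 13 posterior channel labels.
#' @param windowI window number, 1-13.
#' @return integer 0-based feature slot in 0..168.
#' @examples
#' featureIndex("P1", 1)   # 0
#' featureIndex("Oz", 13)  # 168
#' @export
featureIndex <- function(channelLabel, windowI) {
  c <- match(channelLabel, posteriorChannels())
  if (is.na(c)) stop("unknown posterior channel: ", channelLabel)
  stopifnot(windowI >= 1, windowI <= 13)
  (c - 1L) * 13L + (as.integer(windowI) - 1L)
}

#' Extract windowed-amplitude feature vectors
#'
#' Computes, per epoch, the mean amplitude of each posterior channel over
#' each of the 13 feature windows, packed per [featureIndex()]. Requires
#' baseline-corrected epochs containing all 13 posterior channels.
#'
#' @param epochs a baseline-corrected [FixationEpochs-class].
#' @return numeric matrix, epochs x 169, columns `f000`...`f168`.
#' @export
extractFeatures <- function(epochs) {
  if (!baselineApplied(epochs))
    stop("epochs must be baseline-corrected before feature extraction")
  post <- posteriorChannels()
  missing <- setdiff(post, epochs@channels)
  if (length(missing))
    stop("posterior channel(s) missing: ", paste(missing, collapse = ", "))
  arr <- epochArray(epochs)[post, , , drop = FALSE]
  wt <- windowTable()
  nEp <- dim(arr)[3]
  X <- matrix(0, nrow = nEp, ncol = 169)
  for (i in seq_len(13)) {
    idx <- epochSampleIndex(wt$start_ms[i], wt$end_ms[i])
    wm <- apply(arr[, idx, , drop = FALSE], c(1, 3), mean)  # 13 x nEp
    for (c in seq_len(13)) {
      X[, (c - 1L) * 13L + i] <- wm[c, ]
    }
  }
  colnames(X) <- sprintf("f%03d", 0:168)
  X
}
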