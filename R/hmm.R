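# HMM click decoder: PCA front end, two-state Gaussian emissions,
# forward recursion, unsupervised threshold calibration, and the
# two-consecutive-bin click rule.

#' Fit the PCA front end of the click decoder
#'
#' Centers the calibration features and retains exactly the top four
#' eigenvalue-ranked principal components, with a deterministic sign
#' convention (the largest-magnitude loading of each component is made
#' positive).
#'
#' @param x bins x features matrix, or a \linkS4class{BinnedFeatures}
#' @param family when x is a BinnedFeatures, restrict rows to this
#'   feature family ("spike", "hfp", or "both")
#' @return list with \code{center}, \code{rotation} (features x 4) and
#'   \code{featureIndex}
#' @export
fitClickPca <- function(x, family = "both") {
  featureIndex <- integer(0)
  if (is(x, "BinnedFeatures")) {
    rows <- seq_len(nrow(x))
    if (family != "both") rows <- rows[featureFamily(x) == family]
    featureIndex <- rows
    x <- t(featureMatrix(x)[rows, , drop = FALSE])
  } else {
    featureIndex <- seq_len(ncol(x))
  }
  if (nrow(x) < 50L) stop("at least 50 calibration bins are required")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 4L || pc$sdev[4L] < 1e-10)
    stop("calibration features have rank < 4; cannot retain 4 PCs")
  rot <- pc$rotation[, 1:4, drop = FALSE]
  for (j in 1:4) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  list(center = pc$center, rotation = rot,
       featureIndex = as.integer(featureIndex))
}

#' Project features into the click decoder's PC space
#'
#' @param pca projection list from \code{\link{fitClickPca}}
#' @param x features x bins matrix or a \linkS4class{BinnedFeatures}
#' @return bins x 4 projected matrix
#' @export
projectFeatures <- function(pca, x) {
  if (is(x, "BinnedFeatures"))
    x <- featureMatrix(x)[pca$featureIndex, , drop = FALSE]
  t(crossprod(pca$rotation, x - pca$center))        # bins x 4
}

#' Fit the two-state HMM click classifier
#'
#' Per-state multivariate Gaussian emission parameters from labelled
#' calibration bins, and a transition matrix from label bigram
#' frequencies with a pseudocount.
#'
#' @param proj bins x 4 projected calibration features (see
#'   \code{\link{fitClickPca}})
#' @param clickLabels logical per bin: TRUE while the user intends a
#'   click
#' @param pca the projection list from \code{\link{fitClickPca}}
#' @param pseudocount added to every bigram cell
#' @param covRidge diagonal ridge on the emission covariances
#' @return a \linkS4class{ClickHMM} (click threshold not yet set)
#' @export
fitHmm <- function(proj, clickLabels, pca, pseudocount = 1,
                   covRidge = 1e-8) {
  stopifnot(ncol(proj) == 4L, nrow(proj) == length(clickLabels))
  nMove <- sum(!clickLabels); nClick <- sum(clickLabels)
  if (nMove < 10L || nClick < 10L)
    stop("each state needs at least 10 calibration bins (move: ",
         nMove, ", click: ", nClick, ")")
  mMove <- colMeans(proj[!clickLabels, , drop = FALSE])
  mClick <- colMeans(proj[clickLabels, , drop = FALSE])
  cMove <- stats::cov(proj[!clickLabels, , drop = FALSE]) + diag(covRidge, 4)
  cClick <- stats::cov(proj[clickLabels, , drop = FALSE]) + diag(covRidge, 4)
  s <- as.integer(clickLabels) + 1L     # 1 = move, 2 = click
  trans <- matrix(pseudocount, 2L, 2L)
  for (t in seq_len(length(s) - 1L))
    trans[s[t], s[t + 1L]] <- trans[s[t], s[t + 1L]] + 1
  trans <- trans / rowSums(trans)
  new("ClickHMM", center = pca$center, rotation = pca$rotation,
      featureIndex = pca$featureIndex,
      stateMeans = rbind(move = mMove, click = mClick),
      stateCovs = list(move = cMove, click = cClick),
      transition = trans, clickThreshold = NA_real_,
      consecutiveBinsRequired = 2L)
}

#' One step of the HMM forward recursion
#'
#' p(s_k, t) = p(s_k | z_t) * sum_i p(s_k | s_i) p(s_i, t-1), then
#' renormalized over the two states. Log-domain emission likelihoods
#' keep the recursion stable for very small densities.
#'
#' @param hmm a \linkS4class{ClickHMM}
#' @param z projected 4-vector for the current bin
#' @param prev previous normalized state probabilities c(pMove, pClick)
#' @return updated c(pMove, pClick) summing to 1
#' @export
hmmStep <- function(hmm, z, prev = c(0.5, 0.5)) {
  ll <- c(dmvnormLog(z, hmm@stateMeans[1L, ], hmm@stateCovs[[1L]]),
          dmvnormLog(z, hmm@stateMeans[2L, ], hmm@stateCovs[[2L]]))
  if (any(!is.finite(ll))) stop("non-finite emission likelihood")
  lik <- exp(ll - max(ll))
  propagated <- as.numeric(crossprod(hmm@transition, prev))
  post <- lik * propagated
  post / sum(post)
}

#' Run the streaming forward recursion over a projected stream
#'
#' @param hmm a \linkS4class{ClickHMM}
#' @param proj bins x 4 projected features
#' @param init initial state probabilities
#' @return bins x 2 matrix of normalized c(pMove, pClick)
#' @export
hmmFilter <- function(hmm, proj, init = c(0.5, 0.5)) {
  out <- matrix(0, nrow(proj), 2L,
                dimnames = list(NULL, c("pMove", "pClick")))
  prev <- init
  for (t in seq_len(nrow(proj))) {
    prev <- hmmStep(hmm, proj[t, ], prev)
    out[t, ] <- prev
  }
  out
}

#' Unsupervised click-threshold calibration
#'
#' The click threshold is the 93rd quantile (linear interpolation
#' between order statistics) of the per-bin click-state posterior over
#' the calibration block, so 7% of calibration bins lie above it by
#' construction.
#'
#' @param pClick per-bin click-state probabilities of the calibration
#'   block
#' @param probs quantile (default 0.93)
#' @return threshold in (0, 1)
#' @export
calibrateClickThreshold <- function(pClick, probs = 0.93) {
  if (length(pClick) < 100L)
    stop("threshold calibration requires at least 100 bins")
  if (stats::sd(pClick) < .Machine$double.eps)
    stop("degenerate (constant) click-probability stream")
  stats::quantile(pClick, probs, names = FALSE, type = 7)
}

#' Click detection with the consecutive-bin rule
#'
#' A click is generated at the second of two consecutive bins whose
#' click-state probability exceeds the threshold; the consecutive
#' counter resets after each click, so a fresh pair of above-threshold
#' bins is required before the next click.
#'
#' @param pClick per-bin click-state probabilities, in time order
#' @param threshold click threshold (default: stored in \code{hmm})
#' @param consecutive bins required (2)
#' @param hmm optional \linkS4class{ClickHMM} supplying the threshold
#' @return integer vector of click bin indices
#' @export
detectClicks <- function(pClick, threshold = NULL, consecutive = 2L,
                         hmm = NULL) {
  if (is.null(threshold)) {
    if (is.null(hmm) || is.na(hmm@clickThreshold))
      stop("no click threshold available")
    threshold <- hmm@clickThreshold
    consecutive <- hmm@consecutiveBinsRequired
  }
  counter <- 0L
  clicks <- integer(0)
  for (t in seq_along(pClick)) {
    if (pClick[t] > threshold) {
      counter <- counter + 1L
      if (counter >= consecutive) {
        clicks <- c(clicks, t)
        counter <- 0L            # re-arm: a fresh pair is required
      }
    } else counter <- 0L
  }
  clicks
}

#' Set the click threshold of a fitted HMM
#'
#' @param hmm a \linkS4class{ClickHMM}
#' @param calibration a \linkS4class{BinnedFeatures} (or bins x 4
#'   projected matrix) from the retraining block
#' @return the HMM with \code{clickThreshold} set
#' @export
setClickThreshold <- function(hmm, calibration) {
  proj <- if (is(calibration, "BinnedFeatures"))
    projectFeaturesHmm(hmm, calibration) else calibration
  p <- hmmFilter(hmm, proj)[, "pClick"]
  hmm@clickThreshold <- calibrateClickThreshold(p)
  validObject(hmm)
  hmm
}

# Projection using the slots of a fitted ClickHMM.
projectFeaturesHmm <- function(hmm, x) {
  if (is(x, "BinnedFeatures"))
    x <- featureMatrix(x)[hmm@featureIndex, , drop = FALSE]
  t(crossprod(hmm@rotation, x - hmm@center))
}
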