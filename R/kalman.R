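# Velocity Kalman decoder: tuning-based feature selection, observation
# model fitting, steady-state decoding at 15 ms, intention relabelling
# for recalibration, and 1-ms position integration.

# Per-feature tuning p-value: F-test of the regression of the feature
# on (vx, vy).
tuningPValues <- function(Z, vx, vy) {
  X <- cbind(1, vx, vy)
  XtXinv <- solve(crossprod(X))
  H <- XtXinv %*% t(X)
  n <- length(vx)
  apply(Z, 1L, function(z) {
    beta <- H %*% z
    fit <- X %*% beta
    rss <- sum((z - fit)^2)
    tss <- sum((z - mean(z))^2)
    if (tss < .Machine$double.eps) return(1)
    f <- ((tss - rss) / 2) / (rss / (n - 3))
    stats::pf(f, 2, n - 3, lower.tail = FALSE)
  })
}

# Cross-validated velocity-decoding R^2 using OLS on a feature subset.
cvDecodeR2 <- function(Z, vx, vy, nFolds = 5L) {
  n <- length(vx)
  fold <- rep(seq_len(nFolds), length.out = n)
  Y <- cbind(vx, vy)
  sse <- 0; sst <- 0
  for (f in seq_len(nFolds)) {
    tr <- fold != f; te <- !tr
    X <- cbind(1, t(Z[, tr, drop = FALSE]))
    Xte <- cbind(1, t(Z[, te, drop = FALSE]))
    B <- tryCatch(solve(crossprod(X) + diag(1e-8, ncol(X)), crossprod(X, Y[tr, ])),
                  error = function(e) NULL)
    if (is.null(B)) return(-Inf)
    pred <- Xte %*% B
    sse <- sse + sum((Y[te, ] - pred)^2)
    sst <- sst + sum(sweep(Y[te, ], 2L, colMeans(Y[tr, ]))^2)
  }
  1 - sse / sst
}

#' Select decoder features by tuning significance
#'
#' Features are ranked by tuning significance (p-value of the linear
#' regression between binned neural data and cursor velocity), then
#' added in order while tracking cross-validated offline decoding
#' accuracy; the returned set is the smallest one achieving the maximal
#' cross-validated accuracy (ties broken toward fewer features).
#'
#' @param calibration a \linkS4class{BinnedFeatures} with intent labels
#' @param family restrict to "spike", "hfp", or "both" (default)
#' @param alpha significance level a feature must reach to be eligible
#' @param maxFeatures cap on candidate set size
#' @param nFolds cross-validation folds
#' @param tol sets within tol of the best CV accuracy count as ties
#' @return integer vector of selected feature rows (of the stream)
#' @export
selectFeatures <- function(calibration, family = "both", alpha = 0.05,
                           maxFeatures = 60L, nFolds = 5L, tol = 1e-3) {
  il <- intentLabels(calibration)
  if (is.null(il)) stop("calibration stream must carry intent labels")
  if (ncol(calibration) < 100L)
    stop("at least 100 calibration bins are required")
  rows <- seq_len(nrow(calibration))
  if (family != "both")
    rows <- rows[featureFamily(calibration) == family]
  Z <- featureMatrix(calibration)[rows, , drop = FALSE]
  vr <- apply(Z, 1L, stats::var)
  if (any(vr < .Machine$double.eps)) {
    warning("excluding ", sum(vr < .Machine$double.eps),
            " zero-variance feature(s)")
    rows <- rows[vr >= .Machine$double.eps]
    Z <- Z[vr >= .Machine$double.eps, , drop = FALSE]
  }
  p <- tuningPValues(Z, il$vx, il$vy)
  # Bonferroni-corrected eligibility: non-tuned channels must not slip
  # in by multiplicity alone
  eligible <- which(p < alpha / length(p))
  if (length(eligible) == 0L)
    stop("no feature is significantly tuned at alpha = ", alpha,
         " (Bonferroni-corrected); increase the synthetic SNR ",
         "(modulation depth) or the number of calibration bins")
  ord <- eligible[order(p[eligible])]
  ord <- ord[seq_len(min(length(ord), maxFeatures))]
  acc <- vapply(seq_along(ord), function(k)
    cvDecodeR2(Z[ord[seq_len(k)], , drop = FALSE], il$vx, il$vy, nFolds),
    numeric(1))
  best <- max(acc)
  k <- which(acc >= best - tol)[1L]   # smallest set within tol of the best
  sort(rows[ord[seq_len(k)]])
}

#' Fit the velocity Kalman decoder
#'
#' Observation model by least squares of each selected feature on
#' (vx, vy, 1); observation noise from the residual covariance; fixed
#' kinematic model (AR(1) velocity decay per 15-ms bin, process noise
#' from the intent-velocity innovations); steady-state Kalman gain by
#' Riccati iteration.
#'
#' @param calibration a \linkS4class{BinnedFeatures} with intent labels
#' @param features integer feature rows (from \code{selectFeatures})
#' @param decay per-bin velocity decay of the kinematic model
#' @param baseline per-feature offsets subtracted before fitting;
#'   defaults to the calibration means of the selected features
#' @return a \linkS4class{KalmanDecoder}
#' @export
fitKalman <- function(calibration, features, decay = 0.96,
                      baseline = NULL) {
  il <- intentLabels(calibration)
  if (is.null(il)) stop("calibration stream must carry intent labels")
  features <- as.integer(features)
  Zall <- featureMatrix(calibration)[features, , drop = FALSE]
  baseline <- baseline %||% rowMeans(Zall)
  Z <- Zall - baseline
  X <- cbind(il$vx, il$vy, 1)
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12) {
    stop("rank-deficient regression while fitting features: ",
         paste(features, collapse = ", "))
  }
  Ht <- solve(XtX, crossprod(X, t(Z)))     # 3 x nf
  H <- t(Ht)
  resid <- t(Z) - X %*% Ht
  Q <- crossprod(resid) / (nrow(X) - 3L)
  Q <- (Q + t(Q)) / 2 + diag(1e-6, nrow(H))
  innov <- cbind(il$vx[-1] - decay * il$vx[-length(il$vx)],
                 il$vy[-1] - decay * il$vy[-length(il$vy)])
  w <- max(mean(apply(innov, 2L, stats::var)), 1e-6)
  A <- diag(c(decay, decay, 1))
  W <- diag(c(w, w, 0))
  # steady-state gain
  P <- W
  K <- matrix(0, 3L, nrow(H))
  for (i in seq_len(500L)) {
    Pp <- A %*% P %*% t(A) + W
    S <- H %*% Pp %*% t(H) + Q
    Knew <- Pp %*% t(H) %*% solve(S)
    P <- (diag(3) - Knew %*% H) %*% Pp
    if (max(abs(Knew - K)) < 1e-12) { K <- Knew; break }
    K <- Knew
  }
  new("KalmanDecoder", A = A, W = W, H = H, Q = Q, K = K,
      selectedFeatures = features, baseline = as.numeric(baseline),
      binWidth = calibration@metadata$binWidth, decay = decay)
}

#' One decoding step (one 15-ms bin)
#'
#' Standard predict/update recursion at the converged gain over the
#' state (vx, vy, 1).
#'
#' @param decoder a \linkS4class{KalmanDecoder}
#' @param z baseline-subtracted feature vector (selected features only)
#' @param state previous state 3-vector, c(vx, vy, 1)
#' @return updated state 3-vector
#' @export
decodeStep <- function(decoder, z, state = c(0, 0, 1)) {
  if (!all(is.finite(z))) stop("non-finite feature value")
  xp <- decoder@A %*% state
  x <- xp + decoder@K %*% (z - decoder@H %*% xp)
  x[3L] <- 1
  as.numeric(x)
}

#' Decode a whole feature stream
#'
#' @param decoder a \linkS4class{KalmanDecoder}
#' @param stream a \linkS4class{BinnedFeatures}
#' @param baseline per-selected-feature offsets (default: the decoder's
#'   stored calibration baseline; pass a fresh per-block estimate to
#'   apply baseline re-estimation)
#' @return 2 x bins matrix of decoded velocities
#' @export
decodeStream <- function(decoder, stream, baseline = NULL) {
  Z <- featureMatrix(stream)[decoder@selectedFeatures, , drop = FALSE]
  baseline <- baseline %||% decoder@baseline
  Z <- Z - baseline
  state <- c(0, 0, 1)
  out <- matrix(0, 2L, ncol(Z))
  for (t in seq_len(ncol(Z))) {
    state <- decodeStep(decoder, Z[, t], state)
    out[, t] <- state[1:2]
  }
  out
}

#' Intention-based relabelling for decoder recalibration
#'
#' Re-labels closed-loop decoded velocities with the user's presumed
#' intention: the decoded speed is kept, the direction is rotated to
#' point from the cursor to the target; intent is zero on bins where
#' the cursor is over the target (hold/selection epochs).
#'
#' @param cursor 2 x T cursor positions
#' @param decoded 2 x T decoded velocities
#' @param target 2 x T target positions
#' @param overTarget logical length T: cursor over the target
#' @return 2 x T relabelled intent velocities
#' @export
refitRelabel <- function(cursor, decoded, target, overTarget) {
  TT <- ncol(cursor)
  out <- matrix(0, 2L, TT)
  for (t in seq_len(TT)) {
    if (overTarget[t]) next
    d <- target[, t] - cursor[, t]
    nd <- sqrt(sum(d^2))
    if (nd < 1e-12) next          # at the target: hold rule wins
    out[, t] <- sqrt(sum(decoded[, t]^2)) * d / nd
  }
  out
}

#' Integrate cursor position by one 1-ms Euler step
#'
#' @param position 2-vector, workspace units
#' @param velocity 2-vector, units/s
#' @param dt step, s (1 ms)
#' @param bounds workspace bounds c(xmin, ymin, xmax, ymax)
#' @return clamped updated position
#' @export
integratePosition <- function(position, velocity, dt = 0.001,
                              bounds = c(0, 0, 1, 1)) {
  clampPoint(position + velocity * dt, bounds)
}

#' Integrate one 15-ms bin (15 x 1-ms steps) of cursor motion
#'
#' @inheritParams integratePosition
#' @param nSteps integrations per bin (15)
#' @export
integrateBin <- function(position, velocity, bounds = c(0, 0, 1, 1),
                         nSteps = 15L, dt = 0.001) {
  for (i in seq_len(nSteps))
    position <- integratePosition(position, velocity, dt, bounds)
  position
}
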