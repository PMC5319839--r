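# Simulated user: a saturating proportional feedback controller that
# stands in for the human's visually guided corrections.

#' Build a simulated-user policy
#'
#' @param reactionDelay time before a newly cued target affects intent, s
#' @param gain intent speed per unit cursor-to-target distance, 1/s
#' @param maxSpeed intent speed cap, units/s
#' @param clickLatency hover time over the cued target before click
#'   intent turns on, s
#' @param motorNoiseSd angular jitter s.d. on the intent direction, rad
#' @param clickEnabled whether this profile attempts clicks at all
#' @return a \linkS4class{SimulatedUserPolicy}
#' @export
userPolicy <- function(reactionDelay = 0.2, gain = 4, maxSpeed = 1.2,
                       clickLatency = 0.3, motorNoiseSd = 0.15,
                       clickEnabled = TRUE) {
  new("SimulatedUserPolicy", reactionDelay = reactionDelay, gain = gain,
      maxSpeed = maxSpeed, clickLatency = clickLatency,
      motorNoiseSd = motorNoiseSd, clickEnabled = clickEnabled)
}

#' Fresh user-policy state
#' @export
newUserState <- function() {
  list(activeTarget = NULL, pendingTarget = NULL, pendingSince = -Inf,
       hoverTime = 0)
}

#' One step of the simulated user's feedback policy
#'
#' Intended velocity points from the cursor toward the cued target's
#' center with speed gain * distance, saturating at maxSpeed, after the
#' reaction delay, with angular motor noise; intent is zero once the
#' cursor sits over the cued target (beyond a small dead zone), and
#' click intent turns on after the hover has lasted clickLatency.
#'
#' @param policy a \linkS4class{SimulatedUserPolicy}
#' @param state policy state from \code{\link{newUserState}}
#' @param cursor cursor position 2-vector
#' @param cuedCenter cued target center 2-vector
#' @param overCued TRUE when the cursor is over the cued target
#' @param dt step, s (the 15-ms decoder cadence)
#' @param time current block time, s
#' @return list(state, v = intent velocity, click = click intent)
#' @export
simulatedUserStep <- function(policy, state, cursor, cuedCenter,
                              overCued, dt = 0.015, time = 0) {
  # reaction delay: adopt a newly cued target only after the delay
  if (is.null(state$activeTarget)) {
    state$activeTarget <- cuedCenter
  } else if (any(state$activeTarget != cuedCenter)) {
    if (is.null(state$pendingTarget) ||
        any(state$pendingTarget != cuedCenter)) {
      state$pendingTarget <- cuedCenter
      state$pendingSince <- time
    }
    if (time - state$pendingSince >= policy@reactionDelay) {
      state$activeTarget <- cuedCenter
      state$pendingTarget <- NULL
      state$hoverTime <- 0
    }
  }
  d <- state$activeTarget - cursor
  dist <- sqrt(sum(d^2))
  over <- overCued && all(state$activeTarget == cuedCenter)
  state$hoverTime <- if (over) state$hoverTime + dt else 0
  speed <- min(policy@gain * dist, policy@maxSpeed)
  v <- c(0, 0)
  if (dist > 1e-9 && speed > 0) {
    theta <- atan2(d[2], d[1]) +
      (if (policy@motorNoiseSd > 0) rnorm(1L, 0, policy@motorNoiseSd) else 0)
    v <- speed * c(cos(theta), sin(theta))
  }
  click <- policy@clickEnabled && state$hoverTime >= policy@clickLatency
  list(state = state, v = v, click = click)
}
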