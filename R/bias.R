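# Online velocity-bias correction for nonstationary baselines.

#' Create a bias-corrector state
#'
#' @param tau adaptation time constant, s (30 s by default; larger tau
#'   responds more slowly but fluctuates less when no bias is present)
#' @param dt adaptation step, s (0.001 s)
#' @param speedThreshold speed gate, units/s: the estimate is only
#'   updated while decoded speed exceeds this (set it near the 10-20%
#'   quantile of typical speeds, see \code{\link{estimateSpeedGate}})
#' @param B initial bias estimate
#' @return a \linkS4class{BiasState}
#' @export
biasState <- function(tau = 30, dt = 0.001, speedThreshold = 0,
                      B = c(0, 0)) {
  if (tau <= 0) stop("configuration error: tau must be > 0")
  new("BiasState", B = as.numeric(B), tau = tau, dt = dt,
      speedThreshold = speedThreshold)
}

#' Speed gate from observed speeds
#'
#' @param speeds observed decoded speeds from a preceding calibration
#'   block, units/s
#' @param probs quantile (default 0.15, inside the 10-20% range)
#' @return speed threshold, units/s
#' @export
estimateSpeedGate <- function(speeds, probs = 0.15) {
  stats::quantile(speeds, probs, names = FALSE, type = 7)
}

#' One 1-ms bias update
#'
#' Per axis, B <- B + (V - B) * |V - B| * dt / tau; the magnitude term
#' compensates for low speeds being observed for longer stretches than
#' high speeds. No update happens when decoded speed is at or below the
#' gate. V = B is a fixed point.
#'
#' @param bias a \linkS4class{BiasState}
#' @param V decoded velocity 2-vector, units/s
#' @return updated \linkS4class{BiasState}
#' @export
updateBias <- function(bias, V) {
  if (sqrt(sum(V^2)) <= bias@speedThreshold) return(bias)
  d <- V - bias@B
  bias@B <- bias@B + d * abs(d) * bias@dt / bias@tau
  bias
}

# Run nSteps 1-ms updates holding the most recent 15-ms velocity.
updateBiasBin <- function(bias, V, nSteps = 15L) {
  if (sqrt(sum(V^2)) <= bias@speedThreshold) return(bias)
  B <- bias@B; r <- bias@dt / bias@tau
  for (i in seq_len(nSteps)) {
    d <- V - B
    B <- B + d * abs(d) * r
  }
  bias@B <- B
  bias
}

#' Bias-corrected velocity
#'
#' @param bias a \linkS4class{BiasState}
#' @param V decoded velocity 2-vector
#' @return V minus the current bias estimate
#' @export
correctVelocity <- function(bias, V) V - bias@B
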