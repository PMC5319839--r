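# Performance metrics: achieved bitrate, correct characters per
# minute, and click-accuracy summaries over selection-event logs.

#' Achieved bitrate
#'
#' B = log2(N - 1) * max(S - 2E, 0) / t, in bits/s: each incorrect
#' selection charges one additional correct selection, and the floor is
#' 0. Timed-out trials must already be excluded from S and E upstream
#' (their time still counts in t).
#'
#' @param N number of targets on the screen (>= 2)
#' @param S number of selections
#' @param E number of incorrect selections
#' @param t elapsed time, s (> 0)
#' @return bits/s
#' @export
achievedBitrate <- function(N, S, E, t) {
  if (N < 2) stop("achieved bitrate requires N >= 2")
  if (t <= 0) stop("elapsed time must be > 0")
  log2(N - 1) * max(S - 2 * E, 0) / t
}

#' Correct characters per minute
#'
#' C = max(S - 2D, 0) / t, with t in minutes: correct characters are
#' those not subsequently deleted, so each delete charges the deleted
#' character and the delete itself. Uncorrected typos count as correct.
#'
#' @param S number of selections
#' @param D number of delete-key selections
#' @param tSeconds elapsed time, s
#' @return correct characters per minute
#' @export
correctCharsPerMin <- function(S, D, tSeconds) {
  if (tSeconds <= 0) stop("elapsed time must be > 0")
  max(S - 2 * D, 0) / (tSeconds / 60)
}

#' Words per minute from ccpm
#'
#' Standard 5-characters-per-word convention: wpm = ccpm / 5.
#'
#' @param ccpm correct characters per minute (>= 0)
#' @return words per minute
#' @export
wordsPerMin <- function(ccpm) {
  stopifnot(all(ccpm >= 0))
  ccpm / 5
}

#' Improvement factor between two performance means
#'
#' @param current,previous performance values in the same units
#' @return current / previous
#' @export
improvementFactor <- function(current, previous) current / previous

#' Score a selection-event log into a block result
#'
#' Tallies S (selections), E (incorrect selections), D (delete-key
#' selections) from a block's event log -- timeouts never increment S,
#' E or D but their time is part of the elapsed time -- and computes
#' the block's achieved bitrate and ccpm.
#'
#' @param events event log from \code{\link{runGridBlock}} or
#'   \code{\link{runCopyTypingBlock}}
#' @param layout the block's \linkS4class{TaskLayout}
#' @param elapsed elapsed time, s
#' @param task "grid" or "typing"
#' @return one-row data.frame with N, S, E, D, t, bitrate, ccpm
#' @export
scoreBlock <- function(events, layout, elapsed, task = "grid") {
  sel <- events[!events$timeout, , drop = FALSE]
  S <- nrow(sel)
  E <- sum(!sel$correct)
  labs <- layout@targets$label[match(sel$selectedId, layout@targets$id)]
  D <- sum(labs == "<", na.rm = TRUE)
  data.frame(task = task, N = nrow(layout@targets), S = S, E = E, D = D,
             t = elapsed,
             bitrate = if (elapsed > 0)
               achievedBitrate(nrow(layout@targets), S, E, elapsed) else NA_real_,
             ccpm = if (elapsed > 0)
               correctCharsPerMin(S, D, elapsed) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Click-accuracy summary over logged click selections
#'
#' Replicates the spatial click-accuracy analysis: percent of clicks
#' landing on the cued target, plus the distribution of click-to-cued-
#' center distances and a flag for whether misses concentrate near the
#' cued target's edge.
#'
#' @param events event log rows with clickX/clickY, cuedId, selectedId
#'   and method
#' @param layout the \linkS4class{TaskLayout}
#' @param methodFilter count only events with this method (default
#'   "click"; NULL = all selections)
#' @return list with nClicks, nCorrect, percentCorrect (100 * correct /
#'   total, NA when no clicks), distances, histogram (graphics-free
#'   bin counts) and missesNearEdge
#' @export
clickAccuracySummary <- function(events, layout, methodFilter = "click") {
  ev <- events[!events$timeout, , drop = FALSE]
  if (!is.null(methodFilter))
    ev <- ev[!is.na(ev$method) & ev$method == methodFilter, , drop = FALSE]
  n <- nrow(ev)
  if (n == 0L)
    return(list(nClicks = 0L, nCorrect = 0L, percentCorrect = NA_real_,
                distances = numeric(0), histogram = NULL,
                missesNearEdge = NA))
  correct <- ev$selectedId == ev$cuedId
  dists <- vapply(seq_len(n), function(i) {
    ctr <- targetCenter(layout, ev$cuedId[i])
    sqrt(sum((c(ev$clickX[i], ev$clickY[i]) - ctr)^2))
  }, numeric(1))
  tg <- layout@targets
  halfW <- (tg$x1[1L] - tg$x0[1L]) / 2
  h <- graphics::hist(dists, breaks = "Sturges", plot = FALSE)
  missD <- dists[!correct]
  missesNearEdge <- if (length(missD))
    stats::median(missD) < 2 * halfW else NA
  list(nClicks = n, nCorrect = sum(correct),
       percentCorrect = 100 * sum(correct) / n,
       distances = dists, histogram = h,
       missesNearEdge = missesNearEdge)
}
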