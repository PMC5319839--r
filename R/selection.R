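# Target selection: dwell automata, click selection, recentering, and
# the per-tick block engine shared by the grid and copy-typing tasks.

#' Build a selection rule
#'
#' @param mode "dwell_reset", "dwell_cumulative" or "click_or_dwell"
#' @param dwellRequired required hold, s
#' @param recenter recenter the cursor (and lock out selection for
#'   \code{recenterLockout} s) after every selection, correct or not
#' @param recenterLockout lockout duration, s
#' @return a \linkS4class{SelectionRule}
#' @export
selectionRule <- function(mode = c("dwell_reset", "dwell_cumulative",
                                   "click_or_dwell"),
                          dwellRequired = 1.0, recenter = FALSE,
                          recenterLockout = 0.5) {
  mode <- match.arg(mode)
  new("SelectionRule", mode = mode, dwellRequired = dwellRequired,
      recenter = recenter, recenterLockout = recenterLockout)
}

# Ticks a hold must span: the accumulated hold must exceed the dwell
# requirement, counted at tick resolution (so a 1.5-s requirement at
# 15-ms ticks needs 101 ticks, a 1.0-s requirement 67).
requiredDwellTicks <- function(rule, tick = 0.015) {
  as.integer(floor(rule@dwellRequired / tick + 1e-9)) + 1L
}

# Lockout counted in whole bins: floor(0.5 / 0.015) = 33 bins are
# locked; the 34th bin may select.
lockoutBins <- function(rule, tick = 0.015) {
  as.integer(floor(rule@recenterLockout / tick + 1e-9))
}

#' Fresh dwell-tracker state
#' @export
newDwellState <- function() {
  list(current = NA_integer_, count = 0L, counters = integer(0))
}

#' One 15-ms dwell-automaton update
#'
#' Reset mode: the hold counter is zeroed whenever the hovered target
#' changes (leaving a target resets it). Cumulative mode: each target
#' keeps its own counter which persists across exits; all counters are
#' zeroed after any selection (the engine does this via
#' \code{\link{newDwellState}}). A selection fires on the tick where
#' the accumulated hold exceeds the requirement.
#'
#' @param state dwell state from \code{\link{newDwellState}}
#' @param hovered target id under the cursor, or NA
#' @param rule a \linkS4class{SelectionRule}
#' @param tick tick duration, s (15 ms, the decoder cadence)
#' @return list(state = updated state, selected = id or NA)
#' @export
dwellUpdate <- function(state, hovered, rule, tick = 0.015) {
  need <- requiredDwellTicks(rule, tick)
  selected <- NA_integer_
  if (rule@mode %in% c("dwell_reset", "click_or_dwell")) {
    if (is.na(hovered) || is.na(state$current) ||
        hovered != state$current) {
      state$current <- hovered
      state$count <- 0L
    }
    if (!is.na(hovered)) {
      state$count <- state$count + 1L
      if (state$count >= need) selected <- hovered
    }
  } else {                                  # dwell_cumulative
    if (!is.na(hovered)) {
      key <- as.character(hovered)
      state$counters[key] <- (if (key %in% names(state$counters))
        state$counters[[key]] else 0L) + 1L
      if (state$counters[[key]] >= need) selected <- hovered
    }
  }
  list(state = state, selected = selected)
}

# Internal per-tick engine. `controller(ctx)` returns list(position,
# click); ctx carries cursor, cued id and center, lock state and time.
# `nextCue(lastEvent)` returns the next cued id or NA to end the block.
runBlockEngine <- function(layout, rule, controller, nextCue,
                           duration, trialTimeout = Inf, tick = 0.015,
                           startCursor = NULL) {
  bounds <- layout@bounds
  center <- c((bounds[1] + bounds[3]) / 2, (bounds[2] + bounds[4]) / 2)
  cursor <- startCursor %||% center
  dwell <- newDwellState()
  lock <- 0L
  cued <- nextCue(NULL)
  events <- list()
  trialStart <- 0
  nTicks <- as.integer(round(duration / tick))
  endTime <- duration
  for (t in seq_len(nTicks)) {
    tNow <- t * tick
    if (is.na(cued)) { endTime <- (t - 1L) * tick; break }
    locked <- lock > 0L
    ctrl <- controller(list(cursor = cursor, cued = cued,
                            cuedCenter = targetCenter(layout, cued),
                            locked = locked, time = tNow))
    cursor <- clampPoint(ctrl$position, bounds)
    if (locked) { lock <- lock - 1L; next }
    hovered <- hitTest(layout, cursor)
    selected <- NA_integer_
    method <- NA_character_
    if (isTRUE(ctrl$click) && rule@mode == "click_or_dwell" &&
        !is.na(hovered)) {
      selected <- hovered
      method <- "click"
    }
    if (is.na(selected)) {
      du <- dwellUpdate(dwell, hovered, rule, tick)
      dwell <- du$state
      if (!is.na(du$selected)) { selected <- du$selected; method <- "dwell" }
    }
    if (!is.na(selected)) {
      events[[length(events) + 1L]] <- data.frame(
        time = tNow, cuedId = cued, selectedId = selected,
        method = method, correct = selected == cued,
        clickX = cursor[1], clickY = cursor[2], timeout = FALSE,
        stringsAsFactors = FALSE)
      dwell <- newDwellState()       # all hold counters reset
      if (rule@recenter) {
        cursor <- center
        lock <- lockoutBins(rule, tick)
      }
      trialStart <- tNow
      cued <- nextCue(events[[length(events)]])
    } else if (tNow - trialStart > trialTimeout) {
      events[[length(events) + 1L]] <- data.frame(
        time = tNow, cuedId = cued, selectedId = NA_integer_,
        method = NA_character_, correct = NA,
        clickX = cursor[1], clickY = cursor[2], timeout = TRUE,
        stringsAsFactors = FALSE)
      dwell <- newDwellState()
      trialStart <- tNow
      cued <- nextCue(events[[length(events)]])
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(0), cuedId = integer(0),
               selectedId = integer(0), method = character(0),
               correct = logical(0), clickX = numeric(0),
               clickY = numeric(0), timeout = logical(0))
  labs <- layout@targets$label[match(ev$selectedId, layout@targets$id)]
  ev$selectedLabel <- labs
  ev$cuedLabel <- layout@targets$label[match(ev$cuedId, layout@targets$id)]
  list(events = ev, elapsed = endTime, finalCursor = cursor)
}

#' Run one grid evaluation block
#'
#' One target is cued uniformly at random; after each selection a new
#' target is immediately prompted. The block runs for a fixed duration.
#' Timed-out trials are logged with a missing selection: they do not
#' count toward S or E but their time is included in the elapsed time.
#'
#' @param layout a grid \linkS4class{TaskLayout}
#' @param rule a \linkS4class{SelectionRule}
#' @param controller per-tick controller: function(ctx) ->
#'   list(position, click) (see the closed-loop module for the neural
#'   controller; tests may use stubs)
#' @param duration block duration, s (two-minute blocks by default)
#' @param trialTimeout per-trial limit, s
#' @param seed RNG seed for the cued-target sequence
#' @return list(events, result) where result is a one-row
#'   \code{data.frame} from \code{\link{scoreBlock}}
#' @export
runGridBlock <- function(layout, rule, controller, duration = 120,
                         trialTimeout = 10, seed = 1L) {
  set.seed(childSeed(seed, 5L))
  ids <- layout@targets$id
  nextCue <- function(lastEvent) sample(ids, 1L)
  out <- runBlockEngine(layout, rule, controller, nextCue,
                        duration, trialTimeout)
  res <- scoreBlock(out$events, layout, out$elapsed, task = "grid")
  list(events = out$events, result = res)
}

#' Run one copy-typing evaluation block
#'
#' A sentence is prompted; the cued key on each trial is the next
#' needed character given the committed (net-of-backspace) transcript,
#' or backspace after an incorrect selection. The block ends when the
#' final letter of the sentence is typed or the duration cap elapses,
#' whichever occurs first.
#'
#' @param layout a keyboard \linkS4class{TaskLayout}
#' @param rule a \linkS4class{SelectionRule}
#' @param controller per-tick controller (see \code{\link{runGridBlock}})
#' @param sentence prompted sentence; every character must be on the
#'   layout ("_" keys serve spaces)
#' @param duration duration cap, s
#' @param trialTimeout per-trial limit, s (Inf: no per-trial timeout)
#' @param seed RNG seed (cue sequence is deterministic; the seed feeds
#'   the controller's environment if it draws randomness)
#' @return list(events, result, transcript)
#' @export
runCopyTypingBlock <- function(layout, rule, controller, sentence,
                               duration = 120, trialTimeout = Inf,
                               seed = 1L) {
  set.seed(childSeed(seed, 6L))
  chars <- strsplit(sentence, "")[[1L]]
  chars[chars == " "] <- "_"
  if (!all(chars %in% layout@targets$label))
    stop("sentence contains characters not on the layout: ",
         paste(setdiff(chars, layout@targets$label), collapse = ""))
  transcript <- character(0)
  cursorRef <- c((layout@bounds[1] + layout@bounds[3]) / 2,
                 (layout@bounds[2] + layout@bounds[4]) / 2)
  nearestKey <- function(label, from) {
    ids <- targetsWithLabel(layout, label)
    if (length(ids) == 1L) return(ids)
    d <- vapply(ids, function(id)
      sqrt(sum((targetCenter(layout, id) - from)^2)), numeric(1))
    ids[which.min(d)]
  }
  nextCue <- function(lastEvent) {
    if (!is.null(lastEvent) && !lastEvent$timeout) {
      lab <- lastEvent$selectedLabel %||%
        layout@targets$label[match(lastEvent$selectedId, layout@targets$id)]
      if (identical(lab, "<")) {
        if (length(transcript)) transcript <<- transcript[-length(transcript)]
      } else transcript <<- c(transcript, lab)
      cursorRef <<- c(lastEvent$clickX, lastEvent$clickY)
    }
    n <- length(transcript)
    if (n == length(chars) && all(transcript == chars))
      return(NA_integer_)                       # sentence complete
    if (n < length(chars) && (n == 0L || all(transcript == chars[seq_len(n)])))
      return(nearestKey(chars[n + 1L], cursorRef))
    nearestKey("<", cursorRef)                  # error: cue backspace
  }
  out <- runBlockEngine(layout, rule, controller, nextCue,
                        duration, trialTimeout)
  res <- scoreBlock(out$events, layout, out$elapsed, task = "typing")
  list(events = out$events, result = res,
       transcript = paste(gsub("_", " ", transcript), collapse = ""))
}

#' Sample a blockset task ordering
#'
#' The three evaluation blocks of a blockset are randomized subject to
#' the constraint that the two copy-typing blocks are always adjacent,
#' leaving exactly four of the six permutations.
#'
#' @param tasks length-3 character vector: one grid task and two
#'   keyboard tasks (positions 2 and 3 are treated as the copy-typing
#'   pair)
#' @param seed RNG seed
#' @return permuted task vector
#' @export
sampleBlocksetOrder <- function(tasks = c("grid", "opti2", "qwerty"),
                                seed = 1L) {
  stopifnot(length(tasks) == 3L)
  set.seed(childSeed(seed, 7L))
  orders <- list(c(1L, 2L, 3L), c(1L, 3L, 2L),
                 c(2L, 3L, 1L), c(3L, 2L, 1L))
  tasks[orders[[sample.int(4L, 1L)]]]
}
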