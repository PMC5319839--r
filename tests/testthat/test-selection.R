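# Dwell automata, recentering lockout, block engines and blocksets.

# Scripted controller: follows a fixed per-tick itinerary of positions
# and click flags.
scriptController <- function(positions, clicks = NULL) {
  i <- 0L
  function(ctx) {
    i <<- i + 1L
    k <- min(i, nrow(positions))
    list(position = positions[k, ],
         click = if (is.null(clicks)) FALSE else clicks[k])
  }
}

# Controller that teleports onto the cued key and clicks once per
# `period` ticks ("perfect selector").
perfectSelector <- function(period = 66L) {
  i <- 0L
  function(ctx) {
    i <<- i + 1L
    list(position = ctx$cuedCenter, click = i %% period == 0L)
  }
}

test_that("reset dwell requires an uninterrupted hold beyond 1 s", {
  rule <- selectionRule("dwell_reset", 1.0)
  st <- newDwellState()
  # 66 ticks (0.99 s) then exit: no selection
  for (i in 1:66) {
    r <- dwellUpdate(st, 7L, rule); st <- r$state
    expect_true(is.na(r$selected))
  }
  r <- dwellUpdate(st, NA_integer_, rule); st <- r$state
  # re-enter: counter restarted; the 67th consecutive tick selects
  for (i in 1:66) { r <- dwellUpdate(st, 7L, rule); st <- r$state }
  expect_true(is.na(r$selected))
  r <- dwellUpdate(st, 7L, rule)
  expect_identical(r$selected, 7L)
})

test_that("cumulative dwell accumulates across exits", {
  rule <- selectionRule("dwell_cumulative", 1.5)
  st <- newDwellState()
  seqIds <- c(rep(1L, 50L), rep(2L, 10L), rep(1L, 60L))
  fired <- NA_integer_; firedAt <- NA_integer_
  for (k in seq_along(seqIds)) {
    r <- dwellUpdate(st, seqIds[k], rule); st <- r$state
    if (!is.na(r$selected) && is.na(fired)) { fired <- r$selected; firedAt <- k }
  }
  # A selected on its 101st tick: 50 + 51 accumulated ticks (1.515 s)
  expect_identical(fired, 1L)
  expect_identical(firedAt, 50L + 10L + 51L)
})

test_that("dwell automata match the independent oracle", {
  set.seed(81)
  for (mode in c("reset", "cumulative")) {
    rule <- selectionRule(paste0("dwell_", mode),
                          if (mode == "reset") 1.0 else 1.5)
    for (rep in 1:10) {
      hovered <- sample(c(NA_integer_, 1L, 1L, 1L, 2L), 400L,
                        replace = TRUE)
      st <- newDwellState()
      got <- rep(NA_integer_, 400L)
      for (k in seq_along(hovered)) {
        r <- dwellUpdate(st, hovered[k], rule)
        st <- r$state
        if (!is.na(r$selected)) {
          got[k] <- r$selected
          st <- newDwellState()    # engine resets all counters
        }
      }
      expect_identical(got, dwellOracle(hovered, mode, rule@dwellRequired))
    }
  }
})

test_that("recentering teleports the cursor and locks out selection", {
  lay <- makeGridLayout(6L)
  rule <- selectionRule("click_or_dwell", 1.0, recenter = TRUE,
                        recenterLockout = 0.5)
  # click every tick: without lockout this would select every tick
  ctrl <- function(ctx) list(position = ctx$cuedCenter, click = TRUE)
  blk <- runGridBlock(lay, rule, ctrl, duration = 10, seed = 82L)
  ev <- blk$events
  expect_gt(nrow(ev), 2L)
  # the lockout spans 33 full 15-ms bins; the 34th bin may select
  gaps <- diff(ev$time)
  expect_true(all(gaps >= 34 * 0.015 - 1e-9))
  expect_true(any(abs(gaps - 34 * 0.015) < 1e-9))
})

test_that("a perfect one-per-second selector yields S = 120, E = 0", {
  lay <- makeGridLayout(6L)
  rule <- selectionRule("click_or_dwell", 1.0)
  blk <- runGridBlock(lay, rule, perfectSelector(66L), duration = 120,
                      trialTimeout = 10, seed = 83L)
  # 8000 ticks / 66 = 121 clicks; at 1.01 s per selection, ~120 made
  expect_gte(blk$result$S, 119L)
  expect_identical(blk$result$E, 0L)
  expect_identical(blk$result$D, 0L)
  expect_equal(blk$result$t, 120)
})

test_that("cued-target sequences are seeded and uniform", {
  lay <- makeGridLayout(6L)
  rule <- selectionRule("click_or_dwell", 1.0)
  b1 <- runGridBlock(lay, rule, perfectSelector(5L), duration = 30,
                     seed = 84L)
  b2 <- runGridBlock(lay, rule, perfectSelector(5L), duration = 30,
                     seed = 84L)
  expect_identical(b1$events$cuedId, b2$events$cuedId)
  # chi-square uniformity over ~10000 trials
  instant <- function(ctx) list(position = ctx$cuedCenter, click = TRUE)
  big <- runGridBlock(lay, rule, instant, duration = 10000 * 0.015,
                      seed = 85L)
  counts <- table(factor(big$events$cuedId, levels = layoutTargets(lay)$id))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("timeouts are logged but excluded from S and E", {
  lay <- makeGridLayout(6L)
  rule <- selectionRule("dwell_reset", 1.0)
  flip <- TRUE
  idle <- function(ctx) {   # hops between two cells so dwell never fires
    flip <<- !flip
    list(position = if (flip) c(0.05, 0.05) else c(0.95, 0.95),
         click = FALSE)
  }
  blk <- runGridBlock(lay, rule, idle, duration = 30, trialTimeout = 5,
                      seed = 86L)
  expect_gt(sum(blk$events$timeout), 0L)
  expect_identical(blk$result$S, 0L)
  expect_identical(blk$result$E, 0L)
  expect_equal(blk$result$t, 30)
  expect_equal(blk$result$bitrate, 0)
})

test_that("copy typing cues characters, backspace after errors", {
  kb <- makeKeyboardLayout("qwerty")
  rule <- selectionRule("click_or_dwell", 1.0)
  # error-free typist: sentence completes, D = 0, transcript matches
  typist <- function(ctx) list(position = ctx$cuedCenter, click = TRUE)
  blk <- runCopyTypingBlock(kb, rule, typist, "the quick brown fox",
                            duration = 120, seed = 87L)
  expect_identical(blk$transcript, "the quick brown fox")
  expect_identical(blk$result$D, 0L)
  expect_identical(blk$result$E, 0L)
  expect_identical(blk$result$S, nchar("the quick brown fox"))
  expect_lt(blk$result$t, 120)
  # one wrong key, then backspace, then the correct key: S = 3, D = 1
  wrongOnce <- local({
    i <- 0L
    function(ctx) {
      i <<- i + 1L
      pos <- if (i == 1L) {
        xk <- layoutTargets(kb)[layoutTargets(kb)$label == "x", ]
        c((xk$x0 + xk$x1) / 2, (xk$y0 + xk$y1) / 2)
      } else ctx$cuedCenter
      list(position = pos, click = TRUE)
    }
  })
  blk2 <- runCopyTypingBlock(kb, rule, wrongOnce, "t", duration = 60,
                             seed = 88L)
  expect_identical(blk2$result$S, 3L)
  expect_identical(blk2$result$D, 1L)
  expect_identical(blk2$transcript, "t")
  # net correct = S - 2D = 1
  expect_equal(blk2$result$ccpm * blk2$result$t / 60, 1)
  # cap: a sentence that cannot finish records t = cap
  flip <- TRUE
  slow <- function(ctx) {   # hops between keys so nothing ever selects
    flip <<- !flip
    list(position = if (flip) c(0.05, 0.9) else c(0.95, 0.9),
         click = FALSE)
  }
  blk3 <- runCopyTypingBlock(kb, rule, slow, "zzz", duration = 9,
                             seed = 89L)
  expect_equal(blk3$result$t, 9)
  expect_error(runCopyTypingBlock(kb, rule, typist, "café"),
               "not on the layout")
})

test_that("blockset orderings keep the copy-typing blocks adjacent", {
  allowed <- list(c("grid", "k1", "k2"), c("grid", "k2", "k1"),
                  c("k1", "k2", "grid"), c("k2", "k1", "grid"))
  seen <- character(0)
  for (s in 1:500) {
    o <- sampleBlocksetOrder(c("grid", "k1", "k2"), seed = s)
    kbPos <- which(o %in% c("k1", "k2"))
    expect_identical(diff(kbPos), 1L)
    expect_true(any(vapply(allowed, identical, logical(1), y = o)))
    seen <- c(seen, paste(o, collapse = ","))
  }
  # exactly the four permitted orderings occur
  expect_identical(sort(unique(seen)),
                   sort(vapply(allowed, paste, character(1),
                               collapse = ",")))
  expect_identical(sampleBlocksetOrder(seed = 7L),
                   sampleBlocksetOrder(seed = 7L))
})
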