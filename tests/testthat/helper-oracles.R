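# Independent oracles used to check the package's implementations.
# These are written from the definitions, not from the package code.

# Batch forward algorithm for a 2-state Gaussian HMM, with per-step
# rescaling. Densities computed via solve/determinant, independent of
# the package's Cholesky log-density path.
forwardOracle <- function(means, covs, trans, Z, init = c(0.5, 0.5)) {
  dens <- function(z, m, S) {
    d <- z - m
    exp(-0.5 * as.numeric(t(d) %*% solve(S) %*% d)) /
      sqrt((2 * pi)^length(z) * det(S))
  }
  TT <- nrow(Z)
  out <- matrix(0, TT, 2L)
  prev <- init
  for (t in seq_len(TT)) {
    b <- c(dens(Z[t, ], means[1L, ], covs[[1L]]),
           dens(Z[t, ], means[2L, ], covs[[2L]]))
    a <- b * as.numeric(t(trans) %*% prev)
    prev <- a / sum(a)
    out[t, ] <- prev
  }
  out
}

# Counter-automaton oracle for the consecutive-bin click rule.
clickRuleOracle <- function(above, consecutive = 2L) {
  run <- 0L
  clicks <- integer(0)
  for (t in seq_along(above)) {
    run <- if (above[t]) run + 1L else 0L
    if (run == consecutive) {
      clicks <- c(clicks, t)
      run <- 0L
    }
  }
  clicks
}

# Independent dwell-selection oracle over a hovered-id sequence.
# Selection fires once the accumulated hold (ticks) strictly exceeds
# dwellRequired; all counters reset after a selection.
dwellOracle <- function(hovered, mode, dwellRequired, tick = 0.015) {
  need <- floor(dwellRequired / tick + 1e-9) + 1
  sel <- rep(NA_integer_, length(hovered))
  counters <- new.env(parent = emptyenv())
  cur <- NA_integer_; run <- 0L
  for (t in seq_along(hovered)) {
    h <- hovered[t]
    if (mode == "reset") {
      if (is.na(h) || is.na(cur) || h != cur) { cur <- h; run <- 0L }
      if (!is.na(h)) {
        run <- run + 1L
        if (run >= need) {
          sel[t] <- h
          cur <- NA_integer_; run <- 0L
        }
      }
    } else {
      if (!is.na(h)) {
        key <- as.character(h)
        cnt <- (if (!is.null(counters[[key]])) counters[[key]] else 0L) + 1L
        counters[[key]] <- cnt
        if (cnt >= need) {
          sel[t] <- h
          rm(list = ls(counters), envir = counters)
        }
      }
    }
  }
  sel
}

# Regression oracle for preferred-direction recovery: per-channel OLS
# of counts on (vx, vy), direction = atan2 of the slopes.
recoverDirectionsOracle <- function(counts, vx, vy) {
  apply(counts, 1L, function(y) {
    b <- coef(lm(y ~ vx + vy))
    atan2(b[3L], b[2L])
  })
}

# Smallest absolute angular difference in degrees.
angDiffDeg <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d) * 180 / pi
}
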