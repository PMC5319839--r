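# Selectable workspaces: grids and keyboards.

#' Grid task layout
#'
#' Divides the workspace into an n x n grid of equal, tiling,
#' half-open square cells, so every interior point maps to exactly one
#' cell. The standard configurations are 6 x 6 (36 targets) and the
#' denser 9 x 9 (81 targets).
#'
#' @param n grid side; values outside \{6, 9\} are allowed but flagged
#'   nonstandard with a message
#' @param bounds workspace bounds c(xmin, ymin, xmax, ymax)
#' @return a \linkS4class{TaskLayout}
#' @export
makeGridLayout <- function(n = 6L, bounds = c(0, 0, 1, 1)) {
  n <- as.integer(n)
  if (bounds[3] <= bounds[1] || bounds[4] <= bounds[2])
    stop("degenerate workspace bounds")
  if (!n %in% c(6L, 9L))
    message("nonstandard grid size n = ", n)
  xs <- seq(bounds[1], bounds[3], length.out = n + 1L)
  ys <- seq(bounds[2], bounds[4], length.out = n + 1L)
  idx <- expand.grid(col = seq_len(n), row = seq_len(n))
  tg <- data.frame(
    id = seq_len(n * n),
    label = paste0("r", idx$row, "c", idx$col),
    x0 = xs[idx$col], y0 = ys[idx$row],
    x1 = xs[idx$col + 1L], y1 = ys[idx$row + 1L],
    stringsAsFactors = FALSE)
  new("TaskLayout", targets = tg, bounds = bounds,
      layoutKind = if (n == 6L) "grid6" else if (n == 9L) "grid9" else "grid")
}

#' Keyboard task layouts
#'
#' Loads the key arrangement from the packaged layout files. The QWERTY
#' and ABCDEF keyboards share identical key geometry (the ABCDEF keys
#' are simply relabelled alphabetically left-to-right, top-to-bottom).
#' The OPTI-II-style layout is a reconstruction of the published
#' optimized arrangement (high-frequency letters clustered centrally,
#' several space keys); it ships as a documented data file, not as
#' hard-coded logic. Labels: letters, "_" = space, "<" = backspace.
#'
#' @param kind "opti2", "qwerty" or "abcdef"
#' @param bounds workspace bounds c(xmin, ymin, xmax, ymax)
#' @return a \linkS4class{TaskLayout}
#' @export
makeKeyboardLayout <- function(kind = c("opti2", "qwerty", "abcdef"),
                               bounds = c(0, 0, 1, 1)) {
  kind <- match.arg(kind)
  path <- system.file("extdata", paste0("layout_", kind, ".csv"),
                      package = "bcisim", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("integer", "character",
                                       "integer", "integer"))
  nr <- max(df$row); nc <- max(df$col)
  w <- (bounds[3] - bounds[1]) / nc
  h <- (bounds[4] - bounds[2]) / nr
  tg <- data.frame(
    id = df$id, label = df$label,
    x0 = bounds[1] + (df$col - 1L) * w,
    y0 = bounds[2] + (nr - df$row) * h,   # row 1 at the top
    stringsAsFactors = FALSE)
  tg$x1 <- tg$x0 + w
  tg$y1 <- tg$y0 + h
  new("TaskLayout", targets = tg, bounds = bounds, layoutKind = kind)
}

#' Map a workspace position to the target under it
#'
#' Half-open containment ([x0, x1) x [y0, y1)): a point on a shared
#' edge belongs to exactly one cell. Returns NA over dead space.
#'
#' @param layout a \linkS4class{TaskLayout}
#' @param position 2-vector
#' @return target id or NA
#' @export
hitTest <- function(layout, position) {
  tg <- layout@targets
  hit <- tg$x0 <= position[1] & position[1] < tg$x1 &
         tg$y0 <= position[2] & position[2] < tg$y1
  if (!any(hit)) return(NA_integer_)
  tg$id[which(hit)[1L]]
}

# Center of a target id.
targetCenter <- function(layout, id) {
  tg <- layout@targets
  i <- match(id, tg$id)
  c((tg$x0[i] + tg$x1[i]) / 2, (tg$y0[i] + tg$y1[i]) / 2)
}

# Ids of targets carrying a given label (keyboards may have several
# space keys).
targetsWithLabel <- function(layout, label) {
  layout@targets$id[layout@targets$label == label]
}

#' Mean center-to-center travel distance over weighted digraphs
#'
#' The statistic motivating optimized keyboard layouts: expected
#' cursor travel between successive characters under an English
#' digraph distribution. For characters served by several keys (space),
#' the nearest matching key is used.
#'
#' @param layout a \linkS4class{TaskLayout}
#' @param digraphs data.frame with columns from, to, weight; default:
#'   the packaged English digraph table
#' @return weighted mean distance, workspace units
#' @export
meanDigraphDistance <- function(layout, digraphs = NULL) {
  if (is.null(digraphs)) {
    path <- system.file("extdata", "english_digraphs.csv",
                        package = "bcisim", mustWork = TRUE)
    digraphs <- utils::read.csv(path, stringsAsFactors = FALSE,
                                colClasses = c("character", "character",
                                               "numeric"))
  }
  centers <- lapply(layout@targets$id, function(id) targetCenter(layout, id))
  labs <- layout@targets$label
  dist1 <- function(fromLab, toLab) {
    fi <- which(labs == fromLab); ti <- which(labs == toLab)
    if (!length(fi) || !length(ti)) return(NA_real_)
    min(vapply(fi, function(i) min(vapply(ti, function(j)
      sqrt(sum((centers[[i]] - centers[[j]])^2)), numeric(1))), numeric(1)))
  }
  d <- mapply(dist1, digraphs$from, digraphs$to)
  ok <- !is.na(d)
  sum(d[ok] * digraphs$weight[ok]) / sum(digraphs$weight[ok])
}
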