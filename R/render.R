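#' Calibration statistics for the pattern -> pixel mapping
#'
#' Records, per (pattern kind, axis), the minimum and maximum pattern value
#' observed on a calibration (training) set.  These bounds anchor the linear
#' mapping from pattern values to marked-pixel counts; values outside the
#' bounds at encoding time are clamped.
#'
#' @param patterns data.frame as produced by [pattern_table()] (columns
#'   `kind`, `axis`, `value`), typically the training portion of a dataset.
#' @return data.frame of class `calibration_stats` with columns `kind`,
#'   `axis`, `minp`, `maxp`, `flat` (TRUE when maxp == minp).
#' @export
calibrate_patterns <- function(patterns) {
  if (nrow(patterns) == 0) stop("cannot calibrate on an empty pattern table")
  agg <- stats::aggregate(value ~ kind + axis, data = patterns,
                          FUN = function(v) c(min = min(v), max = max(v)))
  out <- data.frame(kind = agg$kind, axis = agg$axis,
                    minp = agg$value[, "min"], maxp = agg$value[, "max"],
                    stringsAsFactors = FALSE)
  out$flat <- out$maxp == out$minp
  if (any(!is.finite(out$minp)) || any(!is.finite(out$maxp))) {
    stop("non-finite pattern values in calibration set")
  }
  structure(out, class = c("calibration_stats", "data.frame"))
}

stats_entry <- function(stats, kind, axis) {
  hit <- stats[stats$kind == kind & stats$axis == axis, , drop = FALSE]
  if (nrow(hit) != 1) {
    stop("uncalibrated pattern: no stats for (", kind, ", ", axis, ")")
  }
  list(minp = hit$minp, maxp = hit$maxp)
}

#' Pixel budget of a region
#'
#' @param maxpx largest number of pixels that may be marked in a region
#'   (defaults to the full region at render time).
#' @param minpx smallest number (default 0).
#' @return list of class `pixel_budget`.
#' @export
pixel_budget <- function(maxpx, minpx = 0L) {
  minpx <- as.integer(minpx); maxpx <- as.integer(maxpx)
  if (minpx < 0 || maxpx < minpx) stop("need 0 <= minpx <= maxpx")
  structure(list(minpx = minpx, maxpx = maxpx), class = "pixel_budget")
}

#' Map a pattern value to a number of marked pixels
#'
#' Linear mapping from the calibrated pattern range `[minp, maxp]` onto the
#' pixel budget `[minpx, maxpx]`, taken through the floor function so the
#' result is a whole number of pixels:
#' `M(pa) = floor(minpx + (maxpx - minpx) * (pa - minp) / (maxp - minp))`.
#' `pa` is clamped to the calibrated range first, so the endpoints map
#' exactly to `minpx` and `maxpx` and the result is monotone nondecreasing
#' in `pa`.  A degenerate (flat) calibration maps everything to `minpx`.
#'
#' @param pa pattern value(s); vectorised.
#' @param stats list with `minp`, `maxp` (one [calibrate_patterns()] row via
#'   its `minp`/`maxp` columns, or any list with those fields).
#' @param budget a [pixel_budget()].
#' @return integer vector of marked-pixel counts in `[minpx, maxpx]`.
#' @export
map_to_pixels <- function(pa, stats, budget) {
  minp <- stats$minp; maxp <- stats$maxp
  if (maxp <= minp) return(rep(budget$minpx, length(pa)))
  pa <- pmin(pmax(pa, minp), maxp)
  # form the ratio first so pa = maxp maps to exactly maxpx (the product
  # (maxpx - minpx) * (pa - minp) can otherwise round just below a whole
  # number and floor one pixel short)
  ratio <- (pa - minp) / (maxp - minp)
  as.integer(floor(budget$minpx + (budget$maxpx - budget$minpx) * ratio))
}

#' Filling strategies
#' @export
fill_strategies <- function() c("CCW", "CW", "Diag", "Strk")

#' Deterministic pixel path covering one region
#'
#' Generates the ordered pixel coordinates along which a region is filled.
#' Every strategy visits each of the `Px * Py` pixels exactly once:
#'
#' * `CCW` — counterclockwise spiral growing outwards from the centre pixel
#'   (for even dimensions, the pixel just before the centre); steps up,
#'   left, down, right with increasing arm lengths, skipping positions that
#'   fall outside the region.
#' * `CW` — clockwise spiral from the top-left corner inwards along the
#'   region boundary.
#' * `Diag` — 45-degree anti-diagonals starting at the top-left corner, each
#'   diagonal drawn upwards (towards the top-right).
#' * `Strk` — continuous strokes crossing a row of 3 regions: reverse
#'   diagonals in the first region, horizontal lines in the second, diagonals
#'   in the third; lines are drawn left to right, stacked alternately above
#'   and below the first line.  The start pixel is the top-left corner,
#'   unless the previous region of the row has a marked pixel in its last
#'   column, in which case the stroke starts next to the highest such pixel.
#'
#' @param strategy one of [fill_strategies()].
#' @param Px,Py region size in pixels.
#' @param context for `Strk` only: list with `position` (1-3, place of the
#'   region in its row-of-3), and optionally `prev_path` (the previous
#'   region's path matrix) and `prev_m` (its marked count) used to anchor the
#'   start pixel.
#' @return integer matrix `Px*Py x 2` of 0-based (row, col) coordinates,
#'   origin top-left, in visiting order.
#' @export
fill_path <- function(strategy, Px, Py, context = NULL) {
  strategy <- match.arg(strategy, fill_strategies())
  Px <- as.integer(Px); Py <- as.integer(Py)
  if (Px < 1 || Py < 1) stop("region dimensions must be >= 1")
  switch(strategy,
         CCW = path_ccw(Px, Py),
         CW = path_cw(Px, Py),
         Diag = path_diag(Px, Py),
         Strk = path_strk(Px, Py, context))
}

path_ccw <- function(Px, Py) {
  n <- Px * Py
  r <- as.integer(ceiling(Py / 2) - 1)   # centre (or just before, even dims)
  cc <- as.integer(ceiling(Px / 2) - 1)
  out <- matrix(NA_integer_, n, 2)
  cnt <- 0L
  emit <- function(r, cc) {
    if (r >= 0 && r < Py && cc >= 0 && cc < Px) {
      cnt <<- cnt + 1L
      out[cnt, ] <<- c(r, cc)
    }
  }
  emit(r, cc)
  dirs <- matrix(c(-1L, 0L,  0L, -1L,  1L, 0L,  0L, 1L), ncol = 2, byrow = TRUE)
  arm <- 0L
  d <- 0L
  while (cnt < n) {
    if (d %% 2L == 0L) arm <- arm + 1L   # arm grows every 2 turns: 1,1,2,2,...
    dr <- dirs[d %% 4L + 1L, 1L]; dc <- dirs[d %% 4L + 1L, 2L]
    for (s in seq_len(arm)) {
      r <- r + dr; cc <- cc + dc
      emit(r, cc)
      if (cnt == n) break
    }
    d <- d + 1L
  }
  out
}

path_cw <- function(Px, Py) {
  n <- Px * Py
  out <- matrix(NA_integer_, n, 2)
  top <- 0L; bottom <- Py - 1L; left <- 0L; right <- Px - 1L
  cnt <- 0L
  add <- function(r, cc) { cnt <<- cnt + 1L; out[cnt, ] <<- c(r, cc) }
  while (cnt < n) {
    for (cc in left:right) add(top, cc)
    top <- top + 1L
    if (cnt == n) break
    for (r in top:bottom) add(r, right)
    right <- right - 1L
    if (cnt == n) break
    for (cc in right:left) add(bottom, cc)
    bottom <- bottom - 1L
    if (cnt == n) break
    for (r in bottom:top) add(r, left)
    left <- left + 1L
  }
  out
}

path_diag <- function(Px, Py) {
  rows <- integer(0); cols <- integer(0)
  for (d in 0:(Px + Py - 2L)) {
    r <- min(d, Py - 1L):max(0L, d - Px + 1L)   # bottom-left to top-right
    rows <- c(rows, r)
    cols <- c(cols, d - r)
  }
  cbind(rows, cols, deparse.level = 0)
}

# line families for the strokes strategy: index of the line through (r, c)
strk_line_index <- function(family, r, cc) {
  switch(family,
         rev_diag = r - cc,
         horizontal = r,
         diag = r + cc)
}

strk_line_pixels <- function(family, d, Px, Py) {
  # all pixels of line d, ordered left to right (increasing column)
  cc <- 0:(Px - 1L)
  r <- switch(family,
              rev_diag = d + cc,
              horizontal = rep(d, Px),
              diag = d - cc)
  keep <- r >= 0 & r < Py
  cbind(r[keep], cc[keep], deparse.level = 0)
}

path_strk <- function(Px, Py, context = NULL) {
  position <- if (is.null(context$position)) 1L else as.integer(context$position)
  if (!position %in% 1:3) stop("Strk position must be 1, 2 or 3")
  family <- c("rev_diag", "horizontal", "diag")[position]
  start <- c(0L, 0L)
  if (!is.null(context$prev_path) && !is.null(context$prev_m) &&
      context$prev_m > 0) {
    marked <- context$prev_path[seq_len(context$prev_m), , drop = FALSE]
    adj <- marked[marked[, 2] == Px - 1L, , drop = FALSE]  # last column
    if (nrow(adj) > 0) {
      start <- c(min(adj[, 1]), 0L)       # next to the highest marked pixel
      start[1] <- min(max(start[1], 0L), Py - 1L)
    }
  }
  d0 <- strk_line_index(family, start[1], start[2])
  drange <- switch(family,
                   rev_diag = (-(Px - 1L)):(Py - 1L),
                   horizontal = 0:(Py - 1L),
                   diag = 0:(Px + Py - 2L))
  # first the line through the start pixel, then alternately the line above
  # and the line below the block drawn so far
  order_d <- d0
  k <- 1L
  while (length(order_d) < length(drange)) {
    for (cand in c(d0 - k, d0 + k)) {
      if (cand %in% drange && !(cand %in% order_d)) order_d <- c(order_d, cand)
    }
    k <- k + 1L
  }
  do.call(rbind, lapply(order_d, strk_line_pixels, family = family,
                        Px = Px, Py = Py))
}

#' Mark the first m pixels of a fill path
#'
#' @param path a [fill_path()] matrix.
#' @param m number of pixels to mark (0..Px*Py).
#' @param Px,Py region size.
#' @return logical `Py x Px` matrix; TRUE = marked.
#' @export
render_region <- function(path, m, Px, Py) {
  if (m < 0 || m > Px * Py) stop("marked count out of range")
  mask <- matrix(FALSE, Py, Px)
  if (m > 0) {
    sel <- path[seq_len(m), , drop = FALSE]
    mask[sel[, 1] + sel[, 2] * Py + 1L] <- TRUE
  }
  mask
}

# --- region values ----------------------------------------------------------

#' Pattern array of a window set
#'
#' Dense `[window, axis, kind]` lookup of pattern values, precomputed once
#' per window set and shared by the renderers.
#'
#' @param ws a `window_set`.
#' @return 3-d numeric array with dimnames (NULL, axes, kinds).
#' @export
pattern_array <- function(ws) {
  kinds <- canvas_pattern_kinds()
  nw <- n_windows(ws)
  P <- array(0, dim = c(nw, length(ws$axes), length(kinds)),
             dimnames = list(NULL, ws$axes, kinds))
  for (w in seq_len(nw)) {
    for (ax in ws$axes) {
      pv <- extract_patterns(ws$values[, w, ax])
      for (k in kinds) P[w, ax, k] <- pattern_value_of_kind(pv, k)
    }
  }
  P
}

# pattern value at a single window index; absent windows contribute 0
pat_at <- function(P, i, axis, kind) {
  nw <- dim(P)[1]
  if (i < 1 || i > nw) 0 else P[i, axis, kind]
}

# value of a region for a given centre window: span w is the window itself,
# spans u/v average the two windows before/after (absent neighbours = 0)
region_value <- function(P, center, axis, kind, span) {
  switch(span,
         w = pat_at(P, center, axis, kind),
         u = (pat_at(P, center - 2L, axis, kind) +
                pat_at(P, center - 1L, axis, kind)) / 2,
         v = (pat_at(P, center + 1L, axis, kind) +
                pat_at(P, center + 2L, axis, kind)) / 2,
         stop("unknown span: ", span))
}

# --- canvas assembly --------------------------------------------------------

# full schedule of strategies over the Rx*Ry regions, row-major
expand_schedule <- function(schedule, n_regions) {
  schedule <- match.arg(schedule, fill_strategies(), several.ok = TRUE)
  rep_len(schedule, n_regions)
}

# per-region marked counts for one centre window; row-major order
region_marks <- function(P, center, layout, cspec, stats, budget) {
  vapply(seq_len(nrow(layout)), function(i) {
    e <- stats_entry(stats, layout$kind[i], layout$axis[i])
    map_to_pixels(region_value(P, center, layout$axis[i], layout$kind[i],
                               layout$span[i]), e, budget)
  }, integer(1))
}

# assemble the boolean canvas mask from per-region marked counts
canvas_mask <- function(marks, layout, cspec, schedule) {
  mask <- matrix(FALSE, cspec$height, cspec$width)
  sched <- expand_schedule(schedule, nrow(layout))
  prev_path <- NULL; prev_m <- NULL
  for (i in seq_len(nrow(layout))) {
    rr <- layout$row[i]; cc <- layout$col[i]
    ctx <- NULL
    if (sched[i] == "Strk") {
      pos <- (cc %% 3L) + 1L
      ctx <- list(position = pos)
      if (pos > 1L && i > 1L && layout$row[i - 1L] == rr &&
          sched[i - 1L] == "Strk") {
        ctx$prev_path <- prev_path
        ctx$prev_m <- prev_m
      }
    }
    path <- fill_path(sched[i], cspec$Px, cspec$Py, ctx)
    reg <- render_region(path, marks[i], cspec$Px, cspec$Py)
    mask[rr * cspec$Py + seq_len(cspec$Py),
         cc * cspec$Px + seq_len(cspec$Px)] <- reg
    prev_path <- path; prev_m <- marks[i]
  }
  mask
}

new_rendered_image <- function(arr, provenance) {
  storage.mode(arr) <- "integer"
  structure(list(pixels = arr, width = dim(arr)[2], height = dim(arr)[1],
                 channels = dim(arr)[3], provenance = provenance),
            class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("<rendered_image> %dx%d px, %d channel(s); window %s, label %s\n",
              x$width, x$height, x$channels,
              x$provenance$window_index, x$provenance$label))
  invisible(x)
}

default_budget <- function(cspec) pixel_budget(maxpx = cspec$Px * cspec$Py)

make_provenance <- function(ws, index, layout, cspec, schedule, coloring) {
  nw <- n_windows(ws)
  list(window_index = index, label = ws$labels[index],
       subject_id = ws$subject_id, sensor_id = ws$sensor_id,
       variant = attr(layout, "variant"), coloring = coloring,
       edge_window = index <= 2L || index > nw - 2L,
       config_hash = config_hash(unclass(cspec), as.data.frame(layout),
                                 schedule, coloring))
}

#' Render one window as a black & white canvas image
#'
#' For each region of the layout the assigned (pattern, axis, span) value is
#' computed from the window and its neighbours, mapped to a marked-pixel
#' count and filled along the scheduled strategy's path.  The default
#' schedule alternates CCW and CW over the regions in row-major order.
#'
#' @param ws a `window_set`.
#' @param index centre window (1-based).
#' @param layout a `region_assignment` (default [baseline_layout()]).
#' @param cspec a [canvas_spec()]; its `C` is ignored (output has 1 channel).
#' @param stats [calibrate_patterns()] output for this dataset.
#' @param schedule character vector of strategies, recycled over regions.
#' @param budget a [pixel_budget()] (default: 0 .. full region).
#' @param patterns optional precomputed [pattern_array()] of `ws`.
#' @return a `rendered_image` with one channel (values 0 or 255).
#' @export
render_bw <- function(ws, index, layout = baseline_layout(axes = ws$axes),
                      cspec = canvas_spec(), stats,
                      schedule = c("CCW", "CW"),
                      budget = default_budget(cspec), patterns = NULL) {
  if (missing(stats) || is.null(stats)) stop("uncalibrated: pass calibration stats")
  if (budget$maxpx > cspec$Px * cspec$Py) stop("pixel budget exceeds region size")
  P <- if (is.null(patterns)) pattern_array(ws) else patterns
  marks <- region_marks(P, index, layout, cspec, stats, budget)
  mask <- canvas_mask(marks, layout, cspec, schedule)
  arr <- array(0L, dim = c(cspec$height, cspec$width, 1L))
  arr[, , 1] <- mask * 255L
  new_rendered_image(arr, make_provenance(ws, index, layout, cspec, schedule,
                                          "bw"))
}

#' Colour rendering: window spans on separate channels
#'
#' The red channel renders the regions whose span is `u` (the two windows
#' before), green the current-window regions (`w`), blue the `v` regions;
#' regions of the other spans stay unmarked on that channel.
#'
#' @inheritParams render_bw
#' @return a `rendered_image` with three channels.
#' @export
color_simple_spans <- function(ws, index,
                               layout = baseline_layout(axes = ws$axes),
                               cspec = canvas_spec(), stats,
                               schedule = c("CCW", "CW"),
                               budget = default_budget(cspec),
                               patterns = NULL) {
  if (missing(stats) || is.null(stats)) stop("uncalibrated: pass calibration stats")
  P <- if (is.null(patterns)) pattern_array(ws) else patterns
  marks <- region_marks(P, index, layout, cspec, stats, budget)
  arr <- array(0L, dim = c(cspec$height, cspec$width, 3L))
  spans <- c("u", "w", "v")
  for (ch in 1:3) {
    m <- marks
    m[layout$span != spans[ch]] <- 0L
    arr[, , ch] <- canvas_mask(m, layout, cspec, schedule) * 255L
  }
  new_rendered_image(arr, make_provenance(ws, index, layout, cspec, schedule,
                                          "simple_spans"))
}

#' Colour rendering: neighbouring windows encoded in the pixel values
#'
#' All three channels share the marked/unmarked mask of the current window's
#' black & white render; the pixel values encode the pattern values of the
#' neighbouring windows, each scaled to `[0, 255]` with the same calibration
#' bounds (p' values).  Per region: marked red = p'(w-2), unmarked red =
#' 255 - p'(w-1); green uses p'(w0) for both (marked = p', unmarked =
#' 255 - p'); marked blue = p'(w+2), unmarked blue = 255 - p'(w+1).
#'
#' @inheritParams render_bw
#' @return a `rendered_image` with three channels.
#' @export
color_neighbor <- function(ws, index,
                           layout = baseline_layout(axes = ws$axes),
                           cspec = canvas_spec(), stats,
                           schedule = c("CCW", "CW"),
                           budget = default_budget(cspec), patterns = NULL) {
  if (missing(stats) || is.null(stats)) stop("uncalibrated: pass calibration stats")
  P <- if (is.null(patterns)) pattern_array(ws) else patterns
  marks <- region_marks(P, index, layout, cspec, stats, budget)
  mask <- canvas_mask(marks, layout, cspec, schedule)
  color_budget <- pixel_budget(maxpx = 255L)
  # p'_k per region: the region's value in the image centred k windows away,
  # scaled to [0, 255] with the shared calibration bounds
  pprime <- function(k) {
    vapply(seq_len(nrow(layout)), function(i) {
      e <- stats_entry(stats, layout$kind[i], layout$axis[i])
      map_to_pixels(region_value(P, index + k, layout$axis[i],
                                 layout$kind[i], layout$span[i]),
                    e, color_budget)
    }, integer(1))
  }
  pm2 <- pprime(-2L); pm1 <- pprime(-1L); p0 <- pprime(0L)
  pp1 <- pprime(1L); pp2 <- pprime(2L)
  arr <- array(0L, dim = c(cspec$height, cspec$width, 3L))
  chan_vals <- list(r = list(marked = pm2, unmarked = 255L - pm1),
                    g = list(marked = p0, unmarked = 255L - p0),
                    b = list(marked = pp2, unmarked = 255L - pp1))
  for (ch in 1:3) {
    plane <- matrix(0L, cspec$height, cspec$width)
    for (i in seq_len(nrow(layout))) {
      rr <- layout$row[i] * cspec$Py + seq_len(cspec$Py)
      cc <- layout$col[i] * cspec$Px + seq_len(cspec$Px)
      sub <- mask[rr, cc, drop = FALSE]
      plane[rr, cc] <- ifelse(sub, chan_vals[[ch]]$marked[i],
                              chan_vals[[ch]]$unmarked[i])
    }
    arr[, , ch] <- plane
  }
  new_rendered_image(arr, make_provenance(ws, index, layout, cspec, schedule,
                                          "neighbor"))
}

#' Colour rendering: one sensor per channel
#'
#' Each sensor's black & white canvas occupies one RGB channel (at most 3
#' sensors; more sensors belong on an augmented canvas, see
#' [augmented_layout()]).  All window sets must be windowed identically.
#'
#' @param ws_list list of up to 3 `window_set`s (one per sensor).
#' @param index centre window, shared across sensors.
#' @param stats_list list of calibration stats, one per sensor.
#' @inheritParams render_bw
#' @return a `rendered_image` with three channels.
#' @export
color_multi_sensor <- function(ws_list, index, layout = NULL,
                               cspec = canvas_spec(), stats_list,
                               schedule = c("CCW", "CW"),
                               budget = default_budget(cspec)) {
  if (length(ws_list) > 3) {
    stop("more than 3 sensors: use an augmented canvas (augmented_layout)")
  }
  arr <- array(0L, dim = c(cspec$height, cspec$width, 3L))
  for (s in seq_along(ws_list)) {
    lay <- if (is.null(layout)) baseline_layout(axes = ws_list[[s]]$axes) else layout
    bw <- render_bw(ws_list[[s]], index, lay, cspec, stats_list[[s]],
                    schedule, budget)
    arr[, , s] <- bw$pixels[, , 1]
  }
  prov <- make_provenance(ws_list[[1]], index,
                          if (is.null(layout)) baseline_layout(axes = ws_list[[1]]$axes) else layout,
                          cspec, schedule, "multi_sensor")
  prov$sensor_id <- paste(vapply(ws_list, `[[`, "", "sensor_id"),
                          collapse = "+")
  new_rendered_image(arr, prov)
}

#' Tile per-sensor renders onto an augmented canvas
#'
#' @param ws_list list of `window_set`s, one per sensor, ordered as in
#'   `aug$sensor_ids`.
#' @param index centre window, shared across sensors.
#' @param aug an [augmented_layout()].
#' @param stats_list list of calibration stats, one per sensor.
#' @param renderer per-tile renderer: [render_bw()], [color_simple_spans()]
#'   or [color_neighbor()].
#' @inheritParams render_bw
#' @return a `rendered_image` covering the full tiling; empty slots stay
#'   unmarked.
#' @export
render_augmented <- function(ws_list, index, aug, stats_list,
                             layout = NULL, schedule = c("CCW", "CW"),
                             renderer = render_bw) {
  cspec <- aug$spec
  probe <- renderer(ws_list[[1]], index,
                    if (is.null(layout)) baseline_layout(axes = ws_list[[1]]$axes) else layout,
                    cspec, stats_list[[1]], schedule)
  C <- probe$channels
  arr <- array(0L, dim = c(aug$height, aug$width, C))
  for (s in seq_along(ws_list)) {
    tile <- if (s == 1) probe else
      renderer(ws_list[[s]], index,
               if (is.null(layout)) baseline_layout(axes = ws_list[[s]]$axes) else layout,
               cspec, stats_list[[s]], schedule)
    ty <- (s - 1L) %/% aug$tiles_x
    tx <- (s - 1L) %% aug$tiles_x
    arr[ty * cspec$height + seq_len(cspec$height),
        tx * cspec$width + seq_len(cspec$width), ] <- tile$pixels
  }
  prov <- probe$provenance
  prov$sensor_id <- paste(aug$sensor_ids, collapse = "+")
  prov$tiling <- c(aug$tiles_x, aug$tiles_y)
  new_rendered_image(arr, prov)
}

#' Write a rendered image as a PNG file
#'
#' 8-bit grayscale (1 channel) or RGB (3 channels) PNG; the image provenance
#' is stored in PNG text chunks, so the bytes are stable for fixed input.
#'
#' @param img a `rendered_image`.
#' @param path output file path (created directories are the caller's job).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  arr <- img$pixels / 255
  dat <- if (img$channels == 1) arr[, , 1] else arr
  prov <- img$provenance
  txt <- c(window_index = as.character(prov$window_index),
           label = as.character(prov$label),
           subject = as.character(prov$subject_id),
           sensor = as.character(prov$sensor_id),
           variant = as.character(prov$variant),
           coloring = as.character(prov$coloring),
           edge_window = as.character(prov$edge_window),
           config = as.character(prov$config_hash))
  png::writePNG(dat, target = path, text = txt)
  invisible(path)
}

#' Encode every window of a dataset as an image
#'
#' End-to-end encoding of one or more window sets: compute pattern arrays,
#' calibrate (unless stats are supplied, e.g. from the training portion),
#' render every window, and optionally write the PNGs under
#' `<out_dir>/<label>/<subject>_<window>.png`.
#'
#' @param ws_list list of `window_set`s (or a single one).
#' @param layout a `region_assignment`.
#' @param cspec a [canvas_spec()].
#' @param coloring one of "bw", "simple_spans", "neighbor".
#' @param schedule strategy schedule, recycled over regions.
#' @param stats optional precomputed calibration; default calibrates on all
#'   windows of `ws_list`.
#' @param out_dir optional directory for PNG output.
#' @return list with `images` (list of `rendered_image`), `labels`,
#'   `meta` (data.frame subject/window/label/path), `stats`.
#' @export
encode_dataset <- function(ws_list, layout = NULL, cspec = canvas_spec(),
                           coloring = c("neighbor", "bw", "simple_spans"),
                           schedule = c("CCW", "CW"), stats = NULL,
                           out_dir = NULL) {
  coloring <- match.arg(coloring)
  if (inherits(ws_list, "window_set")) ws_list <- list(ws_list)
  if (is.null(layout)) layout <- baseline_layout(axes = ws_list[[1]]$axes)
  pats <- lapply(ws_list, pattern_array)
  if (is.null(stats)) {
    stats <- calibrate_patterns(do.call(rbind, lapply(ws_list, pattern_table)))
  }
  renderer <- switch(coloring, bw = render_bw,
                     simple_spans = color_simple_spans,
                     neighbor = color_neighbor)
  images <- list()
  meta <- list()
  for (s in seq_along(ws_list)) {
    ws <- ws_list[[s]]
    for (w in seq_len(n_windows(ws))) {
      img <- renderer(ws, w, layout, cspec, stats, schedule,
                      patterns = pats[[s]])
      path <- NA_character_
      if (!is.null(out_dir)) {
        dir <- file.path(out_dir, ws$labels[w])
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        path <- file.path(dir, sprintf("%s_%05d.png", ws$subject_id, w))
        write_image(img, path)
      }
      images[[length(images) + 1L]] <- img
      meta[[length(meta) + 1L]] <- data.frame(
        subject = ws$subject_id, window = w, label = ws$labels[w],
        path = path, stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  list(images = images, labels = meta$label, meta = meta, stats = stats)
}
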