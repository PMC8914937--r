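#' Canvas geometry
#'
#' The image is an `Rx x Ry` grid of regions, each `Px x Py` pixels, with
#' `C` channels (1 for black & white, 3 for RGB).  The default 6x6 grid of
#' 20x20-pixel regions gives the canonical 120x120 canvas for one
#' three-axis sensor.
#'
#' @param Rx,Ry regions per row / column of the canvas.
#' @param Px,Py pixels per region, horizontally / vertically.
#' @param C channels, 1 or 3.
#' @return object of class `canvas_spec`.
#' @export
canvas_spec <- function(Rx = 6L, Ry = 6L, Px = 20L, Py = 20L, C = 1L) {
  Rx <- as.integer(Rx); Ry <- as.integer(Ry)
  Px <- as.integer(Px); Py <- as.integer(Py); C <- as.integer(C)
  if (any(c(Rx, Ry, Px, Py) < 1L)) stop("canvas dimensions must be >= 1")
  if (!C %in% c(1L, 3L)) stop("C must be 1 or 3")
  structure(list(Rx = Rx, Ry = Ry, Px = Px, Py = Py, C = C,
                 width = Rx * Px, height = Ry * Py),
            class = "canvas_spec")
}

#' @export
print.canvas_spec <- function(x, ...) {
  cat(sprintf("<canvas_spec> %dx%d regions of %dx%d px -> %dx%d image, %d channel(s)\n",
              x$Rx, x$Ry, x$Px, x$Py, x$width, x$height, x$C))
  invisible(x)
}

#' Baseline region assignment
#'
#' The 6x6 canvas is split into four 3x3 quadrants, one per pattern kind:
#' oscillatory variation top-left, steady variation top-right, range maximum
#' bottom-left and range (max - min) bottom-right.  Within each quadrant the
#' rows are the sensor axes (sx, sy, sz top to bottom) and the columns the
#' window spans (u = two windows before, w = current, v = two windows after,
#' left to right).
#'
#' @param axes axis labels filling the quadrant rows (exactly 3).
#' @return data.frame of class `region_assignment` with one row per region:
#'   `row`, `col` (0-based canvas coordinates), `kind`, `axis`, `span`, and
#'   attribute `variant = "baseline"`.
#' @export
baseline_layout <- function(axes = c("sx", "sy", "sz")) {
  if (length(axes) != 3) stop("a quadrant holds exactly 3 axes")
  quads <- data.frame(
    kind = canvas_pattern_kinds(),
    row0 = c(0L, 0L, 3L, 3L),
    col0 = c(0L, 3L, 0L, 3L), stringsAsFactors = FALSE)
  spans <- c("u", "w", "v")
  rows <- list()
  for (q in seq_len(4)) {
    for (r in 0:2) {
      for (cc in 0:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          row = quads$row0[q] + r, col = quads$col0[q] + cc,
          kind = quads$kind[q], axis = axes[r + 1L], span = spans[cc + 1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$row, out$col), ]
  rownames(out) <- NULL
  structure(out, class = c("region_assignment", "data.frame"),
            variant = "baseline")
}

#' Names of the supported canvas-layout variants
#' @export
layout_variants <- function() {
  c("baseline", "bottom_top_switched", "flattened_quadrants",
    "left_right_switched", "tl_br_switched", "tr_bl_switched")
}

#' Layout variants: permutations of the baseline region contents
#'
#' Each variant re-places the 36 (kind, axis, span) region contents of the
#' baseline assignment without altering them: swapping the top and bottom
#' halves, the left and right halves, diagonal pairs of quadrants, or
#' flattening the four 3x3 quadrants into consecutive row-bands (quadrant
#' contents written row-major into the canvas row-major, in order top-left,
#' top-right, bottom-left, bottom-right).
#'
#' @param name one of [layout_variants()].
#' @param axes passed to [baseline_layout()].
#' @return a `region_assignment` with attribute `variant = name`.
#' @export
variant_layout <- function(name, axes = c("sx", "sy", "sz")) {
  base <- baseline_layout(axes)
  name <- match.arg(name, layout_variants())
  if (name == "baseline") return(base)
  out <- base
  if (name == "bottom_top_switched") {
    out$row <- (base$row + 3L) %% 6L
  } else if (name == "left_right_switched") {
    out$col <- (base$col + 3L) %% 6L
  } else if (name == "tl_br_switched") {
    tl <- base$row < 3 & base$col < 3
    br <- base$row >= 3 & base$col >= 3
    out$row[tl] <- base$row[tl] + 3L; out$col[tl] <- base$col[tl] + 3L
    out$row[br] <- base$row[br] - 3L; out$col[br] <- base$col[br] - 3L
  } else if (name == "tr_bl_switched") {
    tr <- base$row < 3 & base$col >= 3
    bl <- base$row >= 3 & base$col < 3
    out$row[tr] <- base$row[tr] + 3L; out$col[tr] <- base$col[tr] - 3L
    out$row[bl] <- base$row[bl] - 3L; out$col[bl] <- base$col[bl] + 3L
  } else if (name == "flattened_quadrants") {
    # order the 36 contents quadrant-major (TL, TR, BL, BR; row-major within
    # a quadrant) and pour them into the canvas row-major
    quad <- with(base, ifelse(row < 3, ifelse(col < 3, 1L, 2L),
                              ifelse(col < 3, 3L, 4L)))
    ord <- order(quad, base$row, base$col)
    pos <- seq_len(36) - 1L              # row-major target positions
    out <- base[ord, ]
    out$row <- pos %/% 6L
    out$col <- pos %% 6L
  }
  out <- out[order(out$row, out$col), ]
  rownames(out) <- NULL
  structure(out, class = c("region_assignment", "data.frame"), variant = name)
}

#' Look up a region's content
#'
#' @param layout a `region_assignment`.
#' @param row,col 0-based region coordinates.
#' @return one-row data.frame (`kind`, `axis`, `span`).
#' @export
region_content <- function(layout, row, col) {
  hit <- layout[layout$row == row & layout$col == col, c("kind", "axis", "span")]
  if (nrow(hit) != 1) stop("no unique region at (", row, ",", col, ")")
  hit
}

#' Augmented canvas for multiple sensors
#'
#' Tiles one per-sensor canvas per sensor into a larger image, row-major in
#' a `tiles_x`-wide grid; trailing empty slots stay all-unmarked.
#'
#' @param sensor_ids character vector (>= 1 sensor).
#' @param spec the shared per-tile [canvas_spec()].
#' @param tiles_x number of tiles per row (default: all in one strip).
#' @return object of class `augmented_canvas` with `sensor_ids`, `spec`,
#'   `tiles_x`, `tiles_y`, `width`, `height`.
#' @export
augmented_layout <- function(sensor_ids, spec = canvas_spec(),
                             tiles_x = length(sensor_ids)) {
  n <- length(sensor_ids)
  if (n < 1) stop("need at least one sensor")
  tiles_x <- as.integer(tiles_x)
  if (tiles_x < 1) stop("tiles_x must be >= 1")
  tiles_y <- as.integer(ceiling(n / tiles_x))
  structure(list(sensor_ids = sensor_ids, spec = spec,
                 tiles_x = tiles_x, tiles_y = tiles_y,
                 width = tiles_x * spec$width,
                 height = tiles_y * spec$height),
            class = "augmented_canvas")
}

# stable hash of a configuration list, embedded in image provenance
config_hash <- function(...) {
  txt <- paste(utils::capture.output(utils::str(list(...), digits.d = 12)),
               collapse = "\n")
  # small rolling hash; provenance only needs stability, not cryptography
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483647))
}
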