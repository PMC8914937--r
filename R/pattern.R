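#' Classify variation segments within a window
#'
#' Every interior sample of a window is classified by the triple it centres:
#' a strict local maximum or minimum marks an *oscillatory* context (the
#' signal goes up and down between consecutive steps), a strictly monotone
#' triple marks a *steady* context (the signal rises or falls consistently).
#' Triples containing a plateau (equal consecutive values) fall to the steady
#' class, which is the residual class: oscillation requires strict extrema.
#' Maximal runs of equal context are merged into segments; a segment spans
#' from the sample before its first interior point to the sample after its
#' last one, so every segment holds k >= 3 samples and adjacent segments of
#' different kind overlap by the two samples flanking the kind change
#' (inclusive boundaries).
#'
#' @param values numeric vector of window samples (length >= 3).
#' @return data.frame with columns `kind` ("oscillatory"/"steady"), `start`,
#'   `end` (1-based inclusive sample indices) and `k` (= end - start + 1),
#'   ordered by `start`.
#' @export
classify_segments <- function(values) {
  n <- length(values)
  if (n < 3) stop("need at least 3 data points to classify variation")
  # context of each interior point i = 2..n-1
  prev <- values[1:(n - 2)]
  cur  <- values[2:(n - 1)]
  nxt  <- values[3:n]
  osc <- (cur > prev & cur > nxt) | (cur < prev & cur < nxt)
  kind <- ifelse(osc, "oscillatory", "steady")
  r <- rle(kind)
  ends_i <- cumsum(r$lengths)          # indices into the interior vector
  starts_i <- ends_i - r$lengths + 1L
  # interior point j corresponds to sample j + 1; segment covers one sample
  # on each side of its run of interior points
  data.frame(kind = r$values,
             start = starts_i,        # (starts_i + 1) - 1
             end = ends_i + 2L,       # (ends_i + 1) + 1
             k = r$lengths + 2L,
             stringsAsFactors = FALSE)
}

#' Variation-pattern value of one segment kind
#'
#' The points of all segments of the requested kind are pooled by
#' concatenation (in segment order) and the value is the mean absolute
#' successive difference over the pooled sequence,
#' `vp = 1/(k-1) * sum |d_i - d_(i-1)|`.  When no segment of the kind
#' exists the value is 0.
#'
#' @param values the window samples the segments index into.
#' @param segments data.frame as returned by [classify_segments()], already
#'   filtered to one kind (rows of other kinds are ignored if a `kind` column
#'   names more than one).
#' @param kind which kind to pool when `segments` mixes kinds.
#' @return non-negative scalar.
#' @export
variation_value <- function(values, segments, kind = NULL) {
  if (!is.null(kind) && "kind" %in% names(segments)) {
    segments <- segments[segments$kind == kind, , drop = FALSE]
  }
  if (nrow(segments) == 0) return(0)
  pooled <- unlist(lapply(seq_len(nrow(segments)), function(i) {
    values[segments$start[i]:segments$end[i]]
  }), use.names = FALSE)
  mean(abs(diff(pooled)))
}

#' Range features of a window
#'
#' @param values numeric vector (non-empty).
#' @return list with `max`, `min` and `diff` (= max - min).
#' @export
range_features <- function(values) {
  if (length(values) == 0) stop("empty window")
  mx <- max(values)
  mn <- min(values)
  list(max = mx, min = mn, diff = mx - mn)
}

#' Extract the pattern vector of one window
#'
#' Composes [classify_segments()], [variation_value()] (once per kind) and
#' [range_features()] into the per-window summary used on the canvas.
#'
#' @param values numeric vector of window samples (length >= 3).
#' @return list of class `pattern_vector` with fields `vp_osc`, `vp_steady`,
#'   `range_max`, `range_min`, `range_diff`.
#' @export
extract_patterns <- function(values) {
  segs <- classify_segments(values)
  rf <- range_features(values)
  structure(
    list(vp_osc = variation_value(values, segs, "oscillatory"),
         vp_steady = variation_value(values, segs, "steady"),
         range_max = rf$max, range_min = rf$min, range_diff = rf$diff),
    class = "pattern_vector")
}

# canonical kinds placed on the canvas, in quadrant order
canvas_pattern_kinds <- function() c("osc", "steady", "range_max", "range_diff")

# pattern value of a window for one canvas kind
pattern_value_of_kind <- function(pv, kind) {
  switch(kind,
         osc = pv$vp_osc,
         steady = pv$vp_steady,
         range_max = pv$range_max,
         range_diff = pv$range_diff,
         range_min = pv$range_min,
         stop("unknown pattern kind: ", kind))
}

#' Pattern table of a window set
#'
#' Computes the pattern vector of every (window, axis) pair of a window set;
#' one row per window x axis x canvas pattern kind.  This long format feeds
#' both calibration ([calibrate_patterns()]) and rendering.
#'
#' @param ws a `window_set`.
#' @return data.frame with columns `window_index`, `axis`, `kind`, `value`,
#'   `label`.
#' @export
pattern_table <- function(ws) {
  kinds <- canvas_pattern_kinds()
  nw <- n_windows(ws)
  rows <- vector("list", nw * length(ws$axes))
  ri <- 0L
  for (w in seq_len(nw)) {
    for (ax in ws$axes) {
      pv <- extract_patterns(ws$values[, w, ax])
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        window_index = w, axis = ax, kind = kinds,
        value = vapply(kinds, function(k) pattern_value_of_kind(pv, k),
                       numeric(1)),
        label = ws$labels[w], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
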