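# Shared fixtures and independent oracles for the test suite.

# Brute-force segmentation oracle: label every interior point of the window
# by the strict local-extremum test, one point at a time, then merge equal
# runs into segments that include one sample on each side.  Deliberately a
# point-by-point loop, independent of the vectorised implementation.
oracle_segments <- function(values) {
  n <- length(values)
  kinds <- character(n - 2)
  for (i in 2:(n - 1)) {
    a <- values[i - 1]; b <- values[i]; d <- values[i + 1]
    is_max <- b > a && b > d
    is_min <- b < a && b < d
    kinds[i - 1] <- if (is_max || is_min) "oscillatory" else "steady"
  }
  segs <- list()
  run_start <- 1
  for (j in seq_len(n - 2)) {
    if (j == n - 2 || kinds[j + 1] != kinds[j]) {
      segs[[length(segs) + 1]] <- data.frame(
        kind = kinds[run_start], start = run_start, end = j + 2,
        k = j - run_start + 3, stringsAsFactors = FALSE)
      run_start <- j + 1
    }
  }
  do.call(rbind, segs)
}

# Oracle for the variation value: pool the points of all segments of a kind
# by concatenation and take the mean absolute successive difference.
oracle_vp <- function(values, segs, kind) {
  segs <- segs[segs$kind == kind, , drop = FALSE]
  if (nrow(segs) == 0) return(0)
  pts <- c()
  for (i in seq_len(nrow(segs))) pts <- c(pts, values[segs$start[i]:segs$end[i]])
  s <- 0
  for (i in 2:length(pts)) s <- s + abs(pts[i] - pts[i - 1])
  s / (length(pts) - 1)
}

# A small labelled window_set built directly from given per-window vectors.
make_window_set <- function(windows_by_axis, labels = NULL,
                            subject = "t1", sensor = "imu") {
  axes <- names(windows_by_axis)
  nw <- length(windows_by_axis[[1]])
  len <- length(windows_by_axis[[1]][[1]])
  vals <- array(NA_real_, dim = c(len, nw, length(axes)),
                dimnames = list(NULL, NULL, axes))
  for (a in seq_along(axes)) {
    for (w in seq_len(nw)) vals[, w, a] <- windows_by_axis[[a]][[w]]
  }
  if (is.null(labels)) labels <- rep("x", nw)
  structure(list(values = vals, labels = labels, axes = axes,
                 spec = window_spec(max(len, 5)), subject_id = subject,
                 sensor_id = sensor),
            class = "window_set")
}

# Tiny synthetic window_set with distinguishable windows, for render tests.
random_window_set <- function(n_win = 8, len = 32, axes = c("sx", "sy", "sz"),
                              seed = 42) {
  set.seed(seed)
  wba <- lapply(axes, function(a) {
    lapply(seq_len(n_win), function(w) cumsum(stats::rnorm(len)))
  })
  names(wba) <- axes
  make_window_set(wba, labels = rep(c("a", "b"), length.out = n_win))
}

# Per-region pixel block of an image, as a matrix list keyed "row,col"
region_blocks <- function(img, cspec) {
  out <- list()
  for (r in 0:(cspec$Ry - 1)) {
    for (cc in 0:(cspec$Rx - 1)) {
      out[[paste(r, cc, sep = ",")]] <-
        img$pixels[r * cspec$Py + seq_len(cspec$Py),
                   cc * cspec$Px + seq_len(cspec$Px), , drop = FALSE]
    }
  }
  out
}
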