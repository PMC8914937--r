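#' Construct a multivariate sensor stream
#'
#' A `sensor_stream` holds the synchronised samples of one inertial sensor
#' (accelerometer, gyroscope, ...) for one subject: one numeric column per
#' axis, a per-sample activity label, and the sampling rate.  Timestamps, when
#' present, are carried as metadata only; all downstream computation is
#' index-based.
#'
#' @param values numeric matrix, samples x axes; column names are the axis
#'   labels (e.g. `sx`, `sy`, `sz`).
#' @param labels character vector of per-sample activity labels, same length
#'   as `nrow(values)`.
#' @param sampling_rate sampling frequency in Hz (positive).
#' @param sensor_id,subject_id identifiers carried into image provenance.
#' @param timestamps optional numeric vector of acquisition times (metadata
#'   only).
#' @return an object of class `sensor_stream`.
#' @export
sensor_stream <- function(values, labels, sampling_rate = 1,
                          sensor_id = "imu", subject_id = "s1",
                          timestamps = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("axis values must be numeric")
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) {
    stop("labels must have one entry per sample")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a positive scalar")
  }
  if (!is.null(timestamps) && length(timestamps) != nrow(values)) {
    stop("timestamps must have one entry per sample")
  }
  structure(
    list(values = values, labels = labels, sampling_rate = sampling_rate,
         sensor_id = as.character(sensor_id),
         subject_id = as.character(subject_id), timestamps = timestamps),
    class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> sensor=%s subject=%s: %d samples x %d axes (%s) @ %g Hz\n",
              x$sensor_id, x$subject_id, nrow(x$values), ncol(x$values),
              paste(colnames(x$values), collapse = ","), x$sampling_rate))
  cat(sprintf("  labels: %s\n", paste(sort(unique(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Windowing specification
#'
#' Windows are non-overlapping by construction; only the window length is
#' tunable.  A window must hold at least 5 samples so that it can contain a
#' 3-point variation segment plus neighbours.
#'
#' @param length window length in samples (>= 5). Default 128, a common
#'   choice for body-worn sensors sampled at tens of Hz.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(length = 128L) {
  length <- as.integer(length)
  if (is.na(length) || length < 5L) stop("window length must be >= 5 samples")
  structure(list(length = length, overlap = 0L), class = "window_spec")
}

#' Load sensor streams from CSV
#'
#' Reads a plain CSV (header row, comma separated) holding one sample per row
#' and returns one [sensor_stream()] per (subject, sensor) group.  The schema
#' maps column names to roles; a sensor column is optional (a single sensor is
#' assumed when absent).
#'
#' @param path CSV file path.
#' @param schema named list with entries `timestamp`, `subject`, `label`,
#'   `axes` (character vector of >= 1 axis column names) and optionally
#'   `sensor`.
#' @param sampling_rate sampling rate recorded on the returned streams.
#' @return list of `sensor_stream` objects, ordered by subject then sensor.
#' @export
load_sensor_csv <- function(path, schema, sampling_rate = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  need <- c("timestamp", "subject", "label", "axes")
  if (!all(need %in% names(schema))) {
    stop("schema must name timestamp, subject, label and axes columns")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("empty input: ", path)
  cols <- c(schema$timestamp, schema$subject, schema$label, schema$axes,
            schema$sensor)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("schema error: column(s) not in file: ", paste(missing, collapse = ", "))
  }
  for (ax in schema$axes) {
    v <- df[[ax]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !anyNA(v)) stop("non-numeric values in axis column ", ax)
      if (anyNA(vn)) stop("non-numeric or missing values in axis column ", ax)
      df[[ax]] <- vn
    }
  }
  ts <- df[[schema$timestamp]]
  sensor_col <- if (!is.null(schema$sensor)) df[[schema$sensor]] else "imu"
  groups <- split(seq_len(nrow(df)),
                  list(subject = df[[schema$subject]], sensor = sensor_col),
                  drop = TRUE, lex.order = TRUE)
  lapply(groups, function(idx) {
    idx <- idx[order(seq_along(idx))]  # preserve file order within group
    tsg <- suppressWarnings(as.numeric(ts[idx]))
    if (!anyNA(tsg) && is.unsorted(tsg, strictly = FALSE)) {
      warning("non-monotone timestamps; sample order kept as in file")
    }
    sensor_stream(
      values = as.matrix(df[idx, schema$axes, drop = FALSE]),
      labels = as.character(df[idx, schema$label]),
      sampling_rate = sampling_rate,
      sensor_id = as.character(sensor_col[idx][1]),
      subject_id = as.character(df[idx, schema$subject][1]),
      timestamps = if (anyNA(tsg)) NULL else tsg)
  })
}

#' Cut a stream into non-overlapping labelled windows
#'
#' Produces `floor(N / length)` windows per axis; trailing samples that do not
#' fill a window are dropped.  Each window's label is the majority label of
#' its samples, ties broken by the lexicographically first label.
#'
#' @param stream a [sensor_stream()].
#' @param spec a [window_spec()].
#' @return an object of class `window_set` with elements `values` (array
#'   `length x n_windows x n_axes`), `labels`, `axes`, `spec`, `subject_id`,
#'   `sensor_id`.
#' @export
segment_windows <- function(stream, spec = window_spec()) {
  stopifnot(inherits(stream, "sensor_stream"), inherits(spec, "window_spec"))
  n <- nrow(stream$values)
  len <- spec$length
  n_win <- n %/% len
  if (n_win == 0) {
    warning("stream shorter than one window; no windows produced")
  }
  n_axes <- ncol(stream$values)
  vals <- array(NA_real_, dim = c(len, n_win, n_axes),
                dimnames = list(NULL, NULL, colnames(stream$values)))
  labels <- character(n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * len + 1):(w * len)
    vals[, w, ] <- stream$values[idx, , drop = FALSE]
    labels[w] <- majority_label(stream$labels[idx])
  }
  structure(
    list(values = vals, labels = labels, axes = colnames(stream$values),
         spec = spec, subject_id = stream$subject_id,
         sensor_id = stream$sensor_id),
    class = "window_set")
}

# majority with deterministic tie-break: lexicographically first label
majority_label <- function(labels) {
  tab <- table(labels)
  winners <- names(tab)[tab == max(tab)]
  sort(winners)[1]
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d samples x %d axes (subject=%s, sensor=%s)\n",
              n_windows(x), x$spec$length, length(x$axes), x$subject_id,
              x$sensor_id))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a `window_set`.
#' @export
n_windows <- function(ws) dim(ws$values)[2]

#' Extract one window's values
#'
#' @param ws a `window_set`.
#' @param index window index (1-based).
#' @param axis axis label or index.
#' @return numeric vector of the window's samples.
#' @export
window_values <- function(ws, index, axis) {
  ws$values[, index, axis]
}

#' Neighbourhood of a window: spans u (w-2, w-1), w (current), v (w+1, w+2)
#'
#' Out-of-range neighbours at the stream boundaries are returned as `NULL`
#' and flagged in `absent`; downstream they contribute pattern value 0.
#'
#' @param ws a `window_set`.
#' @param index current window (1-based).
#' @return object of class `window_neighborhood` with elements `u` (list of 2
#'   matrices `length x n_axes` or NULL), `w` (matrix), `v` (list of 2),
#'   `absent` (named logical for offsets -2,-1,+1,+2), `label`, `index`.
#' @export
neighborhood <- function(ws, index) {
  n <- n_windows(ws)
  if (index < 1 || index > n) stop("window index out of range")
  grab <- function(i) {
    if (i < 1 || i > n) return(NULL)
    m <- ws$values[, i, , drop = FALSE]
    dim(m) <- dim(m)[c(1, 3)]
    colnames(m) <- ws$axes
    m
  }
  offsets <- c(-2L, -1L, 1L, 2L)
  absent <- stats::setNames(index + offsets < 1 | index + offsets > n,
                            c("-2", "-1", "+1", "+2"))
  structure(
    list(u = list(grab(index - 2L), grab(index - 1L)),
         w = grab(index),
         v = list(grab(index + 1L), grab(index + 2L)),
         absent = absent, label = ws$labels[index], index = index,
         axes = ws$axes, subject_id = ws$subject_id, sensor_id = ws$sensor_id),
    class = "window_neighborhood")
}
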