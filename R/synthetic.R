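#' Synthetic activity class specification
#'
#' Each class is a parametric signal family per axis: a triangle-wave
#' oscillation (amplitude, period in samples), a linear drift, a base level
#' and additive Gaussian noise.  The triangle wave is used as the
#' oscillation primitive because its variation-pattern values have exact
#' closed forms (a period-2 triangle of amplitude a alternates +/- a, so the
#' mean absolute successive difference is exactly 2a; a pure drift of slope
#' b gives exactly |b|), which makes every pipeline stage testable against
#' analytic values.
#'
#' @param label class label.
#' @param osc_amplitude oscillation amplitude per axis (recycled over axes).
#' @param osc_period oscillation period in samples (>= 2), per axis.
#' @param drift_slope linear drift per sample, per axis.
#' @param base_level signal offset, per axis.
#' @param noise_sd Gaussian noise standard deviation (>= 0), per axis.
#' @param duration number of windows generated per subject for this class.
#' @return list of class `class_spec`.
#' @export
class_spec <- function(label, osc_amplitude = 1, osc_period = 2L,
                       drift_slope = 0, base_level = 0, noise_sd = 0,
                       duration = 25L) {
  if (any(osc_period < 2)) stop("osc_period must be >= 2 samples")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  structure(list(label = as.character(label),
                 osc_amplitude = osc_amplitude,
                 osc_period = osc_period, drift_slope = drift_slope,
                 base_level = base_level, noise_sd = noise_sd,
                 duration = as.integer(duration)),
            class = "class_spec")
}

#' Synthetic dataset specification
#'
#' @param classes list of [class_spec()]s (>= 2).
#' @param n_subjects subjects to simulate.
#' @param sampling_rate nominal Hz, recorded on the streams.
#' @param window_length samples per window (drives `duration`).
#' @param seed RNG seed; recorded in the manifest.
#' @param axes axis labels.
#' @return list of class `dataset_spec`.
#' @export
dataset_spec <- function(classes, n_subjects = 4L, sampling_rate = 32,
                         window_length = 128L, seed = 17L,
                         axes = c("sx", "sy", "sz")) {
  if (length(classes) < 2) stop("need >= 2 classes")
  structure(list(classes = classes, n_subjects = as.integer(n_subjects),
                 sampling_rate = sampling_rate,
                 window_length = as.integer(window_length),
                 seed = as.integer(seed), axes = axes),
            class = "dataset_spec")
}

# unit triangle wave, period 1, range [-1, 1]; tri(0) = -1 (trough)
triangle_wave <- function(phase) {
  4 * abs(phase - floor(phase + 0.5)) - 1
}

#' Generate one labelled synthetic stream
#'
#' Per axis: `base + slope * t + amplitude * triangle(t / period) + noise`,
#' with `t = 0, 1, ...` in samples; the label is constant.
#'
#' @param cspec a [class_spec()].
#' @param n_samples samples to generate (>= 1).
#' @param axes axis labels; per-axis parameters in `cspec` are recycled to
#'   this length.
#' @param subject_id,sampling_rate stream metadata.
#' @return a [sensor_stream()].
#' @export
generate_stream <- function(cspec, n_samples, axes = c("sx", "sy", "sz"),
                            subject_id = "s1", sampling_rate = 32) {
  n_axes <- length(axes)
  amp <- rep_len(cspec$osc_amplitude, n_axes)
  per <- rep_len(cspec$osc_period, n_axes)
  slope <- rep_len(cspec$drift_slope, n_axes)
  base <- rep_len(cspec$base_level, n_axes)
  sd <- rep_len(cspec$noise_sd, n_axes)
  t <- seq_len(n_samples) - 1
  vals <- vapply(seq_len(n_axes), function(a) {
    base[a] + slope[a] * t + amp[a] * triangle_wave(t / per[a]) +
      if (sd[a] > 0) stats::rnorm(n_samples, 0, sd[a]) else 0
  }, numeric(n_samples))
  colnames(vals) <- axes
  sensor_stream(vals, labels = rep(cspec$label, n_samples),
                sampling_rate = sampling_rate, subject_id = subject_id)
}

# closed-form pattern expectations of a noise-free class signal, per axis;
# exact for pure cases (no drift, or no oscillation), approximate otherwise
class_expectations <- function(cspec, window_length, n_axes = 3) {
  amp <- rep_len(cspec$osc_amplitude, n_axes)
  per <- rep_len(cspec$osc_period, n_axes)
  slope <- rep_len(cspec$drift_slope, n_axes)
  data.frame(
    axis_index = seq_len(n_axes),
    vp_osc_pure = ifelse(per == 2, 2 * amp, 0),
    vp_steady_pure = abs(slope),
    step = abs(slope) + ifelse(per == 2, 2 * amp, 4 * amp / per),
    range_diff = abs(slope) * (window_length - 1) +
      ifelse(amp > 0, 2 * amp, 0))
}

#' Generate a synthetic labelled dataset as CSV files
#'
#' Writes one CSV per subject in the loader schema (columns `t`, `subject`,
#' `label`, one per axis) plus a JSON manifest recording the specification,
#' the seed, and the closed-form per-class pattern expectations.  Each
#' subject performs every class in sequence (`duration` windows each).
#'
#' @param dspec a [dataset_spec()].
#' @param dir output directory (created).
#' @param shuffle_labels permute the label column (seeded); used to build
#'   permutation-null fixtures.
#' @return invisible list with `files`, `manifest_path`, `manifest`.
#' @export
generate_dataset <- function(dspec, dir, shuffle_labels = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(dspec$seed)
  files <- character(0)
  for (s in seq_len(dspec$n_subjects)) {
    subject <- sprintf("subj%02d", s)
    dfs <- lapply(dspec$classes, function(cs) {
      n <- cs$duration * dspec$window_length
      st <- generate_stream(cs, n, axes = dspec$axes, subject_id = subject,
                            sampling_rate = dspec$sampling_rate)
      cbind(data.frame(t = seq_len(n) - 1, subject = subject,
                       label = st$labels, stringsAsFactors = FALSE),
            as.data.frame(st$values))
    })
    df <- do.call(rbind, dfs)
    df$t <- (seq_len(nrow(df)) - 1) / dspec$sampling_rate
    if (shuffle_labels) df$label <- sample(df$label)
    path <- file.path(dir, paste0(subject, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    files <- c(files, path)
  }
  manifest <- list(
    seed = dspec$seed, n_subjects = dspec$n_subjects,
    sampling_rate = dspec$sampling_rate,
    window_length = dspec$window_length, axes = dspec$axes,
    shuffle_labels = shuffle_labels,
    classes = lapply(dspec$classes, function(cs) {
      c(unclass(cs),
        list(expected = class_expectations(cs, dspec$window_length,
                                           length(dspec$axes))))
    }),
    files = basename(files))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(files = files, manifest_path = manifest_path,
                 manifest = manifest))
}

#' CSV loader schema of the synthetic generator
#' @param axes axis labels.
#' @export
synthetic_schema <- function(axes = c("sx", "sy", "sz")) {
  list(timestamp = "t", subject = "subject", label = "label", axes = axes)
}

#' Benchmark fixture: four separable activity-like classes
#'
#' Four classes shaped like the broad activity families body-worn
#' accelerometers see: a near-still "stand" (tiny fast oscillation), a
#' moderate "walk" (unit-amplitude oscillation), a vigorous "jog" (large
#' fast oscillation), and a "stairs" class that pairs walk-like oscillation
#' with a slow drift.  Per-axis amplitude factors (1, 0.8, 0.6) mimic the
#' dominant-axis structure of real recordings.  The classes differ in
#' oscillation amplitude/frequency, drift slope and amplitude range, so
#' they are separable through the window patterns by construction; at the
#' default noise levels the class-conditional pattern distributions do not
#' overlap appreciably.
#'
#' @param windows_per_class windows generated per class per subject.
#' @param n_subjects subjects.
#' @param window_length samples per window.
#' @param seed RNG seed (default 17).
#' @return a [dataset_spec()].
#' @export
benchmark_fixture_spec <- function(windows_per_class = 100L,
                                   n_subjects = 4L, window_length = 128L,
                                   seed = 17L) {
  ax <- c(1, 0.8, 0.6)
  classes <- list(
    class_spec("stand_like", osc_amplitude = 0.05 * ax, osc_period = 2L,
               base_level = c(0.1, 0.1, 9.8), noise_sd = 0.02,
               duration = windows_per_class),
    class_spec("walk_like", osc_amplitude = 1.0 * ax, osc_period = 4L,
               base_level = c(0.5, 0.3, 9.0), noise_sd = 0.05,
               duration = windows_per_class),
    class_spec("jog_like", osc_amplitude = 3.0 * ax, osc_period = 2L,
               base_level = c(1.0, 0.5, 8.5), noise_sd = 0.1,
               duration = windows_per_class),
    class_spec("stairs_like", osc_amplitude = 1.0 * ax, osc_period = 4L,
               drift_slope = 0.02, base_level = c(0.2, 0.2, 9.2),
               noise_sd = 0.05, duration = windows_per_class))
  dataset_spec(classes, n_subjects = n_subjects,
               window_length = window_length, seed = seed)
}
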