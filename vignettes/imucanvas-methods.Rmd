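---
title: "Encoding inertial sensor windows as images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding inertial sensor windows as images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imucanvas)
```

## The idea

Human activity recognition (HAR) from body-worn inertial sensors usually
means feeding windowed accelerometer/gyroscope signals to a model whose
architecture carries most of the design effort. `imucanvas` takes the
opposite route: it moves the design effort into a deterministic,
training-free *image encoding* of each window, so that a deliberately plain
convolutional network suffices. The encoding is built to play to the two
classic strengths of CNNs — locality (a given pattern always appears in the
same image region) and edge detection (marked pixels form contiguous areas
with crisp boundaries).

The pipeline is:

1. cut each axis of the sensor stream into fixed-length, non-overlapping
   windows;
2. summarise every window by a handful of *patterns over time*;
3. map each pattern value linearly to a number of *marked pixels* inside a
   dedicated region of a canvas;
4. mark exactly that many pixels *consecutively* along a deterministic
   filling path, so the marked area has a continuous edge;
5. optionally use the RGB channels to encode neighbouring windows or
   additional sensors;
6. train the reference CNN on the resulting images.

## Patterns over time

Within one window, each interior sample is classified by the triple it
centres: a strict local maximum or minimum is *oscillatory* context (the
signal alternates step to step), a strictly monotone triple is *steady*
context (the signal rises or falls consistently). Maximal runs of equal
context become segments; a segment always includes the sample on each side
of its interior run, so every segment has at least `k = 3` samples and
adjacent segments of different kind overlap by the two samples flanking the
change. Triples containing a plateau (equal consecutive values) fall to the
steady class: oscillation requires strict extrema, and steady is the
residual class.

The *variation-pattern value* of a kind pools the points of all its
segments by concatenation and takes the mean absolute successive
difference,

$$vp = \frac{1}{k-1}\sum_{i=2}^{k} \lvert d_i - d_{i-1} \rvert ,$$

where $d_i$ are the pooled points. We use the *absolute* difference
deliberately: a signed telescoping sum would collapse to
$(d_k - d_1)/(k-1)$ and make every oscillatory value vanish, leaving the
pattern uninformative. Alongside the two variation values, each window
contributes its *range* features: maximum, minimum, and their difference.
The canvas places the oscillatory and steady values, the maximum and the
max−min difference; the minimum is carried in the pattern vector but has no
region of its own.

## Canvas, regions and layouts

The canvas is an `Rx x Ry` grid of regions of `Px x Py` pixels (defaults:
6×6 regions of 20×20 px, i.e. a 120×120 image). The 6×6 grid is divided
into four 3×3 *quadrants*, one per pattern kind: oscillatory top-left,
steady top-right, range-max bottom-left, range-diff bottom-right. Within a
quadrant, rows are the sensor axes (sx, sy, sz) and columns the *window
spans*: `u` (the two windows before the current one), `w` (the current
window), `v` (the two windows after). Span `u`/`v` values are the
arithmetic mean of their two windows' pattern values; windows missing at
the stream boundary contribute 0, so edge windows are kept (and flagged in
the image provenance) rather than discarded.

Five layout *variants* re-place the 36 region contents without altering
them: swapping the top/bottom halves, the left/right halves, either
diagonal quadrant pair, or "flattening" the quadrants — writing the four
3×3 blocks row-major into the canvas row-major, in order TL, TR, BL, BR.
Because a variant is a pure permutation, a variant image is a per-region
block permutation of the baseline image (exactly, under a uniform filling
schedule; under the alternating schedule the strategy at the new position
differs, but the marked-pixel count of every region is unchanged). This is
the basis of the layout-robustness check: classification accuracy should
barely move across variants.

For more than one sensor, up to three sensors can occupy the RGB channels
directly, and any number can be tiled side by side on an *augmented
canvas* (row-major, `tiles_x` wide, empty slots left unmarked). The tiling
width is a configuration parameter.

## From pattern values to pixels

Marked-pixel counts come from a linear calibration. For each (pattern
kind, axis), the minimum `minp` and maximum `maxp` pattern values are taken
over a calibration set — in practice the training portion of the data; a
per-window min/max of a single scalar would be degenerate. A value `pa` is
clamped to `[minp, maxp]` and mapped through

$$M(pa) = \left\lfloor \text{minpx} + (\text{maxpx} - \text{minpx})
  \frac{pa - \text{minp}}{\text{maxp} - \text{minp}} \right\rfloor ,$$

so `pa = minp` marks `minpx` pixels (default 0) and `pa = maxp` marks
`maxpx` (default the full region). Numerically, the ratio is formed
*before* multiplying by the pixel budget: multiplying first can round the
product just below a whole number and floor one pixel short at the upper
endpoint. A degenerate (flat) calibration maps everything to `minpx`.
Clamping, rather than erroring, on out-of-range test values keeps the count
within budget.

## Filling strategies

Pixels are marked consecutively along one of four deterministic paths, each
a permutation of the region's pixels (verified exhaustively in the tests
for all region sizes up to 12×12):

* **CCW** — a counterclockwise spiral growing outwards from the centre
  pixel (for even dimensions, the pixel just before the centre:
  0-based `(ceil(Py/2)-1, ceil(Px/2)-1)`), stepping up, left, down, right
  with increasing arm lengths. On even-sized regions the virtual spiral
  briefly leaves the region; out-of-bounds positions are skipped, which is
  the one place consecutive path pixels can fail to be 4-adjacent.
* **CW** — a clockwise spiral from the top-left corner inwards along the
  region boundary; always 4-adjacent.
* **Diag** — 45° anti-diagonals from the top-left corner, each drawn
  upwards (towards the top-right).
* **Strk** — continuous strokes across a row of three regions: reverse
  diagonals in the first, horizontal lines in the second, diagonals in the
  third. Lines are drawn left to right; after the first line, subsequent
  lines stack alternately above and below it. The first region starts at
  the top-left corner; later regions start next to the highest marked
  pixel in the previous region's last column (top-left if there is none),
  clamped to the region bounds, so strokes continue visually across region
  boundaries.

The default schedule alternates CCW and CW over the regions in row-major
order.

## Colouring

Three schemes share the same region geometry:

* **bw** — one channel; marked = 255, unmarked = 0.
* **simple_spans** — the `u`, `w` and `v` regions are rendered on the red,
  green and blue channel respectively; regions of the other spans stay
  unmarked on that channel.
* **neighbor** (default) — all three channels share the current window's
  marked/unmarked mask, and the *values* encode the neighbourhood. Per
  region, with `p'(k)` the region's pattern value in the image centred `k`
  windows away, scaled to `[0, 255]` with the same calibration bounds:
  marked red = `p'(-2)`, unmarked red = `255 - p'(-1)`; green uses `p'(0)`
  for both (marked = `p'`, unmarked = `255 - p'`); marked blue = `p'(+2)`,
  unmarked blue = `255 - p'(+1)`. The marked/unmarked value assignment on
  the blue channel mirrors the scheme's defining formulas literally, which
  pair the marked pixels with the farther window on both sides. `p'(k)`
  re-evaluates the region's span at the shifted centre, so a `u` region of
  the image two windows back reaches windows `w-4, w-3`; an exactly
  grayscale image therefore requires the nine windows `w-4 … w+4` to be
  identical, not five.

## The reference network

The classifier is intentionally minimal: two convolution blocks (128
filters of 3×3, ReLU, 2×2 max-pool with stride 2), a 256-unit dense ReLU
layer, and a softmax output, trained with cross-entropy, Adam and early
stopping on validation loss (best weights restored). No deep-learning
framework is involved: the network, its exact gradients and the Adam
update are implemented in the package with RcppArmadillo (im2col + GEMM
convolutions), which keeps training fully deterministic given a seed and
is cross-checked against finite-difference gradients in the test suite.

Hyper-parameters that the architecture does not fix are explicit
configuration with common defaults: batch size 32, at most 100 epochs,
learning rate 10^-3, patience 10, inputs scaled to [0, 1]. Evaluation
protocols are stratified: k-fold partitions (per-class counts across folds
differ by at most one, fold sizes balanced by rotating the per-class fold
cursor) and fraction splits (80/20 and 80/10/10), all seeded. When a split
provides no explicit validation part, a tenth of the training part is held
out for early-stopping monitoring; remainder items go first to parts a
positive fraction would otherwise leave empty, so small classes cannot
produce an empty validation part. Metrics are the standard per-class
one-vs-rest accuracy, precision, recall and F1, with a macro average as
the headline number (the synthetic classes are balanced, so macro and
micro agree closely).

## The synthetic generator

The generator exists so every stage is testable without external
downloads. Each class is `base + slope*t + amplitude * triangle(t/period)
+ N(0, sd)` per axis. The triangle wave (rather than a sine) is chosen so
pattern values have exact closed forms: a period-2 triangle of amplitude
`a` alternates ±a and gives an oscillatory variation value of exactly
`2a`; a pure drift of slope `b` gives a steady value of exactly `|b|`;
the noise-free range difference is `|b|(L-1) + 2a`. These closed forms are
frozen into oracle tests.

The benchmark fixture has four classes shaped like the broad families a
body-worn accelerometer sees — "stand" (amplitude 0.05, period 2),
"walk" (amplitude 1, period 4), "jog" (amplitude 3, period 2) and
"stairs" (walk-like oscillation plus drift 0.02/sample) — with per-axis
amplitude factors (1, 0.8, 0.6) and noise standard deviations of
0.02–0.1. The classes differ in oscillation amplitude/frequency, drift and
range, i.e. exactly the features the patterns capture, and their
pattern-value distributions do not overlap appreciably at these noise
levels, so near-perfect classification is expected *by construction*.
What passing tests show is therefore that the pipeline preserves the
information the patterns carry — not that the method reaches any
particular accuracy on real recordings, which have inter-subject
variability, non-stationary noise, and activities that are not separable
by these summaries alone.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on 320
windows (20 per class per subject, 4 subjects, seed 17) rendered at 4×4
pixels per region (24×24 canvases), and train with batch size 32, at most
40 epochs and patience 5. These sizes were chosen once as a compact
configuration that still gives a stable accuracy estimate; the encoding is
resolution-agnostic (the mapping is budget-relative), and the default
20×20 regions behave identically at larger cost. Other fixed choices:

* window length is a required configuration parameter (default 128
  samples, a common HAR convention); the encoding is length-agnostic;
* majority labels break ties by the lexicographically first label;
* timestamps are carried as metadata only — all computation is
  index-based;
* PNG output embeds provenance (window index, subject, sensor, layout
  variant, colouring, config hash, edge-window flag) in text chunks, so
  output bytes are stable for fixed input and seed.

## Known limitations

* The patterns are time-domain summaries; activities distinguished only by
  spectral content beyond oscillation rate/amplitude will not separate.
* Signals are taken as-is: no resampling, gravity removal or filtering.
* One canvas supports exactly three axes per sensor; more sensors go to
  RGB channels (≤3) or augmented tiles.
* The reference CNN is single-threaded CPU code; it is meant for the small
  images this encoding produces, not as a general deep-learning framework.
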