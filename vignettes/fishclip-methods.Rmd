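---
title: "Detecting fish events in stream surveillance video: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fish events in stream surveillance video: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishclip)
```

## The monitoring problem

Underwater IP cameras in small streams record continuously at a fixed frame
rate — typically 16 hours a day per camera during the season. Salmonids
pass the lens for seconds to minutes at a time; everything else is water,
bubbles, debris and light. The pipeline's job is data reduction with
bookkeeping good enough to go *back* from a classified still to the exact
frames of the source video: thin, score, group, pad, cut.

The stages hand off through plain CSV manifests. That separation is
deliberate: scoring can happen on another machine (or be replaced by a
stored score column entirely), and segmentation and reporting never need a
deep-learning stack.

## Frame arithmetic

All frame indices are 1-based. Thinning at interval $\Delta t$ from a video
with frame rate $f$ and $N$ frames anchors sample $i$ at the *first* frame
of its interval:

$$n_i = (i-1)\,s + 1, \quad s = \mathrm{round}(\Delta t f), \quad
i = 1, \dots, \lfloor (N-1)/s \rfloor + 1 .$$

Choices worth stating:

* **Interval anchor.** Different extraction toolchains disagree about
  whether a "frame every $\Delta t$ seconds" comes from the start, middle
  or end of each interval. fishclip fixes first-frame anchoring once, and
  both the thinner and the sample-to-frame mapper share the same formula,
  so the round trip still → frame is exact by construction rather than
  approximately consistent between two tools.
* **Non-integer strides.** $\Delta t f$ need not be integral
  (e.g. 29.97 fps). The stride is rounded to the nearest whole frame, which
  keeps frame numbers integral and strictly increasing at the cost of a
  sub-frame drift relative to true wall-clock spacing — irrelevant at the
  20 s scale the pipeline is used at.
* **Degenerate videos.** A video shorter than one interval yields exactly
  one sample (its first frame), never an error: an almost-empty recording
  is data, not a fault.

## The event algorithm

Given chronologically ordered scored samples, the algorithm is:

1. **Filter** — keep samples with $p \ge \tau$. The comparison is
   *inclusive*; with the default $\tau = 0.5$, a 50% score is kept. Missing
   scores (unreadable stills are recorded as `NA`, never dropped) count as
   below threshold, which conservatively breaks adjacency rather than
   fabricating continuity across a bad frame.
2. **Split by video file, then group** — within each video, maximal runs of
   consecutive sample indices become events. Runs never bridge files even
   when the last sample of one video and the first of the next are both
   positive: files are separate recordings and a cross-file "event" has no
   single source to cut from. `group_id` restarts per video.
3. **Buffer and clamp** — each event's frame span is padded by
   $\mathrm{round}(b f)$ frames on both sides and clamped to
   $[1, N]$. The buffer is specified in seconds (default 20 s) and
   converted through each video's own probed frame rate, so mixed-rate
   batches pad by equal *time*; at 20 fps this is the familiar 400 frames.
4. **Cut** — one clip per event. Buffered windows of nearby events may
   overlap; they are *not* merged by default. Each event is one observation
   for downstream identification work, and merging would silently conflate
   observations; the redundant overlapping footage costs only disk space.

Two invariants the test-suite enforces continuously: the grouping equals a
brute-force run-length encoding of the kept index sequence (checked against
an independently written oracle on a thousand random streams), and for all
events $1 \le \text{buffered start} \le \text{start} \le \text{end} \le
\text{buffered end} \le N$.

## Tunable parameters

| Parameter | Default | Unit | Why this default |
|---|---|---|---|
| `interval_s` | 20 | s | Long enough that successive stills differ (bubbles, debris and fish all move), keeping detection counts reviewable; short enough that a fish pausing in front of the lens spans at least one sample. Detection probability rises as the interval shrinks; change it mid-study only if the change is modelled downstream. |
| `threshold` | 0.5 | probability | The classifier's natural decision point. Raising it trades recall for clip quality. Inclusive comparison. |
| `buffer_s` | 20 | s | One thinning interval on each side: guarantees the clip contains the approach and departure around the sampled detection frames, where the sharpest identification views often are. |
| `review_min_percent` | 3 | % | Score streams are overwhelmingly zero-heavy; below a few percent the images that do contain fish are so poor they carry no identification value, and the review labour is better spent above the line. |

## The classifier contract

Everything downstream needs only "one probability in $[0,1]$ per sample,
order preserved". Four predictors satisfy it:

* **Deep backend** (`build_model(spec, backend = "keras")`): frozen
  Xception/ImageNet backbone, head of global average pooling → dense
  (ReLU) → dropout → dense(2, softmax), categorical cross-entropy, Adam.
  Hyper-parameters come from `classifier_spec()`; `grid_specs()`
  enumerates the 2×2×2 grid over learning rate {1e−2, 1e−3}, dropout
  {0.2, 0.3} and dense width {256, 1024} (batch size 32, 3 epochs), and
  `grid_search()` selects the best validation accuracy, ties to the
  earlier grid position. The stack is an *optional* dependency; without it
  the builder raises a classed capability error and nothing else breaks.
* **Feature GLM** (`backend = "features"`): the package-native trainable
  classifier — a binomial GLM on six pooled intensity features (mean, SD,
  90th/99th percentiles, bright-area fractions above 0.7 and 0.8). It
  exists so training, grid search, persistence (plain-JSON coefficients)
  and validation-accuracy reporting are real, fast and CPU-only. The
  deep-head parameters (`dense_units`, `dropout_rate`, `learning_rate`)
  have no GLM analogue; they are recorded in the report but inert. With
  collinear features (common on clean synthetic data, where the two
  bright-area fractions coincide) the GLM aliases a coefficient; aliased
  terms are dropped at persistence time since they carry no information.
* **Mock heuristic** (`mock_predictor()`): pure function of the pixels,
  $p = a/(a + a_0)$ with $a$ the fraction of pixels above intensity 0.8
  and $a_0 = 0.002$. Deterministic and dependency-free — the predictor
  used to exercise the full pipeline in tests.
* **CSV replay** (`csv_predictor()`): byte-exact pass-through of a stored
  score column, matched by image path when present, else by row order.

Training uses a seeded stratified 80/20 train/validation split (the split
ratio is a package choice; it is reported alongside the accuracy so it is
never ambiguous what the accuracy is measured on). Identical seed and data
give identical split membership; full cross-hardware determinism of deep
training is explicitly not promised. Labelled data follow the two-folder
layout `root/fish`, `root/no_fish`; the feature backend reads PNG (the
package's own still format).

## Reporting choices

Percent binning computes $\mathrm{round}(100p)$ with half values rounded
*away from zero*, documented because languages disagree on ties
(banker's rounding would send 3.5% to 4 but 4.5% to 4). The
floating-point representation of decimal inputs is first rounded at the
ninth decimal so that e.g. 0.035 — stored as 3.4999…×10⁻² — still lands on
its intended tie. The machine-readable table keeps all 101 bins so tables
from different runs align column-for-column; the printed rendering
compresses to nonzero rows. Dates default to the recording timestamp
parsed from each video's filename.

The packaged fixture `table1_fixture.csv` is a real six-day evaluation
table of 17,296 thinned-frame scores summarised this way; the suite checks
its marginals (grand total 17,296; bins 3 and 5 row-summing to 138 and 24)
and uses its expansion via `table_to_predictions()` to exercise the
review-queue arithmetic (311 stills at or above 3%).

## Media backends

Probing, extraction and cutting dispatch on container type:

* **Frame-stack** (`.tif` + JSON sidecar): a lossless multi-page TIFF, one
  page per frame, fps in the sidecar. Frame-accurate by construction —
  page *i* is frame *i* — with no codec in the loop. All synthetic footage
  and all written clips use it, and `write_segment()` on it is exact.
* **ffmpeg** (MP4/MKV/AVI …): shell-out to `ffprobe`/`ffmpeg` when the
  suite is on the `PATH`, with a classed capability error otherwise.
  Cutting defaults to re-encoding (frame-accurate `select` filter);
  stream-copy is offered as a fast option with documented keyframe
  snapping (clip length then accurate to about ±2 frames). When a
  container reports no frame count, it is reconstructed as
  duration × fps and flagged `frames_estimated`.

Chronological order across a batch comes from a configurable filename
timestamp pattern (compact and dashed `YYYYMMDD_HHMMSS` variants by
default), with full path as lexicographic tie-break so ordering is total
and deterministic even for stampless files.

## What the synthetic generator does and does not emulate

`render_video()` composites a moving high-contrast ellipse (the "fish")
over a Gaussian-noise background during configured time intervals;
`generate_probability_stream()` skips imaging entirely and emits scores —
planted above-threshold runs over Beta(1, 30) base noise capped below 0.5,
matching how heavily real score streams pile into the low percents. Ground
truth is stored at frame resolution, so the effect of the thinning
interval on detection (shorter interval, more detections) is directly
measurable. Both are fully seeded: same configuration, byte-identical
output.

What this buys: exact, known-answer testing of frame bookkeeping,
grouping, buffering, clamping and clip lengths, plus a classifier task
(`build_training_set()`) whose separability is *certified* by a
pixel-threshold oracle before any model is trained, and degradable at will
through `noise_level` (at 0.05 the mean-intensity oracle exceeds 95%
accuracy; around 0.45 it collapses toward chance — emulating white-water
footage).

What it does not buy: passing tests on synthetic scenes say nothing about
real-footage classifier accuracy — no blur, turbidity gradients, schooling
cyprinids, partial fish at frame edges, compression artefacts or exposure
changes are modelled. The pipeline's *plumbing* guarantees transfer to
real data; the classifier's skill does not, which is exactly why the score
table and review queue exist.

## Problem sizes in the shipped checks

The test-suite and acceptance script size their simulations for a single
CPU: grouping is verified against the brute-force oracle on 1000 random
streams of 5–40 samples across up to three videos; planted-run recovery on
100 random stream configurations; the end-to-end rendering check uses a
2-minute, 20 fps, 96×54 scene with three fish passes thinned at 2 s
(a 60× shorter interval and 40× smaller frame than field settings, with
identical arithmetic because every formula is parameterised by $f$,
$\Delta t$ and resolution); classifier checks use 100–200 images per
class. The full suite completes in about a minute.

## Known limitations

* No cross-camera fusion, tracking, or re-identification: one event is one
  run of positives in one video file.
* Event boundaries are quantised to the thinning interval; a fish present
  for less than one interval between samples is missed by design, and the
  buffer — not boundary refinement — is what recovers context around
  coarse detections.
* The feature-GLM backend is a contrast classifier; it is honest about
  being one, and murky high-noise footage defeats it (see above).
* Stream-copy cutting inherits keyframe geometry from the encoder;
  frame-exact work should use the default re-encode mode.
* JPEG labelled sets are not read by the feature backend (PNG only); the
  deep backend, where installed, reads whatever its image pipeline
  supports.
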