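---
title: "Composite waveform images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite waveform images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

ATP activates the ionotropic purinergic receptor P2X7 on neural stem cells
and triggers intracellular *calcium sparks*: frequent, high-amplitude,
fast-decaying calcium transients that are mechanistically distinct from the
slower calcium *waves* seen when P2X7 is blocked. Pretreating cultures with
neuroactive substances changes the shape of these spark waveforms in ways
that classical summary parameters — per-cell spike frequency and dynamic
range (max − min of ΔF/F) — do not detect: unpaired t tests between treated
and untreated groups come out non-significant, yet an image classifier
trained on rasterized waveform plots can separate the groups. The key
methodological device is the *composite image*: nine randomly chosen
same-group waveform images tiled 3 × 3 into one training example, which
dilutes per-cell variability and lets the learner focus on the shared,
subtle shape signal.

CaSparkML implements that entire computational arm as a tested, seeded
pipeline: trace simulation, movie segmentation and spike detection, waveform
rasterization, composite construction, classifier training/evaluation, and
the classical statistics it is benchmarked against.

# The synthetic benchmark

No public iNSC calcium-imaging recordings exist for this assay, so the
package ships a generator whose defaults *are* the study conditions it
emulates:

* **Recording geometry.** 300 s recordings sampled at 1 frame/s
  (`durationS = 300`, `frameIntervalS = 1`); movies default to 512 × 512 px.
  Pixel size is not stated in the source methodology; the default is
  1 µm/px and configurable.
* **Sparks.** A renewal train of spark events (`sparkRateHz`, default
  0.04 Hz, i.e. ~12 events per recording) with an 8 s refractory dead time
  between events and the exponential rate corrected so the expected count
  stays `sparkRateHz * durationS`. The dead time reflects the store-refill
  refractoriness of calcium-induced calcium release, and it keeps every
  event resolvable at 1 frame/s — a pure Poisson train would fuse ~10% of
  events into sampling coincidences whose detectability depends on spark
  kinetics, which would leak the treatment effect into the spike-frequency
  marginal that must stay matched. Templates are difference-of-exponentials
  with fast rise (`sparkRiseS = 0.6` s) and slower, "tapered" decay
  (`sparkDecayS = 2.5` s). Each spark is normalized so its *sampled*
  maximum equals the drawn amplitude: the amplitude parameter is defined on
  the recorded trace, which makes the dynamic-range distribution exactly
  invariant to kinetics (a continuous-time peak normalization would make
  broad peaks sample systematically closer to their true maximum than sharp
  ones, again leaking kinetics into a classical marginal).
* **Amplitudes.** Peak ΔF/F amplitudes are lognormal per event
  (`sparkAmpMu = log 1`, `sparkAmpSigma = 0.22`) times a mean-one lognormal
  per-cell multiplier (`cellAmpSigma = 0.22`), giving cell-to-cell
  dynamic-range spreads of roughly two-fold while keeping essentially all
  events well above the detection threshold (sub-threshold events would be
  lost at a rate that depends on waveform kinetics, biasing detected
  frequency between groups).
* **Waves.** A sparse half-sine component (`waveRateHz = 1/300`,
  `waveAmp = 0.25`, 60 s duration) models the slower metabotropic calcium
  waves present in the cultures.
* **Noise.** i.i.d. Gaussian sensor noise, `noiseSigma = 0.03` ΔF/F.
* **The treatment effect** (`effectKnob` ∈ [0, 1]) rescales the mean spark
  rise and decay constants (at full knob: rise × 3.4, decay × 1.15, see
  `effectMultipliers()`) — primarily a rise-asymmetry shift with a mild
  decay slowdown — and renormalizes the template peak. It never touches the
  event times or the amplitude draws, so the spike-frequency and
  dynamic-range marginals of the two groups are matched *by construction* —
  the simulated analogue of the observation that classical parameters do
  not separate the groups. A per-cell lognormal kinetics multiplier
  (`cellTauSigma = 0.15`) adds the biological heterogeneity that makes
  single-waveform classification imperfect.

The default benchmark (`defaultBenchmark()`) uses 800 traces per group and
`effectKnob = 0.6`. The knob value was calibrated once so that the
single-waveform classification arm reaches an average precision of roughly
0.8 — an operating point where single-image learning clearly works yet
leaves real room above it — after which the composite arm's advantage is an
emergent property, not a tuned one.
Several generator choices above (the dead time, the sampled-peak
normalization, the amplitude floor) exist to make the matched-marginal
constraint hold not just in the generative parameters but in the *measured*
statistics the t tests actually see; each is documented at its parameter.

What the generator does **not** emulate: biophysical channel kinetics
(P2X7 gating, CICR), photobleaching, cell motion, focus drift, or
correlated network activity between cells. Passing benchmarks therefore
demonstrate that the *pipeline logic* reproduces the methodology's
statistical structure, not that it would reach the same numbers on real
recordings.

# Movie processing

* **Preprocessing.** Linear contrast stretch between global intensity
  percentiles (the identity at (0, 100)), then per-frame spatial Gaussian
  smoothing — the equivalent of the contrast-enhance + smooth step usually
  done interactively before segmentation.
* **Hexagonal segmentation.** `hexTiling()` tiles the frame with flat-top
  regular hexagons of 20 µm across-corners diameter. "Diameter" is
  interpreted as the circumdiameter; the convention is recorded in the ROI
  map metadata. Pixels are assigned by exact axial-coordinate rounding,
  which reproduces the hexagonal Voronoi partition; hexagons touching the
  frame border are dropped. The lattice origin carries a ¼-pixel offset so
  no pixel centre lies exactly on a hexagon boundary — membership is then
  unambiguous and provably identical to a brute-force point-in-hexagon
  test.
* **Traces.** One waveform per ROI: the mean intensity of the ROI's pixels
  per frame, in raw fluorescence units so the noise model sees the original
  scale.

# Baseline, noise, spikes

* **Baseline F0**: median of a running 10th-percentile filter (60 s
  window).
* **Noise scale σ**: calcium transients only push fluorescence up, so the
  samples *below* the running 10th-percentile baseline are
  transient-insensitive. For Gaussian noise their mean square is a known
  truncated-normal multiple of σ²; inverting that constant gives an
  unbiased σ estimate that tolerates both sparks and slow waves.
* **Spike detection** ("smooth slow dynamic" style): convert to
  ΔF/F = (F − F0)/F0, subtract a slow baseline (centered running median,
  30 s), and mark local maxima exceeding `kSigma` × σ (default k = 4).
  Maxima closer than a 3 s refractory gap are merged, keeping the larger.
  All three constants are configuration keys.

A physical limit worth stating: at 1 s sampling, two Poisson events landing
within ~2 frames of each other fuse into a single local maximum and are
*not* separable by any threshold detector. At 0.05 Hz that costs about 1.3
of 15 events per trace in expectation. Detector-accuracy tests therefore
compare detected counts against *resolvable* ground-truth events (events
separated by at least the merge gap), which the detector recovers
essentially exactly; counts of all events are recovered up to that
coincidence loss.

# Rendering and composites

Waveform images use a **global fixed ΔF/F axis** (default [−0.5, 4]) rather
than per-trace autoscaling: the dynamic-range variability that breaks
single-image learning must remain visible in the rasters, and autoscaling
would erase it. (An autoscaled variant remains available as a config
switch for sensitivity checks.) No axes or decorations are drawn. The rasterizer is
device-free and deterministic: each pixel column is filled between the
min and max of the piecewise-linear trace over that column, so vertical
extent is an exact monotone image of amplitude. Values outside the axis are
clipped and the clipped fraction logged (warning above 1%). JPEG is the
interchange format at the I/O boundary (quality 90); all computation and
testing happens on the lossless raster.

Composites draw nine *distinct* members per image, uniformly without
replacement within a composite; waveforms may recur across composites
(default). That reading of the ambiguous "image-reuses are not considered"
is forced by arithmetic: ~1162 composites cannot be built from 1034
positive waveforms without cross-composite reuse. Tile order is a seeded
random permutation per composite to avoid positional artifacts. The
equal-count control (`equalCount = TRUE`) instead partitions the pool into
⌊pool/9⌋ disjoint composites so both arms consume the same number of
distinct waveforms.

# Classifier

Screening workflows of this kind often lean on opaque cloud image-ML
services that cannot be versioned, seeded or re-run offline; the package
instead uses a local classifier pinned to an explicit contract:
deterministic given a seed, ≥ 0.99 average precision on a linearly
separable toy set, and chance-level on label-shuffled data.
The default backend is a single-threaded, seeded probability random forest
(ranger) over deterministic raster features:

* a coarse block-mean-pooled pixel grid (16 × 32),
* per horizontal band (64 bands per waveform tile): ink fraction, stroke-run
  count, and mean stroke width (ink/runs) — because the y axis is globally
  fixed, bands correspond to fixed ΔF/F levels in every image, making these
  statistics comparable across images and invariant to where in time a
  spark occurred,
* pairwise differences of mean stroke widths across 12 coarse amplitude
  levels; for an exponential decay the stroke width at height *y* is
  τ·ln(a/y) (times the time scale), so width *differences* across heights
  estimate the decay constant τ free of the amplitude scale.

A composite raster is featurized as three stacked tile bands with the same
per-tile band layout, so its features are noise-reduced versions of the
single-image features — which is exactly the mechanism by which composite
training helps. The 90/10 split pools training and validation into one
`trainval` side (the forest needs no early-stopping holdout); evaluation
uses argmax predictions, per-class precision and recall, *average
precision* defined here — fixed, rather than left to a service's opaque
reporting — as the unweighted mean of the two class precisions, plus the
area under the positive-class precision–recall curve for transparency. Ties in argmax go to the negative
class; a never-predicted class gets precision 0 and a degenerate flag.
Voting segregation of an untrained substance predicts each image once and
reports the fraction assigned positive.

The trainval/test split is always drawn at the *waveform* level: in the
composite arm, training composites are built from the training pool and
test composites from the held-out pool, so no waveform appears on both
sides. (The member-disjoint design is forced by the null control —
with shared members a forest scores far above chance on test composites
even when the two groups are generated identically, by recognizing
memorized waveforms rather than reading the treatment effect.)

# Problem sizes and numerical choices

Benchmark experiments run at 800 traces/group with 128 × 224 px tiles and a
300-tree forest — sizes chosen so a full two-arm, ten-repeat comparison
runs on a single CPU in a coffee break while test-set precision estimates
stay stable to a few points. Composite rasters are featurized one at a time
and discarded (a full benchmark's composite rasters would otherwise occupy
gigabytes). The statistics null check uses 100 traces/group per seed across
50 seeds, the generator's own stated test condition for marginal matching.
Every random draw flows through explicit integer seeds derived from one
parent seed; there is no hidden global RNG state, and pipeline reports are
byte-reproducible from (config, seed).

Degenerate inputs are guarded rather than silently handled: σ = 0 on a
non-constant trace, empty movies, ROI sets that do not match the frame,
sub-3-pixel hexagons, pools smaller than nine, single-class training sets
and zero-reference reductions all raise typed errors.

# Known limitations

* The treatment effect is one interpretable kinetic shift; real compound
  effects are unknown mixtures, and nothing guarantees a real effect is
  visible to this feature set.
* The classifier is not convolutional; it sees engineered raster
  statistics. That is sufficient for the benchmark's shape signal and keeps
  the pipeline dependency-light and deterministic, but it is not a claim
  about CNN behaviour.
* Cell-lot dependence — in practice a model trained on one culture lot can
  fail on waveforms from another — has no analogue in the simulator (all
  traces share one parameter set per group).
* Hexagon segmentation assumes one cell-sized region per hexagon; there is
  no cell tracking or motion correction.
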