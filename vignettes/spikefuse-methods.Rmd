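---
title: "spikefuse: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spikefuse: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikefuse)
```

## The problem

spikefuse implements a fully event-driven pipeline for five-class
hand-gesture recognition from two complementary sensors: an 8-channel
surface-EMG armband (200 Hz, unitless unsigned 8-bit samples) and a
DVS-style event camera (asynchronous ON/OFF address events with
microsecond timestamps). Both modalities are converted to spikes, fed to
quantized spiking neural networks sized for small digital neuromorphic
processors, fused at the penultimate layer, and costed with an analytic
model of crossbar-core energy, latency and utilization. Recordings are 2 s
long, organised as subjects x sessions x repetitions x gestures and cut
into 200 ms chunks — the latency budget under which a prosthesis
controller must act.

## Spike encoding

**EMG — delta modulation.** Raw 8-bit values are normalized by the fixed
map $(v - 128)/128$ to $[-1, 1)$; the sensor is unitless, and the
threshold is only meaningful on a normalized scale (the raw-vs-normalized
choice is otherwise free and is documented rather than inferred). The
signal is linearly interpolated by a factor of 3500 (the 200 Hz sampling
leaves too few derivative crossings otherwise) and tracked by a reference
$r$: whenever $s - r \ge \delta$ an UP spike is emitted and
$r \leftarrow r + \delta$, symmetrically for DOWN. Defaults
$\delta = 0.05$, interpolation 3500. Two consequences we rely on in tests:

* reconstruction is exact by construction,
  $r(t) = x(0) + \delta\,(N_\mathrm{up}(t) - N_\mathrm{down}(t))$, and its
  error against the interpolated signal is bounded by $\delta$ plus one
  interpolated-step increment whenever the per-step increment is below
  $\delta$;
* a ramp covering a range $R$ emits exactly
  $\lfloor R/\delta \rfloor$ UP spikes. This requires the trigger to fire
  at $\ge \delta$ (not strictly above), which is the convention used, with
  a $10^{-12}$ tolerance against binary rounding.

The tracking reference is initialized from each chunk's first sample,
i.e. it resets per chunk; whether the original recordings reset it is
unstated, and the per-chunk choice keeps chunks independent.

**DVS.** Events are cropped to a 40x40 window centered on the
per-coordinate *median* of the event addresses (robust against uniform
background noise), clamped to lie in-sensor, and — for the crossbar MLP
path — partitioned into four 20x20 streams by pixel parity
$(x \bmod 2, y \bmod 2)$, one per core. ON/OFF polarities are kept as two
input channels for the CNN path and merged for the crossbar MLP path.
Spike times are binned on a 1 ms tick grid (one algorithmic tick).

## The neuron model

All networks use discrete-time current-based leaky integrate-and-fire
(CUBA-LIF) dynamics with fixed-point decay semantics:

$$ i_t = i_{t-1}\,\frac{4096 - d_i}{4096} + \textstyle\sum w\,s_{in},
\qquad v_t = v_{t-1}\,\frac{4096 - d_v}{4096} + i_t, $$

spike iff $v_t \ge \theta$, then $v \leftarrow 0$. The decay integers are
taken as ground truth (e.g. $d = 1024$ decays 1000 to exactly 750 in one
tick). Note that a decay parameter $d$ corresponds to a time constant of
roughly $4096/d$ ticks; the conventional parenthetical "milliseconds"
labels attached to such parameters elsewhere do not always match this
arithmetic, and the integers win here.

Two timing conventions are fixed package-wide and shared by the
simulator, the trainer, the batched engine and the test oracle: a dense or
convolutional stage adds **one tick of transport latency plus the integer
axonal delay** (0–63 ticks, 6-bit), while pooling (a logical OR of spike
indicators over 2x2 windows — the spike-domain analogue of max) and
flatten are instantaneous reshapes. Crossbar-chip neurons are modelled as
voltage-only LIF (full current decay); their richer on-chip behaviour
repertoires are out of scope.

The classification decision is the argmax of cumulative output spike
counts at stimulus end (plus optional extra integration ticks); ties break
toward the larger final membrane potential, then the lowest class index.
No readout rule is mandated by the hardware; this one is deterministic
and is the documented default.

## Quantization and training

Weight precision mirrors the target cores: signed 3-bit integers times a
per-layer scale (256-neuron single-core chip), binary $\{-1, +1\}$
(quad-core crossbar chip, with per-neuron integer thresholds), and 8-bit
with 6-bit delays (the large-scale research processor).

*Crossbar path.* A ReLU MLP is trained on per-chunk spike-count features
with straight-through-estimator quantization (full-precision shadow
weights receive Adam updates; the forward pass always uses the projected
weights, so every step is quantization-closed). No biases are used —
crossbar neurons carry thresholds, not biases. The trained weights are
installed unchanged in a perfect-integrator LIF network and per-layer
firing thresholds are selected by grid search: candidates are multiples of
the 99th percentile of positive ANN pre-activations divided by a nominal
spikes-per-chunk target; the candidate with the best validation accuracy
wins, near-ties resolving toward a target mean hidden firing rate. That
tie-break is what balances the EMG and DVS hidden-layer activities before
fusion (the DVS net is balanced toward the EMG net's rate).

*Spiking-domain path.* Surrogate-gradient backprop-through-time: the
forward pass runs the hard-threshold dynamics with quantized parameters,
the backward pass uses the shadows and replaces the spike derivative with
the exponential escape-rate form
$f'(v) = e^{-|v-\theta|/w}/(2w)$ (the principle is standard; the concrete
shape is a package choice, width $w$ configurable, default 0.5). The loss
is softmax cross-entropy on output spike counts — also a package choice,
as no loss is mandated. The backward pass is validated against finite
differences of a fully smoothed relaxation of the same dynamics (both
passes smooth), which it matches to $10^{-9}$; in spiking mode the same
formulas are evaluated along the spiking trajectory. Axonal delays train
on continuous shadows via the temporal-difference of the delayed input and
are rounded to integer ticks at each epoch end, clamped to $[0, 63]$.

*Fusion.* The penultimate spike outputs of the two single-modality
networks (230 + 4x210 = 1,070 wide on the crossbar path; 128 + 512 = 640
on the spiking-CNN path) feed a fresh 5-unit output layer. Only that head
is trained (on concatenated penultimate spike counts, STE-quantized);
upstream weights are frozen and verified bit-identical by hash. The head
threshold is selected in the count domain under the perfect-integrator
approximation — the full spiking fusion network is what is evaluated.

Training defaults (Adam, learning rate 0.01, batch 32, 30 epochs) follow
common practice; learning rate, batch size and split proportions are not
dictated by the modelled systems and are recorded in `train_config()`.

## Hardware cost model

For crossbar cores, every spike entering a core triggers one synaptic
operation (SOP) per neuron in the core; only the actual fan-out is useful
(e.g. 512 total / 210 useful per input spike on a 512-neuron core hosting
a 210-unit hidden layer, 512 / 5 for hidden spikes driving 5 outputs).
Power decomposes as $P = P_{leak} + P_{idle} f_{clk} + E_{SOP}\, r_{SOP}$;
the static terms default to zero since only dynamic figures are modelled,
and each SOP takes two clock cycles, capping $r_{SOP}$ at $f_{clk}/2$.
Processing time is set by the busiest core (cores run in parallel),
energy by the total SOP count, EDP is energy x time, and utilization is
the fraction of neuron resources taken by hidden plus output layers. In
fusion mode, hidden spikes can be remapped to the 5-unit fusion head as
single-SOP address events, avoiding the dummy-SOP overhead — the external
mapping table that implements this is excluded from the accounting, as in
the modelled system. The large-scale processor's energy and time are
treated as *measured inputs* (the package stores them and computes EDP);
no analytic model is attempted, and compiler-dependent core placement is
likewise out of scope.

## The synthetic world

The generator emulates the *structure* and qualitative statistics of the
benchmark recordings, not their values:

* **EMG**: per-gesture 8-channel activation profiles (Gaussian bumps over
  the electrode ring, width 2.5 channels — neighbouring gestures share
  most active channels) amplitude-modulating Gaussian noise, a 150 ms
  activation ramp, rest noise, 8-bit quantization. Per-subject electrode
  gains (U(0.85, 1.15)) and, critically, a per-session armband rotation
  (U(-1.5, 1.5) channels): the armband is re-donned every session, and
  with session-held-out cross-validation this makes EMG the weaker
  modality, reproducing the benchmark's qualitative ordering
  (EMG well below vision, fusion at or above vision).
* **DVS**: per-gesture hand-edge templates (palm outline plus the
  distinguishing extended fingers) under a rigid piecewise-linear jitter
  path, event polarity following the motion sign with 10% flips, 4 kHz
  template event rate plus 300 Hz uniform background noise.
* a scalar `difficulty` mixes profiles and templates toward a common
  average; nearest-neighbour separability decreases monotonically in it.

What a green test does **not** establish: absolute accuracies comparable
to the measured benchmark (real EMG nonstationarity, real hand shapes,
sensor noise statistics and cross-subject anatomy are all absent), only
that the pipeline end-to-end learns, fuses and evaluates as specified.
Headline accuracies of the measured benchmark are therefore not
acceptance-checked; desk-scale acceptance rests on the analytic
architecture/cost reproductions and the property suites.

## Numerical and interface choices

* Chunk windows are half-open, `[200k, 200(k+1))` ms (event timestamps)
  and the matching sample-index ranges (EMG), so joints are never counted
  twice; chunk indices are 0-based.
* Coordinates are 0-based, x = column, y = row, origin top-left.
* CSV interchange formats carry a one-line header (`width,height` for
  events, the rate for EMG); network specs serialize to JSON with inline
  weights. No binary containers are used.
* The frame-based baseline camera runs at 20 fps, so the first frame
  arrives 50 ms into the stimulus and the baseline returns *no
  prediction* below one frame period. (A 20 fps rate is sometimes quoted
  alongside a 25 ms first-classification time; these are inconsistent,
  and the 20 fps figure — 50 ms — is used.)
* Evaluation folds are split by session (each fold holds out whole
  sessions across all subjects); whether the reference protocol split by
  session or at random is unstated, and session splitting is both harder
  and closer to deployment.
* Degenerate inputs: a single-sample recording encodes to empty spike
  trains (no derivative — not an error); an empty event stream crops to
  an empty window at the sensor center; an all-silent network classifies
  via the deterministic tie-break (class 1).

## Known limitations

* The crossbar-path ANN is trained on spike-count features (a rate-coding
  assumption); temporal structure within a chunk is only exploited by the
  spiking-domain path.
* The surrogate trainer supports dense topologies (the spiking CNN is
  simulated but trained networks of conv layers are out of the trainer's
  scope at this scale on CPU).
* Vendor binary formats (.aedat, Bluetooth packets) are not parsed; the
  CSV/JSON interchange formats are the on-disk surface.
* On-chip online learning (spike-driven plasticity) is not modelled.
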