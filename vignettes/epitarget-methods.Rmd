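---
title: "Methods: from intracranial EEG to a neuromodulation target"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from intracranial EEG to a neuromodulation target}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitarget)
```

# The problem

In drug-resistant epilepsy, a third of surgical patients do not become
seizure-free, and the resected tissue can no longer be re-examined.
Neuromodulation (TMS, focused ultrasound, implanted stimulators) offers a
second chance, but only if a good *target* can be named.  `epitarget`
implements a computational localization strategy: infer a directed
functional network from interictal intracranial EEG (iEEG), place that
network inside a stochastic bistable neural-mass model in which every
channel is a node that can "escape" from a quiescent state into a
seizure-like oscillation, and rank channels by how strongly raising their
excitability accelerates the escape of the whole network.  The channel
with the greatest leverage is the proposed neuromodulation target.

This vignette records the modelling choices, the tunable parameters, what
the synthetic data generator does and does not emulate, and the numerical
conventions — the things a maintainer would want to know before trusting
or changing a default.

# Stage 1: the directed epileptic network

## Segmentation and MVAR fitting

Recordings (500 Hz in all bundled generators) are cut into 1 s windows
overlapping by 0.5 s; a 10 s recording yields 19 segments.  Each segment
is modelled as a multichannel autoregressive (MVAR) process

$$x(t) = \sum_{j=1}^{p} A_j\, x(t-j) + w(t),$$

with the order $p$ chosen per segment by Akaike's Final Prediction Error
over $1..20$ (ties toward the smaller order).  The coefficients solve the
Yule–Walker normal equations built from biased lagged covariances; the
multichannel Levinson recursion produces the solution at *every* candidate
order in one pass, which is what makes the 200-surrogate null
distributions affordable.  Coefficients are stored in regression form, so
the lag-2 entry $(2,1)$ fitted on the five-node benchmark process is
directly comparable to its printed value 0.5.

## The estimators

Nine estimators can populate the adjacency matrix; all produce
nonnegative weights with a zero diagonal (row = receiver, column =
sender for the directed ones):

* **DTF** — from $H(f) = (I - \sum_j A_j e^{-i2\pi f j/f_s})^{-1}$,
  $r^2_{ij}(f) = |H_{ij}|^2 / \sum_r |H_{ir}|^2$.  Rows sum to one at
  every frequency (tested at 1e-10); values lie in $[0,1]$.
* **PDC** — column-normalized coefficient spectrum
  $|\bar A_{ij}| / \sqrt{\sum_k |\bar A_{kj}|^2}$, the standard
  sender-normalized definition.
* **iCoh** — the isolated-pathway variant: all causal entries except the
  direct link under test and the autoregressive self terms are zeroed
  before a PDC-type ratio weighted by inverse noise variances.  Because
  zeroing leaves the $(i,j)$ and $(j,j)$ coefficient entries unchanged,
  the ratio needs no matrix inversion, and indirect chains (1→4→5 in the
  benchmark process) contribute essentially nothing.
* **PCC** — absolute Pearson correlation per segment (magnitudes, so the
  undirected matrix is comparable with the nonnegative directed ones).
* **wPLI** — from the analytic signal after zero-phase Butterworth
  band-filtering: $|\langle \mathrm{Im}\,S_{12}\rangle| / \langle
  |\mathrm{Im}\,S_{12}|\rangle$; identically zero imaginary cross-terms
  (zero-lag copies) define a wPLI of 0 rather than 0/0.
* **KLDIV** — Kullback–Leibler divergence between normalized short-time
  spectrograms (1 s windows, 50% overlap); reference cells are floored at
  $10^{-12}$ to keep the sum finite.  Asymmetric by construction.

Spectral estimators are averaged over an inclusive integer-Hz grid across
the analysis band — the default is the gamma band, 31–80 Hz, where
network properties track surgical outcome — and per-segment matrices are
averaged arithmetically.  PCC and KLDIV are broadband: the band concept
does not apply to a time-domain correlation or a whole-spectrogram
divergence.

## Surrogate analysis and sparsification

The `-SA` variants threshold each edge against phase-randomization
surrogates: 200 surrogate recordings per analysis, each preserving every
channel's amplitude spectrum exactly (Hermitian-symmetric phase
assignment) while destroying cross-channel structure, each run through
the identical segmentation/fitting/band-averaging pipeline.  An edge
survives if it exceeds the 95th percentile of its own null distribution;
of the survivors, only the strongest 5% of all possible edges
($\lceil 0.05\,N(N-1)\rceil$, halved for undirected methods) are kept.
Two readings were possible for the order of the two rules; significance
is applied first and the budget second, so nothing insignificant can
enter on strength alone.  When fewer edges survive than the budget
allows, all survivors are kept and a warning is logged.

At $N = 5$ the 5% budget is a single edge, which makes the `-SA`
benchmark correlations structurally low on the five-node process (a
one-edge matrix cannot correlate above ~0.53 with a five-edge truth); the
budget only becomes a mild constraint at clinical channel counts.  The
benchmark reports this honestly rather than special-casing small
networks.

# Stage 2: the bistable network model

Each channel becomes a complex normal-form oscillator

$$\frac{dz}{dt} = \bigl(a|z|^4 + b|z|^2 + \lambda - 1 + i\omega\bigr) z,
\qquad a = -1,\; b = 2,$$

which for $0 < \lambda < 1$ has a stable fixed point at the origin
(quiescence), a stable limit cycle at $r = \sqrt{1+\sqrt\lambda}$
(seizure-like oscillation) and an unstable cycle at
$r = \sqrt{1-\sqrt\lambda}$ separating them.  $\lambda$ is the
excitability: as it grows the barrier shrinks.  Nodes are coupled
diffusively through $\beta \sum_j K G_{ij}(z_j - z_i)$ with
$\beta = 0.02$, $K = 1000$ and $G$ the max-normalized connectivity
matrix; noise drives the escape.

Integration is fixed-step Euler–Maruyama with $dt = 0.05$ from
$z_i(0)=0$, with trajectories censored at `t_max = 500` model-time units
and a divergence guard at $|z| > 10$ (flagged, never fatal).  The C++
core uses a seed-reproducible xoshiro256++ stream per realization, shared
across perturbation conditions at equal realization index (common random
numbers), so differences between conditions are not drowned in
realization noise — an exactly zero perturbation yields exactly zero
$\Delta T$.

## Numerical conventions that matter

* **Noise convention.**  The noise moments (mean 0.0003, sd 0.05) are
  applied per integration step on the real and imaginary parts
  independently, scaled by $\alpha$ (default 1).  Under the alternative
  per-unit-time reading (increments scaled by $\sqrt{dt}$) the stationary
  radial fluctuation stays below ~0.05 for $\lambda \le 0.5$ while the
  escape barrier radius exceeds 0.54 — more than ten standard deviations
  — so escapes would essentially never occur in the lower half of the
  excitability range and the documented monotone dependence of escape
  time on $\lambda$ would be unobservable.  The per-step convention is
  the one under which the model behaves as described.
* **Oscillation frequency.**  Explicit Euler applied to the rotation
  $\dot z = i\omega z$ inflates the radius by $\sqrt{1+(\omega\,dt)^2}$
  per step, an artificial growth of $\approx \omega^2 dt/2$ per unit
  time.  At $\omega = 20$ and $dt = 0.05$ that is +10 per unit time,
  which would swamp the basin contraction entirely; the default is
  $\omega = 1$ ($\omega\,dt = 0.05$), configurable, and $\omega$ has no
  effect on the radial escape physics it leaves intact.
* **Escape detector.**  A node escapes when $|z| \ge 1$, a radius that
  lies strictly between the unstable and stable cycle radii for every
  $\lambda \in (0,1)$, so a crossing implies commitment to the
  oscillatory attractor rather than a noise excursion.
* **Network escape time.**  The network-level $T_{es}$ is the *mean* of
  per-node escape times, censored values entering at `t_max`.  Under a
  first-crossing rule a perturbed node's escape time would be independent
  of its out-coupling, and the perturbation map could not distinguish a
  hub from an isolated node — the mean is the weakest aggregate through
  which a node's downstream influence is visible.  The first-crossing
  time is still computed and reported by `escape_times()`.

# Stage 3: perturbation map, grid search, validation

With all nodes at baseline excitability $\lambda_0$ the network escape
time is $T_0$.  Raising one node to $\lambda_1$ gives $T_1(k)$, and
$\Delta T(k) = T_0 - T_1(k)$ measures that node's leverage: a hub whose
excitation drags its receivers over the barrier produces a much larger
$\Delta T$ than a leaf, and a node that is itself strongly slaved to a
quiescent driver produces almost none.  The target is the argmax
(exact ties break toward the lexicographically smallest label, with a
warning — ties occur only between structurally identical nodes under
common random numbers).

The operating pair $(\lambda_0, \lambda_1)$ is chosen by scanning
$\lambda_0 \in \{0.05, 0.05, 0.10, ..., 0.50\}$ (a baseline of zero is
clamped to 0.05: the model requires positive excitability, and the grid
deliberately keeps its 11 entries) against
$\lambda_1 \in \{0.50, ..., 1.00\}$ and maximizing the across-node
standard deviation of $\Delta T$ — the most discriminative operating
point.  Note that because $\Delta T(k)$ scales with
$T(\lambda_0) - T(\lambda_1)$, this criterion inherently favours small
$\lambda_0$ and large $\lambda_1$ on sparse networks; on the five-node
benchmark the selected $\lambda_1$ sits at ~0.85 while $\lambda_0$ lands
at the bottom of its grid.  Baseline samples are computed once per
$\lambda_0$ and shared across the row.

Virtual resection drops the channels flagged as resected *before*
network construction — connectivity is re-estimated on the surviving
channels, giving a genuinely smaller network — and re-runs the
localization at the fixed pair $(\lambda_0, \lambda_1) = (0.22, 1.0)$.

Validation reverses the sign of the intervention: clamping one node to
$\lambda_{\text{inhib}} = 0.01$ (near-maximal stability; the value is a
package choice, exposed as a parameter) while the rest sit at
$\lambda_0$, and asking whether inhibiting the *localized* target delays
network escape more than inhibiting anyone else.  Escape samples are
min–max normalized per network and compared by a two-sided Wilcoxon
rank-sum test (target stimulation vs pooled non-target stimulation);
p-values are reported per network rather than pooled across networks of
different sizes.

# The synthetic data generators

`simulate_mvar5()` reproduces the printed five-node validation process:
X1 is a resonant AR(2) source (root modulus 0.95, resonance ≈ 83 Hz at
500 Hz — just above the gamma band edge, so its gamma-band skirt carries
the directed signal), X2–X4 are driven by X1 at lags 2–3, X4/X5 form a
weakly coupled bidirectional pair.  Innovations are i.i.d. standard
Gaussian (the innovation scale is not printed anywhere; 1.0 is the
package default and benchmark conclusions were checked at that value),
and 500 burn-in samples are discarded.  The stored ground truth holds
coupling *magnitudes*, because every estimator under comparison returns
nonnegative strengths; estimator diagonals are excluded from all
comparisons.

`generate_synthetic_ieeg()` plants a hub in an otherwise uncoupled
N-channel MVAR process: the hub gets a strong gamma-band AR(2) resonance
and drives at least three receivers with lagged coefficients of magnitude
0.3–0.6; all other channels carry independent mild resonances.  Unstable
draws (companion spectral radius ≥ 0.97) are resampled a bounded number
of times.  This emulates the *statistical* structure the pipeline relies
on — a directed gamma-band outflow from one channel — and deliberately
nothing else: no volume conduction or common reference artifacts, no
nonstationarity, no line noise, no spatial correlation among electrodes.
Passing the recovery tests therefore shows the chain
"directed coupling → estimated network → escape-time leverage → target"
is faithful, not that the estimators are robust to the confounds of
clinical recordings.

`generate_electrode_layout()` places contacts on a 10 mm grid with a
seeded label permutation, enough to exercise distance-to-resection
reporting; it makes no anatomical claims.

# Problem sizes and limitations

The bundled tests and the acceptance script run the five-node benchmark
at 10 s × 500 Hz with 200 surrogates, grid searches at 50 realizations
per condition and perturbation maps at 100 realizations — sizes at which
every stage's behaviour is already stable and a full run completes on a
single CPU in tens of minutes.  Larger realization counts shrink the
Monte-Carlo error of $T_0$ like $1/\sqrt{n}$ (tested).

Known limitations: recordings are read from headered CSV (no EDF reader
is bundled); the model inherits the fixed-step solver of its source, so
stiff coupling (rows of $\beta K G$ summing far beyond $2/dt$) can make
single realizations diverge — such realizations are flagged and dropped;
and escape-time censoring at `t_max` biases $T_0$ downward in deeply
subcritical regimes, which is why censoring fractions are carried through
every report.
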