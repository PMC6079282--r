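---
title: "Methods: model, fitness, optimization and subtype analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, fitness, optimization and subtype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`neurofit`: the biophysical model and its assumptions, the fitness
function, the optimizer, the synthetic-data generator used for
validation, and the post-hoc statistics. It states no result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The biophysical model

A neuron is a tree of compartments (a spherical soma plus cylinders) with
membrane dynamics per compartment

$$C_m \frac{dV_i}{dt} = -\frac{V_i - E_{leak}}{R_m/a_i}
  - \sum_c \bar g_c a_i \prod_g x_g^{p_g} (V_i - E_c)
  + \sum_{j \sim i} g_{ij} (V_j - V_i) + I_{inj}(t),$$

where $a_i$ is the compartment surface area (sphere $\pi d^2$, cylinder
$\pi d L$; no spine correction), $\bar g_c$ a maximal conductance density
in S/m², and $g_{ij}$ the axial coupling computed from half-cylinder
resistances $R_A (L/2)/(\pi r^2)$ (a spherical soma uses its diameter as
effective length). Gating variables follow
$dx/dt = (x_\infty(V) - x)/\tau_x(V)$ in one of three forms: explicit
$\alpha/\beta$ rates in the five-parameter form
$(A + B V)/(C + e^{(V+D)/F})$, direct `tau-inf` specifications (the same
functional form evaluating $x_\infty$ and $\tau$), or calcium-dependent
Hill activation $x_\infty = [Ca]^n/([Ca]^n + K^n)$ for BK-type channels.
Each compartment can carry one calcium pool,
$d[Ca]/dt = -([Ca] - Ca_0)/\tau_{Ca} - B_{Ca} I_{Ca}$, with $B_{Ca}$
folding shell volume and the Faraday constant into one constant
(mM/(A·s)); calcium-channel reversal follows the Nernst potential
$\frac{RT}{2F}\ln([Ca]_{out}/[Ca]_i)$ at 305 K.

Assumptions: channel kinetics are fixed (only densities and passive
properties are tuned — adjusting half-activations or time constants is a
known limitation of this approach); no spines, synapses, or calcium
buffers/pumps/diffusion beyond the single-exponential pool; no
temperature corrections. Everything is SI internally (V, s, A, S/m²,
F/m², Ω·m², Ω·m, mM); morphology files in µm are converted at parse time.

Regions: appending `_0`, `_1` or `_2` to a channel name in a parameter
map restricts it to soma, proximal or distal dendrite. Region 0 is the
root segment; region 1 covers segments whose midpoint path distance (from
the soma surface, along the tree) is at most the first threshold (default
60 µm, configurable); region 2 is everything beyond. The second threshold
is carried in the model document for future finer splits but does not
enter the default rule — published morphology splits vary by cell type
and no canonical value exists, so the split is deliberately configurable.

## Numerical integration

The voltage step is implicit (backward Euler) with channel conductances
frozen within the step, solved on the compartment tree by Hines
elimination (exact for trees, $O(n)$ per step). Gates use the
exponential integrator $x \leftarrow x_\infty + (x - x_\infty)
e^{-\Delta t/\tau}$ evaluated at the just-computed voltage; the calcium
pool uses the exact exponential update toward its current-dependent fixed
point. Defaults: `dt` = 10 µs (a warning above 100 µs), `record_dt` =
100 µs. Gate steady states and decay factors for voltage-dependent gates
are tabulated on a 0.1 mV grid over [−200, 150] mV with linear
interpolation, the standard device in compartmental simulators; the
removable singularity of the rate form (vanishing denominator) is guarded
by linear interpolation from V ± 10 µV.

Accuracy is pinned by oracles rather than asserted: the passive response
matches the RC closed form (steady state and the 63.2 % point within 1 %);
steady states on random passive trees of up to 50 segments match a dense
linear solve of the full conductance matrix to 10⁻⁹ V; halving `dt`
changes subthreshold traces by less than 0.1 mV; for spiking traces, where
millisecond spike-time jitter makes pointwise voltage bounds meaningless
for any integrator, spike counts are compared against a 16-fold finer
integration instead.

## The fitness function

Each trace is reduced to features. Spike threshold is the first point on
the upstroke where dV/dt (central differences) exceeds 5 % of that
upstroke's maximum — the "maximum" is taken per spike, which makes the
rule robust to trains whose largest spike differs from the rest. Height
is peak minus threshold; width is full width at half height with linear
interpolation on both flanks. The AHP window runs from each peak to the
next spike's threshold or 20 ms; its shape, like the charging curve from
depolarization onset to the first threshold crossing, is resampled at 20
evenly spaced points so traces of different durations compare pointwise.
The histogram feature is the occupancy histogram of Vm during injection
over 64 bins spanning [−100, +50] mV; it is one reasonable reading of an
otherwise underdetermined feature name and is isolated behind the
feature-vector contract. Features undefined for a trace polarity (sag on
a depolarizing step) or content (AHP without spikes) are absent, never
zero-filled, and the fitness layer skips them.

Model/data differences are normalized by the sum of magnitudes,
$f = |m - d|/(|m| + |d|)$ (absolute values, because membrane potentials
are negative and a signed sum can vanish); vector features average the
pointwise values, histograms use half the L1 distance, per-spike features
pair the first $\min(n_{sim}, n_{data})$ spikes, and spike count uses the
normalized count difference. The combined fitness is the weighted RMS
$\sqrt{(1/N)\sum w_i f_i^2}$ over the $N$ features with positive weight.
RMS, not a plain weighted sum, is the combination pinned by the published
per-feature/total tables shipped in `inst/extdata/`: the six striatal
totals are reproduced within ±0.005 by the RMS of the printed means, and
all seven pallidal totals within ±0.01 once the across-model spread is
included (the printed total averages per-model totals, and the squared
RMS is linear in $f^2$, so $\overline{T^2} = (\sum_i \bar f_i^2 +
s_i^2)/N$). Tabulated per-feature values are therefore treated as already
weight-scaled; raw features are weight-scaled inside the combination.
Two weight presets ship: an SPN-style preset (AHP curve ×4, no
rectification/spike-time terms) and a GPe-style preset (rectification ×2,
spike time and height ×0.5, no baseline-pre/latency/charging terms).

## Optimization

Parameters are affinely scaled to $[0,1]$ by their bounds. The optimizer
is CMA-ES with the standard published strategy defaults — log-decreasing
recombination weights including negative ("active") weights for the worse
half, cumulative step-size adaptation, rank-one plus rank-µ covariance
update — exposed through `ask`/`tell`/`stop`. Choices worth recording:

- **Sampling** uses the symmetric square root $C^{1/2} = B D B^\top$
  rather than $B D z$. The distributions are identical, but the symmetric
  root is a unique, well-conditioned function of $C$, so independently
  coded implementations follow the same trajectory; eigenvector bases of
  near-degenerate covariances are arbitrary and amplify last-bit
  differences chaotically. The test suite exploits this: a loop-style
  transcription of the published equations reproduces 20 generations of
  mean, step size and covariance to 10⁻⁶ relative.
- **Bounds**: projection repair plus a quadratic penalty on the squared
  scaled repair distance, added to the fitness during ranking only; the
  distribution update uses the unrepaired steps. The mean is clamped to
  the box.
- **Determinism**: per-generation sampling is seeded by
  `seed + 10007·generation`, so `ask` is reproducible and calling it twice
  on the same state yields the same candidates; ties in ranking break by
  candidate index. `sigma0` defaults to 0.3 in scaled space — a high
  initial variance that explores the full permitted range.
- **Budget bookkeeping**: every evaluation is persisted
  (`params.yaml` + `fitness.yaml` per evaluation, `history.csv` per
  generation) before it is reported, simulations failing with numerical
  errors score +∞ and the run continues, and exact duplicate parameter
  vectors (12-significant-digit canonical serialization) are served from
  the cache. Trace CSVs per evaluation are optional (`save_traces`), as
  they dominate disk traffic without serving the cache.
- **Convergence** is declared when the least-squares slope of the
  per-generation mean fitness over the last 25 generations is below 0.002
  in magnitude and its standard deviation is below 0.06. The magnitude
  matters: a steeply *improving* run satisfies a signed "< 0.002" reading
  but has not converged, so the absolute value is used.
- **Best-model selection**: the 2.5 % lowest-fitness evaluations
  (ceiling, at least one), or the 50 lowest once more than 2,000
  evaluations were performed.

## Synthetic recordings and parameter recovery

Because wet-lab recordings are external to the package, validation rests
on two repository-defined reference neurons (soma + 3 dendrites), whose
ground-truth densities are printed by `reference_densities()`:

- **spiker** (SP-like): NaF/KDr/KA with a slowly inactivating transient
  potassium current; rests near −83 mV, silent at rest and under
  hyperpolarization, rheobase between 160 and 200 pA, and first-spike
  latency of 100–250 ms above rheobase. Default protocols: 400 ms steps
  at −100, +160, +200, +240 pA (one depolarizing step sub-rheobase, as in
  typical experimental sets).
- **pauser** (GPe-like): a depolarized leak reversal and a
  low-threshold sodium window current drive spontaneous firing at zero
  injected current; slow HCN produces sag under the two 1 s
  hyperpolarizing steps (−200, −100 pA); an N-type calcium current feeds
  the pool and a calcium-activated BK current shapes the AHP. The two
  kinds use different channel kinetics, as their biological counterparts
  do.

Recordings are the clean simulation plus seeded additive Gaussian noise
(default SD 0.5 mV, representative of whole-cell noise). The generator
emulates step-protocol current clamp only: no electrode artifacts, series
resistance error, bridge imbalance, drift, or trial-to-trial variability.
Passing recovery tests therefore demonstrates that the optimization
machinery works when the model class contains the truth; they cannot show
that the model class is adequate for real neurons.

The recovery experiment fits the spiker's somatic NaF, KDr, KA densities
and RM (initial values 35 % high / 20 % low, bounds [0, 3×truth] for
densities and [truth/3, 3×truth] for RM) to noiseless synthetic
recordings over 50 generations × population 8 × 3 seeds — about 1,200
model evaluations, sized so the full experiment runs in a few minutes on
one core. The acceptance test asserts median best fitness below 0.05, RM
within 10 % and the spiking conductances within 30 %; the NaF/KDr pair is
the hard direction, as increases in both compensate each other almost
perfectly in the voltage traces — the same degeneracy that motivates the
subtype analysis below.

## Subtype analysis

Given best-model parameter matrices pooled across recordings with subtype
labels: columns are z-scored (`standardize`); stepwise discriminant
analysis (forward by largest partial F via the Wilks' lambda ratio,
backward removal, SAS-default thresholds 0.15/0.15, ties broken by column
order) selects the separating parameters; Ward-linkage hierarchical
clustering scored by the Calinski–Harabasz pseudo-F chooses the cluster
count (the specific criterion behind the original hierarchical procedure
is not documented, so pseudo-F was chosen as the standard default);
k-means with deterministic k-means++ seeding (10 restarts derived from
one seed, Lloyd iterations, empty clusters re-seeded once) yields
assignments, centroid distances and the cluster × subtype confusion
matrix. On instances of up to 8 points the k-means result equals the
exhaustive-enumeration optimum; on synthetic two-subtype parameter sets
with one shifted conductance the full chain recovers the shifted column
and a ≥90 %-correct confusion matrix across 20 seeds. Note that at the
0.15 entry threshold pure-noise columns enter the selection in roughly
half of datasets (the expected false-entry rate of five candidates at
α = 0.15); the "exactly one informative column" behaviour appears at
stricter thresholds, and the tests exercise both regimes.

## Known limitations

- Channel kinetics cannot be tuned, only densities and passive
  properties.
- One calcium pool per compartment with a single decay constant; no
  buffers, pumps, or diffusion.
- Igor binary traces are not read; CSV plus a YAML sidecar is the
  interchange format.
- The histogram and AHP-shape features are fixed-definition stand-ins for
  loosely specified quantities; they are confined behind the feature
  vector so alternative definitions are drop-in.
- Single-machine parallelism only (`parallel::mclapply` over candidate
  evaluations; results are identical regardless of the degree of
  parallelism).
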