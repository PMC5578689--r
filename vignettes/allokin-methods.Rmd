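---
title: "Methods: wavelet events, frame-set PCA, current-flow networks and WHAM"
author: "allokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet events, frame-set PCA, current-flow networks and WHAM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(allokin)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic-data tests
do and do not demonstrate about real trajectories.

## The scientific setting

Type 1 serine/threonine kinase receptors carry an electrostatic lock: a
salt bridge between the activation-loop arginine and the DLG-motif
aspartate (R375–D354 in ALK2) that blocks ATP coordination in the
resting state. Regulatory events far from the catalytic site — GS-domain
phosphorylation, FKBP12 release, disease mutations — destabilize this
lock allosterically. Dissecting that mechanism from MD output takes four
kinds of post-processing, each a module here: locating *when* and
*where* unusual motion happens (wavelet event detection), describing
*what* the motion is within each temporal regime (frame-set PCA),
tracing *how* motion is transmitted between distant sites (current-flow
betweenness on residue networks), and quantifying the *energetics* of
lock rupture (WHAM over umbrella-sampling windows).

Units are Å, ps, amu and kcal/mol throughout; conversions happen only at
I/O boundaries. Thermal energy defaults to kT at 300 K
(`kT_at(300)` = 0.5961 kcal/mol), the conventional simulation
temperature. Residue numbering is 1-based PDB author numbering.

## Trajectory handling

PDB (MODEL-aware) and DCD I/O go through bio3d, plus a minimal
CHARMM-format DCD writer (bio3d reads but does not write DCD);
round-trip fidelity is format precision (single-precision coordinates,
~1e-3 Å). Superposition is the Kabsch least-squares fit over a
selection (default: backbone atoms; CA-only synthetic topologies fall
back to all atoms). The default reference is the trajectory average
computed with the standard two-pass scheme — fit to the first frame,
average, refit to that average — which matches the "average structure"
reference the field's tools use. Fitting a fitted trajectory again
changes coordinates by less than 1e-8 Å.

The fitting selection used before wavelet analysis and PCA is not a
settled convention in the field; the default here (backbone atoms of the
retained residues) is configurable through the selection argument.

## Wavelet event detection

The per-residue signal transformed is the Euclidean displacement of each
residue's heavy-atom geometric center from its position in the first
frame, computed after RMS fitting. This choice is
rotation/translation-invariant and residue-resolved; it is a documented
assumption, since upstream tooling does not pin down the exact per-atom
signal.

The transform is a continuous Morlet wavelet transform (center frequency
ω₀ = 6, Torrence–Compo normalization, FFT implementation with zero
padding to the next power of two) across `n_scales = 60` log-spaced
timescales between the frame spacing and the trajectory duration.
Intensity is the squared modulus. Two numerical choices matter:

* **Demeaning.** Each residue signal is demeaned before the transform.
  The Morlet wavelet is blind to a constant, but under zero padding an
  offset turns the record into a box function whose low-frequency
  content dominates the longest scales and drowns genuine events.
* **Cone of influence.** Frames closer than √2·scale to either edge are
  inside the padding's influence; the mask is carried with the
  spectrogram, the denoising maximum ignores out-of-COI cells, and the
  temporal partition drops frames outside the COI of its largest
  embedded scale.

Denoising keeps (residue, frame) points whose max-over-scales intensity
exceeds `chi2_cutoff = 1.6094` times that residue's noise level — the
median over frames of the same max-over-scales series, times the
`correction = 1.01` factor. A median-of-maxima null keeps the standard
cutoff meaningful: a stationary residue retains only its upper tail,
while genuinely loud epochs survive intact. Thresholding is idempotent.

Surviving points are clustered by DBSCAN on the (frame, residue) grid
(`eps = 20`, `min_pts = 350`, both on the unscaled index grid with
scale factors exposed — whether ε is meant in frames or ps is not a
settled convention, so it is configuration). The implementation uses an
ε-sized grid hash for neighbor search; labels are invariant to point
order.

### Temporal partitioning into frame sets

Frames are embedded as vectors of log(intensity + 1e-12) over
(residue, scale), Ward-clustered (`hclust`, `ward.D2`) on Euclidean
distances, and the cut k in 2..6 maximizing the mean silhouette
(`cluster::silhouette`) is chosen; if the best silhouette is below 0.25
the trajectory is one frame set. Because agglomerative clusters need not
respect time order, labels are majority-smoothed along the frame axis,
short runs are merged, and the result is a disjoint, contiguous,
exhaustive set of half-open intervals.

Two problem-size choices are documented rather than hidden:

* At most 800 embedded frames enter clustering (longer trajectories are
  strided; boundaries map back to original frames). The stride, a few
  frames at typical sizes, is far inside the percent-level boundary
  resolution of interest.
* Only timescales up to 1/64 of the trajectory duration enter the
  embedding. A wavelet smears any discontinuity over roughly its own
  support, so the largest embedded scale *is* the boundary resolution;
  scales comparable to the whole trajectory add smearing (and edge
  artifacts) but no information about where a regime changes. With this
  default, a planted 3× fluctuation switch in a 5000-frame, 100-residue
  ensemble is located to 3–4 frames in ten seeds of ten; with a 1/16 cap
  the boundary was bistable between the true switch and the onset of the
  largest scale's ramp, a couple of hundred frames early.

## Frame-set PCA and the separation metric

PCA is the eigendecomposition of the 3N×3N coordinate covariance of the
selected atoms over a frame interval (unweighted covariance, the common
trajectory-PCA practice; group centers elsewhere are mass-weighted).
Eigenvector signs are fixed by making each vector's largest-magnitude
entry positive, so downstream quantities are deterministic.

The R-component field of mode m is √λₘ·vₘ per atom — RMS displacement
amplitude in Å, the convention that makes arrows drawn on structures
physically scaled. "Normalized by eigenvalues" is ambiguous between
√λ·v and λ·v; both are implemented, √λ·v is the default
(`convention = "lambda"` selects the other).

The separation metric takes a target group (e.g. the A-loop arginine's
atoms) and a barrier group (the steric-barrier stretch of the αC helix;
its residue range is a required user input, since it is defined
structurally, not by sequence), forms the unit vector **u** from the
barrier mass center to the target mass center on the interval-average
structure, and reports per mode the mean projection on **u** of the
target atoms' R-components minus that of the barrier atoms'. Positive
values mean opening. The natural log of |s| is reported alongside the
sign rather than dropping negative components. Swapping the two groups
flips **u** and the subtraction together, so the metric is symmetric
under the swap — "moving apart" does not depend on which group you call
target.

Modes export to NMD (NormalModeWizard dialect: `name`, `atomnames`,
`resnames`, `resids`, `coordinates`, then one
`mode <index> <eigenvalue> <vector>` line each, 15 by default).

## Current-flow betweenness networks

Nodes are residues (Cα representative); edges are contacts — any
heavy-atom pair within 4.5 Å in at least 75 % of frames, excluding
sequence-adjacent residues (the established dynamical-network
convention; both parameters are configuration). Edge conductance is
|C<sub>ij</sub>|, the absolute Pearson correlation of Cα displacement
vectors from the interval mean (generalized correlations are a known
alternative; Pearson is the default). Edges below a 1e-6 conductance
floor are dropped with a warning.

With L = D − W the weighted Laplacian and L⁺ its Moore–Penrose
pseudoinverse (dense `MASS::ginv`; these networks are small, typically
well under 500 nodes), driving one unit of current from s to t puts
node i at potential L⁺ᵢₛ − L⁺ᵢₜ, and edge (i,j) carries current
w<sub>ij</sub>·(potential difference). The edge score sums the absolute
current over all S×T pairs:

    Ebtw(i,j) = w_ij * sum_{s in S} sum_{t in T}
                |L+_{is} + L+_{jt} - L+_{it} - L+_{js}|

The conductance factor is what makes the score the *current* the
resistor interpretation promises; without it the score would be a
potential drop, would change under a global rescaling of the
correlations, and a bridge edge would not carry |S|·|T|. No |S||T|
normalization is applied by default (a normalized variant is available
for cross-query comparison). S and T must be disjoint — the pair sum
assumes distinct source and target sets. Node scores are half the sum of
incident edge scores.

Sub-network extraction assigns each edge the length 1/(Ebtw + 1e-12) —
the paper's own length metric for "optimal path" is unspecified, so
reciprocal betweenness (high-current edges are short) is the documented
choice — takes the shortest S→T path as optimal, and keeps any edge
whose constrained-through-that-edge S→T path is at most (1 + 0.20)×
the optimal length. The included set grows monotonically with the
tolerance.

## WHAM

Standard self-consistent WHAM on a fixed grid (default 100 bins over
the sample range): P(x_b) ∝ Σᵢhᵢ(x_b) / Σⱼ nⱼ exp((Fⱼ − bⱼ(x_b))/kT)
with harmonic biases bⱼ(x) = ½kⱼ(x − xⱼ)², iterated until the largest
window free-energy shift is below 1e-6 kT. W(x) = −kT ln P(x),
min-shifted to zero; empty bins are NA and flagged, never interpolated.
No autocorrelation or statistical-inefficiency weighting is applied —
appropriate for the exact-sample generator used in validation and a
documented limitation for strongly autocorrelated window time series.
The umbrella force constant is a required input with no default: there
is no universal convention to assume silently.

Cumulative diagnostics recompute the PMF over growing sample subsets
[start, start + m·blocks]; convergence is declared when successive
profiles differ by under 0.2 kcal/mol (max-abs on bins occupied in
both). Window overlap is reported as the histogram intersection
Σ_b min(p_a(b), p_b(b)) of adjacent windows' normalized histograms — 1
for identical windows, 0 for disjoint ones — and the solver warns when
adjacent windows share less than 5 % of their mass. Barrier heights are
read off a profile by pairing the global minimum with the local minimum
of greatest mutual prominence, which keeps bin-count noise at a well
bottom from posing as a second well.

## Synthetic data: what it emulates, and what it does not

The generators supply every input with known ground truth:

* `gen_gaussian_trajectory` — i.i.d. multivariate-Gaussian frames about
  a reference with prescribed 3N×3N covariance (optionally AR(1)-mixed
  in time, preserving the stationary covariance; optionally switching
  reference and/or covariance at a known frame). Correlation/covariance
  structure is exact by construction, which is what the PCA and network
  recovery tests need. Regime switches in the tests change the
  fluctuation *amplitude* (covariance scale): a mean-only step produces
  a wavelet response localized at the step rather than two
  distinguishable stationary regimes, so an amplitude change is the
  scenario that matches "discontinuity of the motions".
* `gen_langevin_doublewell` — Euler–Maruyama overdamped Langevin on
  U(x) = A((x − c)²/w² − 1)², emulating a distance coordinate that
  reversibly hops between a formed and a broken state.
* `gen_umbrella_samples` — exact inverse-CDF draws from the biased
  Boltzmann density on a fine grid (8192 points), so WHAM recovery
  errors are attributable to WHAM, not to sampling dynamics. Window
  ladders default to 1.5 Å spacing, the conventional umbrella width for
  a salt-bridge separation coordinate.
* `gen_resistor_graph` — path/diamond/ladder/random templates with
  exact unit-current edge flows from a nodal Kirchhoff solve
  (deliberately a different computational route — reduced-system
  `solve` with a grounded node — from the pseudoinverse scoring it
  validates).
* Lattice geometries (`lattice_coords`) place residues on a 4 Å grid so
  the contact graph is known exactly, with residue numbers assigned by
  a coprime modular stride (`scattered_resno`): consecutive numbering
  would make every x-step a sequence-adjacent pair — exactly the
  contacts the network convention excludes — whereas folded domains
  genuinely have spatial neighbors distant in sequence.

All generators are deterministic given their seed and restore the
caller's RNG stream, so adding one call never perturbs another's
output.

What passing these tests shows: the transforms, estimators and solvers
do what their definitions promise, at realistic sizes, with known
answers. What they do not show: real trajectories have autocorrelated,
anharmonic, non-Gaussian fluctuations; real events are not clean
covariance switches; umbrella windows inherit the sampling dynamics of
the biased simulations. Conclusions about a real system still require
the usual convergence diagnostics (the cumulative PMFs, the window
overlaps, the silhouette profile) on that system's data.

## Problem sizes used in validation

The bundled validation runs at: 27 resistor graphs (n ≤ 12) for the
betweenness oracle; 13 umbrella windows × 10⁴ exact samples for WHAM
recovery (harmonic RMSE < 0.1 kcal/mol; 3 kcal/mol double-well barrier
within 5 %); ten seeds of 5000 frames × 100 residues for regime-switch
recovery (boundary within 2 % of trajectory length); 20 000 frames for
planted-mode PCA (|cos| > 0.99); 50 000 frames × 64 residues for
correlation-network recovery (±0.02) with a planted 6-residue
transmission chain whose edges rank in the top decile of Ebtw. These
sizes were chosen as the smallest at which the statistical claims are
comfortably resolved.

## Known limitations

* Trajectory formats are PDB and DCD only; other formats need
  conversion upstream.
* No periodic-boundary imaging: inputs are assumed whole (stripped
  protein or synthetic ensembles).
* WHAM is 1D, without replica-exchange demultiplexing (inputs are the
  usual per-window post-exchange files) and without autocorrelation
  weighting.
* Density clustering is exact DBSCAN; very large thresholded point sets
  cluster in chunked vectorized passes, but memory grows with the
  densest ε-cell.
* The wavelet stage holds the full residues × frames × scales intensity
  array in memory (~240 MB at 100 residues × 5000 frames × 60 scales).
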