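# allokin

Post-simulation analysis of allosteric regulation in type 1
serine/threonine kinase receptors (STKR1: ALK1–7) and similar kinases.
In these receptors a conserved electrostatic lock — a salt bridge between
the activation-loop arginine and the DLG-motif aspartate (R375–D354 in
ALK2) — blocks ATP coordination; phosphorylation of the regulatory GS
domain, FKBP12 release, or disease mutations destabilize it through
allosteric channels that span the whole kinase domain. `allokin`
implements the analysis machinery used to dissect that mechanism from
molecular-dynamics output:

* **Salt-bridge state metrics** — donor–acceptor distance series from
  PDB/DCD trajectories, labeled *formed* below a 5 Å threshold.
* **Wavelet event detection (WAFEX-style)** — per-residue Morlet
  spectrograms (60 log-spaced timescales), chi-squared denoising (cutoff
  1.6094, correction 1.01), density clustering of the surviving
  (time, residue) points (ε = 20, minimum cluster size 350), and
  silhouette-scored Ward clustering of frames into contiguous *frame
  sets* — the temporal windows that bound conformational events.
* **Frame-set PCA** — backbone-fluctuation PCA restricted to one frame
  set; R-component fields √λₘ·vₘ (per-atom mode vectors in Å); a
  separation metric s·u quantifying how much component *m* moves a target
  group (e.g. the A-loop arginine) away from a steric-barrier group (the
  αC helix) along the unit inter-group axis **u**; NMD export for
  NormalModeWizard.
* **Current-flow betweenness networks** — the residue contact network is
  treated as a resistor network with edge conductance |C<sub>ij</sub>|
  (Cα fluctuation correlation). Driving one unit of current from source
  residues S to target residues T, each edge's score is the total current
  it carries,

  E<sub>btw</sub>(i,j) = w<sub>ij</sub> Σ<sub>s∈S</sub> Σ<sub>t∈T</sub>
  |L⁺<sub>is</sub> + L⁺<sub>jt</sub> − L⁺<sub>it</sub> − L⁺<sub>js</sub>|,

  with L⁺ the Moore–Penrose pseudoinverse of the weighted graph
  Laplacian. Sub-networks keep the optimal S→T path plus edges whose
  constrained path length exceeds it by at most 20 %.
* **WHAM** — self-consistent weighted-histogram reconstruction of 1D
  free-energy profiles from umbrella-sampling windows (the conventional
  per-window two-column layout plus a metadata file), with
  cumulative-block convergence diagnostics and window-overlap guards.
* **Synthetic data with known ground truth** — multivariate-Gaussian
  trajectories with prescribed covariance and regime switches, overdamped
  Langevin walks on a double well, exact Boltzmann draws under harmonic
  umbrella biases, and resistor graphs with analytic edge currents. Every
  analysis stage is validated against these generators.

## Worked example

The bundled demonstration wires every stage together on synthetic data
whose answers are known: a 36-residue lattice "kinase" with a planted
high-correlation transmission chain and a 3× fluctuation jump at frame
1200, a Langevin salt-bridge distance hopping between wells at 4 and
8 Å, and 13 umbrella windows drawn from a double well with a 3 kcal/mol
barrier.

```sh
Rscript inst/cli/allokin.R all --outdir demo --seed 1
cat demo/report/report.txt
```

```
allokin synthetic demonstration report
======================================
Salt bridge: formed in 33.1% of frames (threshold 5.0 A)
Temporal partition: 2 frame set(s); boundaries at 0, 1200
Top separation components (component: separation):
  PC3: 0.0517
  PC5: 0.04306
  PC6: 0.03874
Top current-flow betweenness edges (from-to: score):
  1-22: 0.9639
  22-13: 0.6836
  13-34: 0.2838
  7-34: 0.2822
  22-7: 0.2798
  ...
PMF barrier: 3.11 kcal/mol (wells at 3.97, 7.99 A); converged: TRUE
```

Reading the numbers: the temporal partition recovers the planted regime
boundary exactly (frame 1200); the five top-scoring edges are precisely
the planted transmission chain 1–22–7–34–13 (plus its internal
shortcut); the WHAM barrier reproduces the generator's 3 kcal/mol within
sampling error, with wells at the planted 4 and 8 Å positions; and the
salt-bridge occupancy matches the double well's Boltzmann weight below
5 Å. Each stage leaves its artifacts (CSV/JSON/NMD/GraphML) and a
manifest under `demo/<stage>/`; the same stages are available as R
functions (`run_stage()`, `run_pipeline()`) for scripted use on real
trajectories.

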