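---
title: "saxstruct: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{saxstruct: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`saxstruct` turns size-exclusion-coupled small-angle X-ray scattering
(SEC-SAXS) measurements of flexible multi-domain proteins into
low-resolution structural information: a validated one-dimensional
scattering curve, real-space size parameters, an ab initio molecular
envelope, and — when predicted atomic models are available — a dual-space
assessment and envelope-restrained refinement of those models. This
vignette explains the underlying models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## 1. From an elution series to one curve

A SEC-SAXS injection yields hundreds of frames, each a curve
$I(q)$ with uncertainties $\sigma(q)$ on a common grid of momentum
transfer $q$ (Å⁻¹ throughout; files whose $q_{max}$ exceeds 3 are
rejected as probable nm⁻¹ data rather than silently converted, because
silent unit conversion is a classic source of error in this field).

* `chromatogram()` integrates each frame over $q$ (trapezoid rule) to
  give the elution profile.
* `frame_rg()` buffer-subtracts each frame and runs a Guinier fit,
  giving per-frame $R_g$ with uncertainties. Frames with no decaying
  low-$q$ signal (buffer-only regions) return `NA`.
* `select_window()` chooses the frames to average: among all contiguous
  windows inside the peak whose frames all have a valid $R_g$, the
  longest one whose $R_g$ standard deviation does not exceed
  $\kappa \times$ the median per-frame $R_g$ uncertainty. The default
  $\kappa = 1$ encodes "homogeneous means the $R_g$ scatter is within
  measurement error". Ties go to the smaller scatter, then the earlier
  start; if no window of length ≥ 3 qualifies, the scatter-minimizing
  length-3 window is returned with a `fallback` flag, so drifting
  (non-homogeneous) peaks are never silently averaged.
* `average_and_subtract()` averages the window, averages the buffer
  frames, subtracts, and propagates
  $\sigma = \sqrt{\sigma_s^2/n_s + \sigma_b^2/n_b}$ per point.
  `auto_buffer_frames()` defaults to the 20 lowest-chromatogram frames
  preceding the first peak — the pre-elution baseline. This default is a
  documented assumption: beamline pipelines differ in how they pick
  buffer frames, and the choice is exposed as an argument.
* `compare_datasets()` tests whether two reduced curves sample the same
  underlying profile: B is interpolated onto A's grid (linear in $q$), A
  is scaled onto B by analytic weighted least squares (so the test is
  symmetric up to interpolation, rather than depending on which curve is
  "reference"), and the reduced $\chi^2$ with combined variances gives a
  p-value from the $\chi^2$ distribution with $N-1$ degrees of freedom
  (one fitted scale). The conventional significance level for "these
  datasets disagree" is $\alpha = 0.01$.
* `rebin()` merges every $k$-th point or re-bins to a linear or
  logarithmic grid with inverse-variance weights, the standard
  signal-to-noise improvement before indirect transformation.

## 2. Guinier analysis

`guinier_fit()` performs the weighted regression of $\ln I$ on $q^2$,
iterating the upper end of the range until $q_{max} R_g \le 1.3$, the
standard cutoff for globular particles. Two refinements matter in
practice:

* **Start-point screening** (`auto_start`): each leading point is judged
  against a fit that *excludes* it; points deviating by more than
  3σ (aggregation upturns, beamstop artifacts) are dropped. Judging a
  point against a fit that includes it lets a strong upturn bend the fit
  enough to mask itself.
* **Curvature correction**: within $qR_g \le 1.3$ the Guinier line is
  not exact — for a homogeneous sphere the next term in the expansion
  biases the fitted $R_g$ upward by about 2%. When the data are precise
  enough that a quadratic term in $q^2$ is statistically resolved
  ($t > 3$), the $q^2 \to 0$ slope of the quadratic fit is used instead,
  which removes the bias without affecting exact-Guinier data (where the
  quadratic term is never significant). With this correction the
  analytic sphere oracle is recovered to well under 1%.

The initial fitting window spans the first fifth of the usable points
rather than a minimal set: in nearly flat, noisy low-$q$ data a minimal
window can show a spurious positive slope and abort a perfectly good fit.

## 3. P(r), Dmax, quality, and molecular weight

`ift()` inverts
$I(q) = 4\pi \int_0^{D_{max}} P(r)\,\mathrm{sinc}(qr)\,dr$ on the Moore
parameterization $P(r) = \sum_k a_k \sin(k\pi r/D_{max})$, truncated at
the information limit $k \le D_{max} q_{max}/\pi$ plus a three-term
buffer. The sine basis pins $P(0) = P(D_{max}) = 0$ by construction. A
second-derivative penalty stabilizes the inversion; its weight `alpha`
is chosen by the maximum-curvature corner of the L-curve (residual norm
vs roughness norm over a 40-point logarithmic grid), with a guard that
rejects corners that degrade the fit by more than a factor ~3 over the
best achievable $\chi^2$. The normal equations are solved with column
scaling, because the inverse-variance weights of real curves span many
orders of magnitude; `alpha` is therefore expressed relative to the
scaled problem (α ≈ 1 balances fit and smoothness). The r-grid default
is 201 points.

`find_dmax()` scans candidate $D_{max}$ values from $2R_g$ (Guinier) up
to $\min(2\pi/q_{min},\ 5R_g)$, scoring each inversion by
$\chi^2 + 2\,(\text{negative area fraction}) + 10\,(\text{negative
oscillation near } D_{max})$. Below the true $D_{max}$ the fit degrades
sharply; above it the score plateaus. The estimate is the *onset* of the
plateau — the smallest candidate within a small tolerance
(max(0.03, 2%) of the best score), refined by a second, finer scan. On
the analytic sphere this recovers $2R$ to within ~4%, on an elongated
rod-like toy within ~8%.

`real_space_params()` gives $R_g^2 = \int r^2 P\,dr / (2\int P\,dr)$ and
$I(0) = 4\pi \int P\,dr$. Agreement of the real-space $R_g$ with the
Guinier $R_g$ is the pipeline's basic internal consistency check (about
2% on simulated data at 1% noise).

`pr_quality()` is a composite score in [0, 1] in the spirit of the
quality estimates that indirect-transform programs print. It is *not* a
reproduction of any program's formula (none is published); it is the
equal-weight geometric mean of four sub-scores: fit
($e^{-|\chi^2-1|}$), positivity (1 − negative area fraction), smooth
approach of $P$ to zero at $D_{max}$ (penalizing negative oscillation in
the last 15% of the range, not the legitimate decay of $P$ itself), and
stability of the real-space $R_g$ under ±10% $D_{max}$ perturbation.

`estimate_mw()` uses the Porod relation $V = 2\pi^2 I(0)/Q$ with the
invariant $Q = \int_0^\infty q^2 I\,dq$, but evaluates it in real space,
where the truncated and oscillating reciprocal-space integral is exact:
$Q = 2\pi^2\gamma(0)$ with $\gamma(0) = \lim_{r\to0} P(r)/r^2$, hence
$V = 4\pi\int P\,dr \,/\, \gamma(0)$. The limit is taken by fitting
$P = c_2 r^2 + c_3 r^3$ over the inner quarter of the range (the cubic
term absorbs the leading surface correction). For an ideal homogeneous
body the estimate equals the true volume; a direct $q^{-4}$ tail
extrapolation was several percent biased by form-factor oscillation on
the sphere oracle, which is why the real-space route is used. MW is
$V / 1.6$ ų·Da⁻¹, the standard protein packing factor. This
volume-based estimate replaces Bayesian-consensus MW methods, which need
an empirical training corpus; accordingly MW agreement should be read at
the ±10% level. `sequence_mw()` provides the sequence-based expectation
(average residue masses plus one water).

## 4. Theoretical profiles and the χ² metric

`debye_profile()` evaluates
$I(q) = \sum_{ij} f_i f_j \,\mathrm{sinc}(q d_{ij})$. At residue level
one scatterer sits on each Cα with $f$ = the residue's electron count
(built-in table, neutral side chains); bead models use occupancy
weights. Pair distances are binned at 0.1 Å with the *weighted mean
distance per bin* as the bin coordinate, which makes the binning error
second order (< 0.5% against the exact pair sum) while the $q$-loop
scales with the number of bins, not pairs. Excluded-volume and
hydration-shell contrast terms are deliberately omitted: the package
compares models *relative* to one another against the same data, so
absolute χ² values are not comparable with solvent-corrected programs,
and published absolute χ² values are not reproduction targets.

`fit_profile()` scales the calculated curve analytically
($c = \sum w I_e I_c / \sum w I_c^2$) and reports
$\chi^2 = \frac{1}{N-1}\sum \left((I_e - cI_c)/\sigma\right)^2$; with a
fitted constant background, a 2-parameter weighted solve and $N-2$
degrees of freedom. Under unit-σ noise the statistic calibrates to
1.0 ± 0.2 over seeds.

## 5. Ab initio envelopes

`anneal_beads()` reconstructs shape as binary occupancy on a
face-centered-cubic lattice of touching beads filling a sphere of
diameter $D_{max}$. The default bead radius $D_{max}/20$ gives a
few-hundred-to-thousand-site search space — envelope-program resolution
at desktop cost. Single-bead flips are accepted by Metropolis on

$$E = \chi^2 + \lambda(\text{looseness} + \text{disconnectivity})$$

where looseness is the mean fraction of empty neighbor sites and
disconnectivity counts occupied beads outside the main connected
component (evaluated exactly at every candidate move by a component
search seeded at the bead nearest the occupied centroid). The χ² term
uses a 40-point log-rebinned copy of the curve and an incremental
intensity update via precomputed 0.1 Å distance classes, so each move
costs $O(n_{occ} + n_q n_{cls})$.

The balance $\lambda$ is set to `lambda_scale` (default 0.02) times the
starting χ² divided by the starting penalty. Balancing the penalty to
the *full* starting χ² — the obvious choice — turned out to let the
compactness prior dominate once χ² had dropped two orders of magnitude,
which produced penalty-shaped, mutually inconsistent reconstructions of
multi-domain shapes; at 0.02 the data steer the end state and
independent runs of the three-domain toy agree pairwise below NSD 1.

Cooling is geometric ($T \to 0.9T$ per chunk of moves) from a starting
temperature at which about half of probed uphill moves are accepted; a
run stops when in-chunk acceptance falls below 1% or the move budget
(default 30 × sites) is spent. Every run is seeded (`seed + run`), so a
fixed seed reproduces the whole set bit for bit. The number of
independent runs defaults to 20.

`align_nsd()` superposes envelopes by the normalized spatial
discrepancy: centroid superposition, principal-axis alignment over all
proper sign combinations, the same for the inverted copy (solution
scattering cannot distinguish enantiomers, so both hands are scored and
the best kept), then local Nelder-Mead refinement over rotation and
translation. For shapes with degenerate principal axes (a sphere) the
axis candidates are uninformative and the method reports the lattice
mismatch rather than zero — an intrinsic property of axis-based
alignment, visible in the tests, and irrelevant in practice because such
shapes are rotationally equivalent anyway.

`average_models()` aligns all runs onto the one with the lowest mean NSD
to the others, excludes runs beyond mean + 2 SD, snaps aligned beads
onto the reference lattice to form per-site occupancies, and cuts the
occupancy-ranked model at the median single-run volume.
`refine_beads()` restarts the annealing from that state at 5% of the
auto temperature with the high-occupancy core (≥ 0.7) frozen.

Interpretation thresholds follow envelope-modeling convention: NSD < 1
among reconstructions of the same data, NSD < 3 between an envelope and
a full-atom model.

## 6. Dual-space validation, splicing, and flexible fitting

`validate_dual()` reports the pair the pipeline uses to judge an atomic
model: χ² of its Debye profile against the measured curve (reciprocal
space) and NSD of the envelope beads against its Cα set (direct space).

`splice_models()` builds one model from two overlapping construct models
by Kabsch superposition over the shared residues (the "lever arm") and
takes each side's residues from its better model; junction Cα–Cα
distances outside 2.9–4.1 Å are reported, not silently accepted.
Residue ranges are explicit inputs — the package does not adjudicate
boundary conventions for the overlap.

`combine_envelopes()` aligns each construct's envelope onto the Cα set
of its residue range in the full model, rasterizes both onto one grid,
and merges by voxel-wise maximum: a single union restraint, so that
refining the full model against both datasets cannot tear it into two
incompatible halves. The per-range alignment is an interpretation of
"superposed on the initial conformation"; it is deterministic and
commutative in its two envelope arguments.

`flexfit()` is a deterministic, Cα-level surrogate of
density-restrained molecular-dynamics fitting — full MD (explicit
solvent, Ewald electrostatics, femtosecond integration, protonation
assignment) is out of scope for a self-contained package and is not
needed for the geometric question the restraint answers. Gradient
descent with backtracking line search minimizes

$$U = -w\sum_i \rho(x_i) + k_{bond}\sum (\lvert x_{i+1}-x_i\rvert -
3.8)^2 + k_{dom}\sum_{dom}\lVert x - \hat x_{ref}\rVert^2 +
\sum_{pairs} k (\lvert x_i - x_j\rvert - r_0)^2$$

with trilinearly interpolated density ρ (analytic gradient). Three
choices matter:

* the map **saturates** at `cap_frac` (default 0.5) of its maximum, so
  atoms already inside well-covered density feel no force — the standard
  trick that keeps fitted regions undistorted while outside regions are
  pulled in;
* the map weight $w$ auto-scales so the mean map force equals the force
  of a half-Å bond stretch — strong enough to move a domain, weak
  enough not to shred it (the counterpart of tuning an external-potential
  scaling factor in MD-based fitting);
* each rigid domain is tethered to its reference coordinates *after*
  optimal superposition, recomputed every step — free rigid-body motion,
  restrained internal geometry (the targeted-MD surrogate). With
  $k_{dom}=\infty$ domains are projected exactly rigid each step.

Virtual bonds connect consecutive Cα at 3.8 Å; pairs more than 4.5 Å
apart in the start model are treated as chain breaks and carry no bond.
Optional harmonic pair restraints with the metal-coordination
convention (spring constant 50 energy units per Å², reference 2.5 Å)
stand in for Zn-site bonds at Cα resolution, where explicit ions and
protonation states do not exist. The trajectory reports the map
cross-correlation (`density_corr()`: Pearson over voxels where either
map exceeds 1% of its maximum) and RMSD to the start per step.

## 7. The PAV descriptor

`pav_profile()` computes per-residue backbone dihedrals (IUPAC sign,
from N–Cα–C, cross-checked against an independent torsion
implementation) and folds them into the protein angular value
$\mathrm{PAV}_i = \frac{180}{\pi}\arccos(\cos(\psi_i + \varphi_i))$,
which maps the circular sum onto [0°, 180°] and so avoids the
range-definition problem of circular variables. Terminal residues (no
$\varphi$ or no $\psi$) and residues flanking a chain break
(Cα–Cα > 4.5 Å) are omitted. `pav_matrix()` aligns profiles by residue
index, excluding column-wise any residue missing in some model — the
conservative choice when ensembles have ragged coverage.
`pav_pca()` (column-mean-centered) and `pav_hcluster()` (average
linkage, Euclidean) are thin wrappers over the standard implementations,
providing the coordinate system and grouping in which conformational
families separate.

## 8. The synthetic-data generator

`make_toy_structure()` builds Cα-level multi-domain chains: domains are
cubic-lattice fillings of spheres or ellipsoids at 3.8 Å spacing joined
by extended linkers, with placement directions seeded and re-drawn on
overlap. The `nsd3` preset mirrors the topology of the NSD3 C-terminal
region — three domains of 84, 249 and 105 residues (the PWWP2,
AWS–SET–postSET and PHD4 region sizes) with short linkers — as a
stand-in with known ground truth, not a model of the real coordinates.
`simulate_curve()` adds Gaussian noise with
$\sigma(q) = a\,I(q)\,(1 + b\,q/q_{max})$ (defaults $a=0.01$, $b=4$:
about 1% relative error at low $q$ rising to ~5% at the high-$q$ end,
SEC-SAXS-like), on the default 512-point grid over 0.0026–0.340 Å⁻¹, a
typical bioSAXS camera range. `simulate_secsaxs()` composes any number
of Gaussian elution peaks (a shoulder is just an overlapping species)
over a flat buffer with the same noise model, and records per-frame
composition as ground truth.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: detector geometry and smearing,
radiation damage, inter-particle structure factors at high
concentration, capillary-fouling backgrounds, side-chain-level scattering
contrast, and hydration-layer effects. Tests against the generator
demonstrate the correctness and self-consistency of the algorithms under
a known forward model, plus closed-form agreement wherever an analytic
oracle exists (sphere form factor and $P(r)$, two-point Debye, PAV
folding, Kabsch optimality).

Noise-model caveat: purely multiplicative noise gives the deep
form-factor minima of idealized bodies vanishing σ and hence infinite
weight; fixtures built from analytic curves therefore add a small
absolute σ floor, as real detectors do.

## 9. Orchestration and problem sizes

`run_pipeline()` chains the stages from a config list or YAML file and
writes every stage product plus a consolidated, versioned JSON report;
each stochastic stage records its seed. The package's functions, this
configuration runner, and `scripts/acceptance.R` are the interfaces; no
shell wrapper is provided.

Default problem sizes were chosen so that a full synthetic study — SEC
series of 70 × 256-point frames, 20 annealing runs on a ~700-site
lattice, pairwise NSD averaging, and a 150-step flexible fit — completes
in a few minutes on one core; all are arguments, and scale up linearly
(annealing per-move cost grows with sites × distance classes).

## 10. Known limitations

* Envelope χ² is not comparable with solvent-corrected profile fitting;
  only orderings and self-consistency are meaningful.
* Axis-based NSD alignment can report non-zero values for rotationally
  degenerate shapes (see §5).
* The Dmax scan assumes a single monodisperse species; it will not
  flag mixtures (dataset comparison and window selection are the tools
  for that).
* Flexible fitting explores a single basin deterministically; it will
  not cross energy barriers the way thermostatted MD can.
* P(r) endpoint pinning means curves with a genuine constant background
  must have it removed (fit_profile's offset, or buffer subtraction)
  before inversion.
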