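---
title: "Structural and pharmacological diagnostics of apelin-receptor ligand bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural and pharmacological diagnostics of apelin-receptor ligand bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apelinbias)
```

## The problem

The apelin receptor (APLNR/APJ) is a class-A GPCR that signals through both
Gi proteins and beta-arrestin. A ligand is *biased* when it preferentially
activates one of those transducers. Two structural observables from
molecular-dynamics (MD) trajectories of the active receptor discriminate the
pathways:

1. **The TM5-TM7 tyrosine gate.** A persistent hydrogen bond between the
   phenolic hydroxyls of Tyr221 (TM5) and Tyr309 (TM7) marks a conformation
   competent for beta-arrestin recruitment. Persistence is measured as the
   fraction of frames in which the donor-acceptor O...O distance sits inside
   the 2.7-3.3 A window regarded as optimal for hydrogen bonding.
2. **The G-protein cavity clash.** Superposing the receptor conformer into a
   receptor/G-protein template complex (by Kabsch fitting on shared CA atoms,
   then discarding the template receptor) and testing Arg127 (TM3,
   intracellular cavity) against the G-alpha Tyr356 for van der Waals overlap
   decides whether a G protein can physically dock.

`classify_bias()` combines the two: *beta-arrestin-biased* when the tyrosine
bond is persistent **and** the cavity clashes; *G-protein-competent* when
neither holds; *indeterminate* otherwise. The classification is a pure
function of (occupancy, clash) and is invariant to frame order.

On the assay side, beta-arrestin recruitment luminescence curves are
quantified with three standard models: saturation binding with Hill slope
(`fit_binding_hill()`: Bmax, Kd, h), the Black-Leff operational model of
partial agonism (`fit_operational()`: Em, tau, KA, n), and a Hill inhibition
curve (`fit_inhibition()`: top, bottom, IC50, slope). `normalize_bmax()`
expresses maximal binding as a percentage of a reference full agonist
(apelin-13 = 100%).

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| H-bond donor-acceptor cutoff | 3.5 | A | the convention of the common MD H-bond tools, paired with a 30 degree hydrogen-donor-acceptor angle |
| optimal H-bond window | [2.7, 3.3] | A | the donor-acceptor band regarded as optimal for bond formation; used for occupancy |
| occupancy threshold | 0.5 | fraction | a bond that holds for ~70% of a run should count as persistent, one present "in a limited manner" should not; 0.5 separates the regimes and is configurable |
| clash tolerance | 0.4 | A | standard steric-overlap allowance below the sum of Bondi vdW radii |
| contact cutoff | 4.0 | A | common heavy-atom convention for ligand-residue interaction tables |
| cluster cutoff | 0.2 | nm | GROMOS neighbor-counting cutoff used for conformer extraction |
| SASA probe | 1.4 | A | water probe; 960 surface points per atom |

Van der Waals radii are the Bondi set with a 1.70 A fallback for unlisted
elements; elements are read from the PDB element column or inferred from
atom names. Residue numbering is preserved verbatim from input files because
the diagnostic residues (Tyr221, Tyr309, Arg127, Tyr356) are identified by
author-style numbers.

### Reporting convention

`mean_distance()` returns exact arithmetic means. Report tables print
distances *truncated* (not rounded) to two decimals via
`format_distance()`, matching the convention of the upstream visualization
tools whose printed distance tables this package reproduces; with ordinary
rounding the third decimal of some column means would differ.

Both donor directions of the tyrosine pair are always reported
(`Tyr309O-HTyr221` and `Tyr221O-HTyr309`, i.e. acceptor oxygen against
donor hydrogen), because published distance tables label the two directions
separately and they differ whenever the hydroxyl hydrogens are not
symmetric. Occupancy, by contrast, is computed on the heavy-atom O...O
distance, since the geometric criterion for bond formation is stated
between donor and acceptor heavy atoms.

## Numerical choices

* **Kabsch superposition** uses the SVD construction with the determinant
  sign correction, so the returned rotation is always proper. Fewer than 3
  pairs or collinear point sets raise a degenerate-geometry error.
* **GROMOS clustering** is the Daura neighbor-counting scheme; ties in the
  neighbor count are broken by the lowest frame index, which makes the
  partition deterministic, and clusters are renumbered by decreasing size.
  The all-vs-all RMSD matrix is O(n^2) in frames, so trajectories are
  subsampled to a few hundred frames before clustering; the conformer passed
  to the clash assessment is the neighbor-richest frame of the top cluster.
  The cluster RMSD is computed on CA atoms, consistent with backbone-based
  RMSD traces.
* **SASA** is Shrake-Rupley with a deterministic golden-spiral point set
  (default 960 points/atom). The molecular volume is Monte-Carlo
  integration of the union of (vdW + probe) spheres under a fixed seed, with
  the standard error reported alongside the estimate.
* **H-bond hydrogens** are located by the bonded-name convention (donor
  `OH` pairs with `HH`, `NE2` with `HE2`, ...) with a 1.25 A proximity
  fallback; structures without hydrogens fall back to the distance criterion
  alone and the bonds are flagged `distance_only`.
* **Curve fits** are damped least squares (Levenberg-Marquardt via
  minpack.lm) in log10-parameter space for every positive parameter, started
  from a fixed 5x5x3 grid (location parameter across the dose range x shape
  values x scale multipliers). No randomness enters the optimization, so
  fits are reproducible bit-for-bit.

### Identifiability of the operational model

At transducer slope n = 1 the operational model collapses to a hyperbola in
which only the observed maximum Em·tau^n/(1 + tau^n) and the EC50 are
determined — Em, tau and KA cannot be separated even from noiseless data.
At realistic noise the Em-tau correlation remains severe for any slope, so
`fit_operational()` offers `Em_policy = "shared"`, fixing Em at a supplied
system maximum (classically, the reference full agonist's fitted maximum).
In simulation at 2% Gaussian noise, tau is recovered within +/-50% in ~97%
of replicates with Em shared, versus ~20% with Em free. The binding model
with very shallow slopes (h ~ 0.22) likewise needs a wide design; the
recovery simulations use 12 doses spanning five decades either side of Kd
so that both plateaus are sampled.

## The synthetic-data generator

Real receptor models and trajectories are not redistributable here, so every
stage is exercised on generated inputs with known ground truth:

* `make_toy_receptor()` builds an idealized helical CA scaffold (1.5 A rise,
  100 degrees/residue) carrying the TYR 221/309 pair with the O...O distance
  set exactly, hydroxyl hydrogens on the O-O axis (textbook donor geometry),
  and an ARG 127 with an NH1 nitrogen when the numbering covers it.
* `make_trajectory()` drives the O...O distance with a discrete
  Ornstein-Uhlenbeck process (mean mu, stationary sd, relaxation time in
  frames) with an optional regime switch — e.g. mean 3.0 A for 70% of frames
  then 6.0 A, emulating a hydrogen bond that breaks late in a run. Defaults:
  sd 0.1 A (so the +/-0.3 A optimal window captures ~99.7% of stationary
  samples and the occupancy of a switched run equals the pre-switch
  fraction), relaxation 50 frames, 0.05 A isotropic jitter on all
  non-controlled atoms, 0.01 ns/frame (100 ns per 10,000 frames).
* `make_template_complex()` builds a two-chain receptor/G-protein stand-in
  whose closest cross-chain heavy-atom separation is set exactly (realized
  by the Arg127 NH1 ... Tyr356 OH pair), so the clash flag flips at the
  computed vdW threshold (1.55 + 1.52 - 0.4 = 2.67 A).
* `make_assay()` evaluates the named model curve at the requested doses and
  adds Gaussian noise scaled to the model maximum, deterministically under
  its seed.

What the generator does **not** emulate: force-field physics, solvent,
side-chain packing, correlated backbone motions, ligand chemistry, or
periodic boundaries. Passing tests therefore demonstrate that the
*observables and decision rules* are computed correctly and that parameters
are recoverable under the stated noise — not that the biological conclusion
would survive on new MD data.

## Problem sizes

The default test-suite and reproduction runs use 10,000-frame trajectories
for the end-to-end bias classification (matching a 100 ns production run
sampled every 0.01 ns), 8-12-frame systems for clustering oracle
comparisons, 12-dose 3-replicate assays for the fit simulations (200
replicates for the coverage studies), and 960 surface points per atom for
SASA. These sizes keep every analysis deterministic and fast on a single
CPU while leaving the statistics meaningful.

## Known limitations

* The clash assessment is a deterministic vdW-overlap rule standing in for
  expert visual inspection of a docked G protein; borderline geometries near
  the tolerance boundary flip the call.
* Chain correspondence for template superposition is by shared residue
  numbers, not sequence alignment; renumbered receptors must be mapped by
  the user first.
* The PDB reader handles fixed-column ATOM/HETATM/MODEL records only (the
  formats the pipeline emits); mmCIF and binary trajectory formats are out
  of scope.
* Clustering at tens of thousands of frames is quadratic; subsample first.
* Whether reported Kd/h derive from the same joint fit as Bmax is exposed
  rather than resolved: `fit_binding_hill()` reports them jointly, and h is
  a per-fit free parameter.

## A worked example

```{r example, eval = FALSE}
base <- make_toy_receptor(30, pair_distance_A = 3.0)
traj <- make_trajectory(
  trajectory_spec(n_frames = 10000, pair_mean_A = 3.0, seed = 101,
                  transition_frame = 7000, post_mean_A = 6.0), base)
tyr <- tyr_pair_report(traj)
clash <- gprotein_dock_assess(get_frame(traj, 10000),
                              make_template_complex(1.0))
classify_bias(tyr, clash)
```
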