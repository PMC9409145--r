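# apelinbias

Structural and pharmacological diagnostics of ligand bias at the apelin
receptor (APLNR/APJ), a class-A GPCR that signals through both Gi proteins
and beta-arrestin.

A biased agonist preferentially activates one transducer. This package
implements, as tested and reproducible code, the two-observable structural
diagnostic used to call that bias from molecular-dynamics trajectories,
together with the quantitative pharmacology of the beta-arrestin recruitment
assay:

* **Tyrosine gate (TM5-TM7).** For the Tyr221/Tyr309 hydroxyl pair the
  package reports both donor-direction distance series
  (`Tyr309O-HTyr221`, `Tyr221O-HTyr309`) and the hydrogen-bond occupancy:
  the fraction of frames whose donor-acceptor O...O distance lies in the
  optimal window [2.7, 3.3] A. A persistent bond (occupancy >= 0.5 by
  default) marks a beta-arrestin-competent conformation.
* **G-protein cavity clash.** The receptor conformer (top GROMOS cluster
  centroid) is Kabsch-superposed into a receptor/G-protein template complex
  on shared CA atoms, the template receptor is discarded, and Arg127 (TM3)
  is tested against the G-alpha Tyr356 for van der Waals overlap: a pair
  closer than the radius sum minus a 0.4 A tolerance precludes G-protein
  docking.
* **Classification.** `classify_bias()` maps (occupancy, clash) to
  *beta-arrestin-biased* (persistent AND clash), *G-protein-competent*
  (neither), or *indeterminate*.
* **Assay pharmacology.** Saturation binding with Hill slope
  B(x) = Bmax x^h / (Kd^h + x^h); the Black-Leff operational model of
  partial agonism E(A) = Em tau^n A^n / ((KA + A)^n + tau^n A^n); Hill
  inhibition R(x) = bottom + (top - bottom)/(1 + (x/IC50)^s); and Bmax
  normalization against a reference full agonist (apelin-13 = 100%). All
  fits are deterministic multi-start Levenberg-Marquardt in log-parameter
  space.

Supporting machinery: a multi-model PDB reader/writer with a uniform
topology + coordinates data model, atom selection, Kabsch superposition and
RMSD traces, geometric hydrogen-bond detection, Shrake-Rupley SASA with
Monte-Carlo volume, ligand contact-residue tables, GROMOS (Daura)
conformational clustering, and a synthetic-data generator
(structures, trajectories with a controlled tyrosine-pair distance process,
template complexes with exact separations, assay tables with known
parameters) so the whole pipeline is testable without external downloads.

## Worked example

An epicatechin-like scenario: the tyrosine-pair bond holds near 3.0 A for
70% of a 10,000-frame run, then opens to 6.0 A; the induced conformer
blocks the G-protein cavity (template separation 1.0 A).

```r
library(apelinbias)
base <- make_toy_receptor(30, pair_distance_A = 3.0)
traj <- make_trajectory(
  trajectory_spec(n_frames = 10000, pair_mean_A = 3.0, seed = 101,
                  transition_frame = 7000, post_mean_A = 6.0), base)
tyr <- tyr_pair_report(traj)
clash <- gprotein_dock_assess(get_frame(traj, 10000),
                              make_template_complex(1.0))
classify_bias(tyr, clash)
#> <bias_report> call = beta-arrestin-biased
#>   - Tyr-pair donor-acceptor window occupancy 0.701 >= threshold 0.50 -> hydrogen bond persistent
#>   - Arg127 vs Tyr356 min heavy-atom distance 0.94 A (vdW overlap tolerance 0.40 A) -> clash TRUE
#>   - Clash is computed from van der Waals overlap, a deterministic stand-in for visual inspection of the docked G protein.
```

The occupancy 0.701 is the fraction of frames inside the optimal window —
by construction the bond holds in the first 70% of the run. The clash
report's 0.94 A minimum distance is far below the N/O threshold
1.55 + 1.52 - 0.4 = 2.67 A, so a G protein cannot dock and the ligand is
called beta-arrestin-biased. A run with the pair open throughout (mean
6.1 A) and a free cavity (separation 8.0 A) yields `G-protein-competent`.

On the assay side:

```r
x <- 10^seq(-15, -7, length.out = 12)
d <- make_assay(assay_spec("hill_binding",
                           list(Bmax = 801286, Kd = 2.508e-11, h = 0.2202),
                           doses_M = x, seed = 1))
fit_binding_hill(d)
#> <binding_fit> Bmax = 8.013e+05 RLU, Kd = 2.508e-11 M, h = 0.2202 (SSE 5.144e-19)

normalize_bmax(c("apelin-13" = 801286, "EC" = 810100,
                 "EC+ML221" = 733981), "apelin-13")
#>       label   Bmax   percent percent_report
#> 1 apelin-13 801286 100.00000          100.0
#> 2        EC 810100 101.09998          101.1
#> 3  EC+ML221 733981  91.60038           91.6
```

Bmax, Kd and the Hill slope are recovered exactly from noiseless data, and
the normalized maximal binding is 101.1% for EC and 91.6% for EC + ML221
relative to apelin-13.

## Command line

A thin dispatcher over the same functions ships in `inst/scripts`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","apelinbias.R", package="apelinbias"))')" \
  bias-report --config config.yaml
```

Subcommands: `distances`, `hbonds`, `rmsd`, `sasa`, `cluster`, `clash`,
`bias-report`, `fit`, `simulate`. Each run is driven by a YAML config,
echoes it into a log with the package version and seed, and writes a
manifest; exit codes are 0 (ok), 1 (user error), 2 (internal error).

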