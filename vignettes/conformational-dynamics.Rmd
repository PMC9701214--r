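---
title: "Conformational dynamics metrics for engineered cofactor specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational dynamics metrics for engineered cofactor specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confdyn)
```

## The scientific problem

Water-forming NADH oxidases (Nox) regenerate oxidized nicotinamide
cofactors. Engineering them to accept truncated, noncanonical cofactors
(such as NMNH or N-methyl-1,4-dihydronicotinamide, MNAH) removes the
adenosine "handle" that normally anchors the cofactor in the Rossmann
fold. The working hypothesis this package operationalizes is mechanistic:
with the small cofactor bound, the wild-type enzyme's active-site loops
become excessively flexible, the nicotinamide rattles out of the pocket,
and the geometry required for hydride transfer to FAD is rarely sampled.
Allosteric mutations that pack the vacated adenosine cleft rigidify the
loops and restore productive sampling.

`confdyn` quantifies that story with three ensemble metrics, each applied
to a conformational ensemble stored as a multi-model PDB file:

1. **Loop flexibility.** Every frame is superposed on a reference model
   using all alpha carbons of the analysis chain (Kabsch least-squares
   superposition, reflection-corrected SVD), then the RMSD of the
   loop-region alpha carbons is computed *without re-fitting*. The
   global-fit/local-no-refit protocol measures loop displacement relative
   to the protein's rigid body rather than alignment residual. The default
   regions are the three Rossmann-fold loops enveloping the AMP moiety,
   residues 153–157, 177–188 and 238–242 (inclusive, 1-based, taken
   verbatim from the coordinate file).
2. **Hydride-transfer occupancy.** The per-frame distance between the
   nicotinamide C4 (hydride donor) and flavin N5 (acceptor), classified
   at a 4.5 Å threshold into active and inactive poses. Distances are
   deliberately not capped: once the cofactor has left the cavity its
   exact distance is biologically meaningless, and only the binary
   classification enters the summary. Equality at the threshold counts as
   active so the boundary case is deterministic.
3. **Free-energy landscape.** Backbone φ/ψ dihedrals of every residue
   (φ undefined at the first residue, ψ at the last, so a chain of R
   residues yields 2R − 2 angles) are pooled over *all* conditions,
   standard-scaled to zero mean and unit variance, and reduced by PCA.
   Each condition is projected with the shared scaling and basis — fitting
   per condition would make the projections incomparable, which is why the
   pipeline refuses to do it. Free energies are the Boltzmann inversion of
   the 2-D histogram density, `F = −ln p`, shifted so the occupied minimum
   is zero. Units are kT: no temperature factor is applied, and the
   documentation says so rather than guessing a conversion. K-Means
   (k-means++ seeding, 10 restarts, Lloyd iterations) on the pooled
   projections assigns conformational states, relabelled A, B, C, … by
   ascending PC1 coordinate of their centers so the lettering is
   deterministic.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| loop regions | 153–157, 177–188, 238–242 | Rossmann-fold loops lining the AMP pocket |
| distance threshold | 4.5 Å | maximum C4–N5 separation for an active pose |
| histogram bins (flexibility) | 30 over [0, max] | display resolution only |
| landscape bins | 60 × 60 | free-energy surface grid over the pooled bounding box |
| k (states) | 3 | number of conformational states |
| k-means seed | 0 | initialization stream for k-means++ |
| dihedral mode | `raw` | `sincos` optionally maps each angle to its (sin, cos) pair |

The standard deviation reported for loop RMSD is the sample standard
deviation (n − 1): the frames are a finite sample of the ensemble.
Standard scaling for the landscape uses the population standard deviation
(divide by n); the choice only rescales the latent axes globally and is
fixed for reproducibility. PCA component signs are made deterministic by
forcing the largest-magnitude loading of each component positive.

Raw dihedral angles live on a circle, and PCA of raw angles distorts
basins near the ±180° seam. The default remains raw-angle PCA because
that is the convention this analysis follows; `mode = "sincos"` is the
classical dihedral-PCA alternative and is exercised in the test suite
with basins straddling the seam. The synthetic generator places its
default basins away from the seam so both modes agree there.

An alternative reading of "alpha-carbon dihedrals" — pseudo-torsions over
four consecutive CA atoms — exists in the literature; this package
implements the φ/ψ reading and does not build the pseudo-torsion variant.

## The synthetic generator and what it does (not) emulate

Production MD trajectories for this system are hundreds of nanoseconds
long and are not redistributable, so the package ships a generator
(`synthetic_spec()`, `simulate_ensemble()`) whose output has *known*
ground truth:

- **Backbone.** An idealized N–CA–C backbone (bonds 1.458 / 1.525 /
  1.329 Å, angles 111° / 117° / 121°, ω = 180°) rebuilt every frame from
  internal coordinates by sequential NeRF placement. Backbone dihedrals
  hop among prescribed (φ, ψ) basins under a row-stochastic Markov chain,
  plus Gaussian angular noise. The torsion measurer and the builder are
  exact inverses (verified to 10⁻⁶ degrees in the tests), so prescribed
  basins are recovered exactly at zero noise.
- **Loop jitter.** Atoms inside named regions receive iid Gaussian
  Cartesian jitter with per-coordinate σ. The expected mean region RMSD
  is then σ√3 (E‖Δ‖² = 3σ² per atom), giving flexibility recovery an
  analytic target. Because jitter is applied after backbone building it
  corrupts local dihedrals; landscape scenarios therefore use jitter-free
  specs and flexibility scenarios use single-basin specs. This test
  matrix is deliberate.
- **Ligand.** A two-state bound/unbound process: iid Bernoulli with a
  prescribed bound fraction (study conditions: 0.74, 0.01 and 0.60),
  bound distances drawn near 3.1 Å (the crystallographic C4–N5 contact)
  and unbound distances near 9 Å with σ = 1 Å — far enough above the
  4.5 Å threshold that misclassification is negligible (≈3 × 10⁻⁶ per
  frame), which matters for recovering a 1% occupancy within binomial
  error. The donor sits on a fixed axis from a static acceptor so the
  sampled distance is exact by construction. Binding is iid rather than
  autocorrelated so occupancy recovery tests can use plain binomial
  standard errors.

All randomness flows from one root seed through named substreams (chain,
dihedrals, jitter, ligand): adding jitter to a spec does not change its
ligand draws.

What the generator does **not** emulate: force-field energetics, solvent,
side chains, correlated loop motions, cofactor-protein contacts, or
kinetic realism of any sort. Passing recovery tests therefore demonstrates
that the *analysis pipeline* is correct and well-calibrated — not that the
published trajectory statistics are reproduced, which is impossible
without the trajectories themselves.

## Numerical choices and degenerate inputs

- Kabsch superposition requires ≥3 non-collinear points; rank-deficient
  cross-covariance raises a degenerate-geometry error. Reflections are
  corrected by flipping the axis of the smallest singular value.
- The PDB reader enforces model-to-model atom consistency (error names
  the offending model), reports unparseable fields with line numbers,
  keeps the first altloc, and rejects insertion codes outright: synthetic
  and refined-model inputs never carry them, and mishandling them would
  silently corrupt residue-number selections. Coordinates of magnitude
  ≥10⁴ Å refuse to format (fixed-column overflow).
- Zero-variance dihedral columns make standard scaling undefined; the
  error names the column and the pipeline records the failure while other
  stages proceed.
- `free_energy_surface()` masks empty bins as `NA` rather than inventing
  an energy; a degenerate (zero-extent) bounding box is an error.
- K-Means with more clusters than distinct points is an error; ties in
  occupancy are impossible by construction since labels partition frames.

## Library-coverage arithmetic

`theoretical_diversity()` enumerates the scheme's codon table (NNK: 32
codons per site, all 20 amino acids, one stop, TAG) rather than trusting
constants; three NNK sites give 20³ = 8000 protein variants over
32³ = 32768 codon combinations. `coverage_stats()` uses the Poisson
approximation with uniform variant abundance: fold coverage N/V, expected
fraction observed 1 − e^(−N/V), completeness (1 − e^(−N/V))^V. Real
libraries are skewed; the uniform assumption matches the back-of-envelope
usage these numbers have in library design, and is a documented
limitation.

## Problem sizes used in validation

The validation suite runs the generator at sizes chosen to make the
statistical targets sharp while staying desk-scale: occupancy recovery at
5000 frames (3 binomial SEs at p = 0.01 is ±0.42%), flexibility recovery
at 2000 frames and 60 residues with 10 jittered residues (σ√3 within 5%;
the global CA fit absorbs ≈3% of the jitter, which sits inside that
band), and landscape recovery at 1500–5000 frames and 8 residues with
basin separations ≥105° at 10° noise (k-means occupancy error well under
2% absolute). Replicate pooling, where it arises, concatenates frames
rather than averaging replicate summaries.

## A worked example

```{r example, eval = FALSE}
library(confdyn)

# three synthetic conditions mirroring the study design
mk <- function(seed, bound, sigma) {
  regions <- region_set(tibble::tibble(
    region = "loop", chain_id = "A", start = 20L, end = 29L
  ))
  regions$sigma <- sigma
  spec <- synthetic_spec(
    n_residues = 60, n_frames = 2000, seed = seed,
    bound_fraction = bound, jitter_regions = regions
  )
  list(
    ensemble = simulate_ensemble(spec)$ensemble,
    reference_ensemble = build_reference(60), chain = "A"
  )
}
config <- analysis_config(
  conditions = list(
    wt_nadh = mk(1, 0.74, 0.50),
    wt_mnah = mk(2, 0.01, 0.635), # flexible: 1.27x the loop RMSD
    mut_mnah = mk(3, 0.60, 0.50)
  ),
  regions = "20-29"
)
report <- run_analysis(config)
report$flexibility
report$occupancy
```

The flexible condition shows ≈1.27× the loop RMSD of the rigid ones and
≈1% active-pose occupancy, the qualitative signature the metrics are
built to expose.

## Known limitations

- Single-chain analyses only; multi-chain files need explicit chain
  filters, and the two cofactor copies of a dimeric assembly are treated
  as separate measurements.
- Only the MODEL/ENDMDL multi-model PDB dialect is read; binary MD
  formats are out of scope for desk-scale ensembles.
- No RMSF profiles, no Markov-state modelling, no kinetics: occupancies
  are thermodynamic (frame-count) quantities.
- Free energies are reported in kT with no temperature conversion.
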