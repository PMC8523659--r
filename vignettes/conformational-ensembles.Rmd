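---
title: "Quantifying CDR conformational space in single-domain antibodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CDR conformational space in single-domain antibodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrflex)
```

## The problem

Single-domain (VHH) antibodies bind antigen through three
complementarity-determining region (CDR) loops carried on a conserved
framework beta-sandwich. How much conformational space those loops explore
at equilibrium bears directly on the molecule's thermal stability and
binding behavior: a loop that wanders between conformations pays an
entropic and packing cost that a restrained loop does not. `cdrflex`
quantifies that exploration for conformational ensembles — molecular
dynamics trajectories or any other multi-model source — with four
complementary instruments:

1. **Per-CDR Cα-RMSD after framework superposition.** Each frame is rigidly
   superposed onto the reference using only framework Cα atoms (a Kabsch
   least-squares fit with reflection correction), and the RMSD of one CDR's
   Cα atoms is recorded. Framework motion is removed; loop motion relative
   to the scaffold remains.
2. **Fraction of native contacts (Q).** With native heavy-atom contact
   pairs $(i,j)$ and native distances $r^0_{ij}$ frozen from the reference
   structure,
   $$Q(X) = \frac{1}{N}\sum_{(i,j)}
     \frac{1}{1 + \exp\!\left[\beta\,(r_{ij}(X) - \lambda\, r^0_{ij})\right]}$$
   soft-counts how many native contacts remain formed in frame $X$.
   Defaults: $\beta = 5\ \text{Å}^{-1}$ (switch steepness),
   $\lambda = 1.8$ (the all-atom tolerance for a formed contact's thermal
   fluctuation), native pairs at $\le 4.5$ Å with sequence separation
   $> 3$ residues. Q needs no superposition and is exactly rigid-invariant.
3. **Convergence diagnostics.** Burn-in discard, a post-burn-in stability
   check (population standard deviation of the global Cα-RMSD below 1.0 Å),
   a half-split histogram-overlap check, and a deterministic outlier-run
   flag.
4. **Conformational-space profiles.** Pooled post-burn-in samples are
   summarized as peak-normalized Gaussian kernel densities, and the
   coupling of the two observables is reported as pooled (plus per-run)
   Pearson and Spearman correlations of Q against a CDR's RMSD.

## Region annotation

Regions follow the IMGT delimitation of a heavy-chain variable domain:
FR1 1–26, CDR1 27–38, FR2 39–55, CDR2 56–65, FR3 66–104, CDR3 105–117,
FR4 118–128. The boundaries are configuration data, not constants:
deposited or renumbered structures sometimes place CDR3 insertions
sequentially, pushing FR4 beyond 128, and published mutant nomenclature
occasionally implies such a scheme. Users supply either a two-column TSV
mapping residue ordinals to scheme positions (insertion suffixes like
`112A` inherit the integer part's region) or use identity numbering when
the coordinate file is already numbered on the scheme. Automatic numbering
from raw sequence is out of scope — it is the job of dedicated alignment
tools, and the analysis itself only needs the mapping.

## Numerical choices

* **Superposition** fits Cα atoms only, unweighted: the analysis reports
  Cα-RMSDs exclusively, so mass weighting would be immaterial. Degenerate
  (rank < 2) point sets and fits with fewer than 3 atoms are errors. The
  reflection branch is corrected by flipping the smallest singular
  direction, so the rotation determinant is always +1.
* **Contacts** are computed once from the reference and frozen for every
  frame and run: Q always compares to one native state. Hydrogens are
  excluded even when present. Sequence separation is measured on author
  residue numbering, so numbering gaps count as sequence distance.
* **Burn-in** is a frame fraction, not a time, so synthetic and imported
  trajectories share one code path. The pipeline default, 6/11, mirrors
  discarding the first 600 ns of a 1.1 µs trajectory; analyses then run on
  the retained tail (the half-split check can be switched to the full
  series with `convergence.split_after_burn_in: false`).
* **"Substantial" half-split overlap** is operationalized as the histogram
  overlap coefficient $\sum_k \min(p_{1k}, p_{2k}) \ge 0.5$ on shared
  Freedman–Diaconis bins computed from the pooled series (20 equal bins if
  the IQR is zero; a constant series counts as overlap 1). The coefficient
  is symmetric in the halves and invariant under affine rescaling of the
  series.
* **Outlier runs** are flagged when a run's mean deviates from the median
  of run means by more than `k = 3` times the raw median absolute
  deviation of the run means *and* by more than 0.5 Å. The absolute floor
  is deliberate: among well-behaved replicates the run means differ by
  milliångströms, the MAD is correspondingly tiny, and a purely relative
  rule would flag one of them in a sizable fraction of datasets. A
  deviation that small is never scientifically an outlier, so the floor is
  expressed in the measurement's own units. The flag is advisory — the
  pipeline reports it and excludes flagged runs only when
  `convergence.exclude_outliers` is set.
* **KDE** uses a Gaussian kernel with Silverman's rule-of-thumb bandwidth
  (overridable) on a 512-point grid spanning [min − 3h, max + 3h], then
  divides by the maximum so the peak is exactly 1 — a display convention;
  normalization never moves the argmax or changes modality. Reported means
  and standard deviations are plain sample moments and bypass the KDE
  entirely. A zero-spread sample yields a flagged single-point profile
  instead of aborting the pipeline.
* **Correlation** is reported pooled (the headline, matching how merged
  trajectories are usually plotted) and per-run (the diagnostic, because
  pooling across runs with different means can inflate a correlation).

## The synthetic-ensemble generator

No public trajectories accompany the kind of study this package serves, so
validation rests on a generator whose ground truth is known exactly.

**Scaffold.** `build_scaffold()` lays a Cα trace along a serpentine path
through a compact cubic lattice with 3.8 Å spacing, plus a small seeded
jitter (σ = 0.015 Å). Consecutive Cα atoms sit at 3.8 ± 0.1 Å (the
trans-peptide Cα–Cα distance), no two non-consecutive atoms come closer
than 3.5 Å, and lattice adjacency guarantees a substantial native contact
set (≥ 50 pairs at the default 128 residues) — the three properties the
analyses actually need from a "folded" reference. It is a synthetic
stand-in, not a physical model: no excluded-volume chemistry, no secondary
structure, no side chains (an optional pseudo-side-chain mode adds atoms
1.5 Å from each Cα).

**Ensembles.** Frame $k$ of run $r$ is the reference plus (i) independent
isotropic Gaussian displacements whose per-coordinate σ is set per region,
(ii) optionally a discrete alternative conformation of one region — a
frozen random displacement direction per residue, scaled to a set
magnitude and drawn with a mixture weight — and (iii) a random rigid
motion of the whole frame. Every (run, frame, stage) triple reseeds R's
RNG from its own 31-bit substream (run seed = `xor(base_seed, run)`;
exact stream separation holds for up to 2047 frames per run), and region
σ values only *scale* standard-normal draws. Two consequences matter for
testing: ensembles are bit-reproducible, and changing one region's σ
leaves every other region's displacement draws — and the rigid-motion
draws — bitwise untouched, so independence tests can assert exact
equality.

**What the generator does not emulate.** Displacements are i.i.d. across
frames: there is no temporal autocorrelation, no slow relaxation, and no
force field. Tests passing on this generator therefore validate the
*estimators* (superposition, Q, pooling, densities, convergence rules) on
distributions with known parameters; they do not validate force-field
physics, nor do the synthetic Q and RMSD magnitudes correspond to any real
antibody's.

**The `vhh_contrast` preset** encodes, at desk scale, the qualitative
contrast between a flexible and a conformationally restrained VHH: two
systems share one 128-residue scaffold and differ in CDR1 dynamics. The
"broad" system has CDR1 σ = 1.5 Å and hops into an alternative CDR1
conformation (2.5 Å displacement, 25% occupancy); the "narrow" system
keeps CDR1 in a single basin (σ = 0.5 Å). Both use CDR3 σ = 1.8 Å >
CDR1 σ > CDR2 σ = 0.3 Å (the canonical VHH mobility ordering, CDR3 being
the long antigen-binding loop and CDR2 a short rigid one), framework
σ = 0.15 Å (a rigid beta-sandwich core), per-frame rigid noise of 5° / 1 Å
to exercise the superposition, and 5 runs × 200 frames. The two-state
CDR1 mixture is what couples CDR1 motion to Q strongly enough to mirror
the empirically observed Q-versus-CDR1-RMSD anti-correlation: CDR1 touches
only ~13% of the native contacts, so independent within-basin jitter alone
dilutes the pooled correlation to around −0.25, whereas discrete loop-state
hopping — the mechanism believed to underlie broad CDR1 distributions in
real VHHs — both broadens the RMSD density and breaks a coherent block of
contacts. These values were fixed once, at design time, from the physical
picture above, and are not tuned per dataset.

Problem sizes throughout the package's own validation (5 runs × 200
frames × 128 residues, pooled n = 455 after burn-in) were chosen as the
smallest at which the distributional contrasts are comfortably resolved.

## Worked example

```{r example, eval = FALSE}
library(cdrflex)

cfg <- default_config(output_dir = "contrast_out", seed = 1)
res <- run_pipeline(cfg)

# breadth contrast between the two systems
res$compare$rmsd_broader   # "broad"
res$broad$q$mean           # pooled Q, flexible system
res$narrow$q$mean          # pooled Q, restrained system
res$broad$correlation$spearman_rho  # Q vs CDR1 RMSD, pooled
```

Per system the pipeline writes `contacts.csv`, `rmsd_series.csv` (global
and per-CDR), `q_series.csv`, `convergence.json`/`.csv`, density CSVs with
a JSON sidecar, `correlation.json` and `summary.json`; a `manifest.json`
echoes the configuration and seed, and every number in `summary.json` is
recomputable from the stage CSVs. Identical configuration gives
byte-identical outputs.

To analyze externally produced trajectories instead, point the
configuration's `inputs` section at a reference PDB and one multi-model
PDB per run, with a numbering TSV (or `identity`); binary trajectory
formats should be converted to multi-model PDB by the user's MD tooling.

## Known limitations

* Single-chain analysis: only one chain of a multi-chain file is kept
  (VHHs are single-domain); select it explicitly via `chain`.
* No insertion-code-aware renumbering; the numbering map is the user's
  responsibility.
* The generator's frames are temporally uncorrelated, so it cannot be used
  to study autocorrelation-aware equilibration detection — which is also
  why the convergence module implements threshold rules rather than
  statistical-inefficiency estimators.
* Q is computed over heavy atoms; an all-atom variant including hydrogens
  is deliberately not offered, since contact conventions with hydrogens
  are force-field dependent.
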