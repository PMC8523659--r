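# cdrflex

Conformational-ensemble analysis of single-domain (VHH) antibody CDR
loops, for structural bioinformaticians who have ensembles — molecular
dynamics trajectories exported as multi-model PDB, or any other
multi-conformation source — and want reproducible, scriptable answers to
the question: *how much conformational space does each CDR explore, and
how does that exploration relate to the integrity of the native fold?*

## What it computes

- **Framework-superposed per-CDR Cα-RMSD.** Each frame is superposed onto
  the reference on framework Cα atoms only (Kabsch least-squares fit,
  reflection-corrected), then the Cα-RMSD of one CDR is recorded — the
  standard mobility metric for antibody loops.
- **Fraction of native contacts.** With native heavy-atom pairs (i, j) and
  native distances r⁰ᵢⱼ frozen from the reference:

      Q(X) = (1/N) Σ(i,j) 1 / (1 + exp[β (rᵢⱼ(X) − λ r⁰ᵢⱼ)])

  with β = 5 Å⁻¹, λ = 1.8, native pairs at ≤ 4.5 Å and sequence
  separation > 3 residues (all configurable).
- **Convergence diagnostics.** Burn-in discard (default 6/11 of frames),
  post-burn-in stability (population σ of the global Cα-RMSD < 1.0 Å),
  half-split histogram overlap (coefficient ≥ 0.5), and an advisory
  MAD-based outlier-run flag.
- **Conformational-space profiles.** Peak-normalized Gaussian KDE of the
  pooled post-burn-in RMSD and Q samples, plus pooled and per-run
  Pearson/Spearman correlation of Q against a CDR's RMSD, and a breadth
  comparison between systems.
- **A synthetic-ensemble generator** (compact self-avoiding Cα scaffolds;
  per-region Gaussian flexibility; optional two-state alternative loop
  conformations; per-frame rigid noise) with exact, seeded ground truth —
  the package's validation backbone.

Regions follow the IMGT delimitation (FR1 1–26, CDR1 27–38, FR2 39–55,
CDR2 56–65, FR3 66–104, CDR3 105–117, FR4 118–128), overridable in the
configuration; residue numbering comes from a two-column TSV map or from
the coordinate file itself.

## Worked example

```r
library(cdrflex)

cfg <- default_config(output_dir = "contrast_out", seed = 1)
res <- run_pipeline(cfg)

res$compare$rmsd_broader            # "broad"
res$broad$rmsd_profile$sample_std   # 0.5304288  (Å, pooled CDR1 RMSD)
res$narrow$rmsd_profile$sample_std  # 0.1036613
res$broad$q$mean                    # 0.9721707  (pooled Q)
res$narrow$q$mean                   # 0.9830791
res$broad$correlation$spearman_rho  # -0.4591919
```

This runs the `vhh_contrast` preset — two 128-residue synthetic systems
sharing one scaffold, a flexible "broad" CDR1 (σ 1.5 Å plus a 25%-occupied
alternative loop conformation) against a restrained "narrow" one (σ 0.5 Å),
5 runs × 200 frames each — and analyzes both ends to end. The numbers
above say: the flexible system's CDR1 explores a five-fold broader RMSD
distribution, its native-contact fraction is lower on average, and Q
anti-correlates with CDR1 displacement (ρ ≈ −0.46), the signature of loop
excursions breaking native packing. Per system the output directory holds
`rmsd_series.csv`, `q_series.csv`, `contacts.csv`, `convergence.json`,
density CSVs, `correlation.json` and `summary.json`; outputs are
byte-reproducible for a fixed configuration.

To analyze your own trajectories, replace the `generator` section of the
configuration with an `inputs` section (reference PDB, one multi-model PDB
per run, numbering map or `identity`) — see
`inst/extdata/default_config.yaml` and the vignette.

A thin CLI wrapper is available at `inst/cli/cdrflex.R`
(`run` / `simulate` / `validate` subcommands).

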