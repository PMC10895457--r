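# allodyn

Trajectory-ensemble analytics for allosteric coordination in large protein
complexes — built for the kind of question raised by chaperone machines
(Hsp90/Hsp70/Hop/p23 with a client such as the glucocorticoid receptor):
which residue pairs move in a coordinated way, how the assembly responds
when a nucleotide is removed or hydrolysed, and which regions are
energetically rigid (folding cores) or loose (soft spots, candidate
interfaces).

The package implements four analysis stages over coordinate ensembles,
plus a synthetic-ensemble generator with known ground truth so everything
is testable without microsecond trajectories:

- **Distance fluctuations (DF).** For Cα sites *i, j*,
  `DF_ij = ⟨(d_ij − ⟨d_ij⟩)²⟩` — the variance of the inter-residue
  distance over all frames of a (meta)trajectory. Low DF = quasi-rigid,
  coordinated motion. With 40×40 block averaging, few-shade quantized
  views, state-difference maps and per-residue coordination profiles.
- **D-NEMD response (Kubo–Onsager subtraction).** Branch points extracted
  every 20 ns after a 100 ns discard; the response of residue *r* at
  relative time *t* is the mean over branch pairs of
  `|x_pert(r,t) − x_unpert(r,t)|`, with across-pair standard errors.
- **MLCE.** Eigendecomposition `M_ij = Σ_α λ_α v_iα v_jα` of a residue-pair
  interaction-energy matrix, low-rank reconstruction over the most negative
  eigenvalues, Hadamard masking by a 6 Å Cα contact matrix, and extraction
  of strongest-coupling cores and weakest-coupling soft spots as contiguous
  residue segments.
- **Descriptors & clustering.** RMSD series, per-residue RMSF versus the
  average structure, and conformational-family clustering (align on ordered
  regions, cluster on disordered-region RMSD, hierarchical agglomeration
  with silhouette-based cluster-count selection, medoid representatives).

I/O: PDB and multi-model PDB (read/write, B-factor annotation), DCD
(read/write), residue-labelled TSV matrices, YAML configs and JSON
manifests. See `vignettes/ensemble-analytics.Rmd` for the methods account.

## Worked example

The repository is organised as an analysis workflow: numbered drivers
under `analysis/` run the full study on a synthetic two-state system and
write tables under `results/`.

```sh
Rscript analysis/01_simulate.R             # generate the study system
Rscript analysis/03_distance_fluctuation.R # DF matrices + difference map
Rscript analysis/04_dnemd.R                # branch schedule + response
Rscript analysis/05_mlce.R                 # cores and soft spots
```

Stage 01 builds a 40-residue elastic-network protein in two "ligand
states": the coupled state carries springs linking residues 1–8 to 33–40,
the decoupled state lacks them. Stage 03 then prints:

```
coupled   state: 200 frames, mean DF 0.017 A^2, profile range 0.013-0.020 A^2
decoupled state: 200 frames, mean DF 0.037 A^2, profile range 0.029-0.056 A^2

DF difference (decoupled - coupled): top decile of pairs is
9.2x enriched in the planted site1 x site2 block (residues 1-8 x 33-40).
```

i.e. the DF difference map localises the coordination loss to exactly the
residue-pair block whose coupling was removed — the planted analogue of
comparing nucleotide states of a chaperone complex. Stage 04 prints:

```
Branch schedule (discard 100 ns, every 20 ns): 176 points, 44 per replica
Response at t = 5 ns: residue 5 deviates 1.000 A (planted 1.0 A);
largest off-target deviation 0.0000 A across 10 pairs.
```

— four 1-μs replicas give 44 branch points each, and the Kubo–Onsager
subtraction recovers the planted 1 Å perturbation exactly while every
unperturbed residue stays at zero. Stage 05 prints:

```
Folding-core segments: 10-14 (-8.06 kcal/mol)
Soft-spot segments:    30-34 (-0.02 kcal/mol)
Planted core 10-14: 5/5 recovered; planted soft patch 30-33: 4/4 recovered.
```

The same machinery is exposed as functions (`compute_df()`,
`compute_response()`, `mlce()`, `cluster_conformations()`, ...) and as a
single-config pipeline:

```r
library(allodyn)
paths <- make_demo(seed = 1, dir = "demo")
run_pipeline(paths$config)   # writes TSV/PDB outputs + manifest.json
```

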