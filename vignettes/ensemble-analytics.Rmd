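---
title: "Methods: distance fluctuations, D-NEMD responses and local coupling energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance fluctuations, D-NEMD responses and local coupling energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allodyn)
```

allodyn implements the analysis layer used to interrogate
molecular-dynamics ensembles of large chaperone–client assemblies (Hsp90,
Hsp70, Hop, p23 and a client such as the glucocorticoid receptor): where in
the complex residues move in a coordinated way, how the complex responds
when a nucleotide perturbation is introduced, and which regions are
energetically nailed down or loose. The MD engine, force-field work and the
MM/GBSA evaluation that produces interaction-energy matrices are all
upstream of this package; its inputs are coordinate ensembles, structures
and plain-text energy matrices. Units are fixed throughout: lengths in
Å, times in ns, energies in kcal/mol. Residues are always identified by
author (PDB) numbering; matrices use positional indices with an explicit
label map, so the two can never be silently conflated.

## Distance fluctuations

For sites $i, j$ (one Cα per residue) and frame set $F$, the
distance-fluctuation statistic is the variance of the inter-site distance

$$\mathrm{DF}_{ij} \;=\; \bigl\langle (d_{ij} - \langle d_{ij}\rangle)^2
\bigr\rangle ,$$

with $\langle\cdot\rangle$ the average over all frames of the (meta)
trajectory. Low DF means the pair maintains its separation — it moves
quasi-rigidly, which is read as allosteric coordination; high DF means
uncoordinated motion. `compute_df()` uses an exact two-pass variance
(mean pass, then squared-deviation pass) rather than a streaming
single-pass update, so results are bit-stable against naive reference
implementations. The square root is available via `statistic = "sd"`; the
convention used is recorded in the object. Because $d_{ij}$ is an internal
coordinate, DF is invariant to any per-frame rigid-body motion; aligning a
metatrajectory before DF is harmless but unnecessary, and the test suite
pins this invariance at $10^{-9}$ Å².

Coarse views follow the standard rendering: `block_average()` averages the
$N \times N$ matrix over $b \times b$ residue blocks (default $b = 40$, so
a full block pools 1600 pairs), with trailing partial blocks averaged over
their actual pair counts rather than padded — padding would bias edge
blocks low. `quantize_df()` bins the block matrix into a small number of
equal-width shades (default 5) spanning the observed range; the bin edges
are not part of the published convention, so equal-width over the observed
range is used and the maximum maps to the top shade. `df_difference()`
subtracts two states over identical residue labels, and `df_profile()`
gives each residue's mean coordination with all partners or with a named
subset (e.g. "coordination with the client only").

## D-NEMD response (Kubo–Onsager subtraction)

The dynamical non-equilibrium protocol branches many short perturbed runs
off an equilibrium trajectory and measures, at matched relative times, the
average deviation between each perturbed run and its unperturbed
continuation. Averaging over branch pairs cancels the intrinsic
fluctuations common to both members; what survives is the response to the
perturbation.

`extract_branch_points()` implements the branching schedule: per replica,
frames on the grid `discard + k * interval` (defaults 100 ns and 20 ns).
The schedule is data-driven over the time stamps actually present — the
pair count is never hard-coded. Under the production layout this package
emulates (four 1-μs replicas sampled every 20 ns, frame $k$ stamped
$(k-1)\,\Delta t$ so stamps run 0–980 ns), the schedule yields 44 branch
points per replica, 176 in total.

`compute_response()` computes, for residue $r$ at relative time $t$,

$$R_r(t) = \frac{1}{P}\sum_{p=1}^{P}
  \bigl\lVert x^{\mathrm{pert}}_{p}(r,t) - x^{\mathrm{unpert}}_{p}(r,t)
  \bigr\rVert ,$$

the mean over pairs of per-residue deviation norms (the established
D-NEMD practice; the norm-of-mean-displacement alternative is exposed as
`metric = "norm_mean"` for sensitivity checks). Uncertainty is the
across-pair standard error with no autocorrelation correction — branch
points are distinct equilibrium configurations by construction. Two
numerical choices matter here. First, each perturbed frame is by default
superposed onto its paired unperturbed frame over all sites before
subtraction, removing rigid-body drift that would otherwise swamp local
signal; whether the original protocol fitted before subtracting is not
documented, so the flag `superpose_first` keeps both paths open, and an
exactly identical pair short-circuits the fit so a null perturbation is an
exact zero rather than rotation round-off. Second, per-pair deviations are
accumulated by sorted summation, which makes the profile bit-identical
under any reordering of the pairs. `response_snapshot()` extracts the
per-residue response at one time and writes it into a structure's B-factor
column for 3-D rendering.

## MLCE: folding cores and soft spots

A symmetric residue-pair non-bonded interaction-energy matrix $M$ is
eigendecomposed, $M_{ij} = \sum_\alpha \lambda_\alpha v_{i\alpha}
v_{j\alpha}$. The most negative eigenvalues carry the dominant stabilising
structure, so a low-rank approximation $\tilde M$ sums the $k$ most
negative components. The matrix of local coupling energies is the Hadamard
product $\mathrm{MLCE}_{ij} = \tilde M_{ij} \, C_{ij}$ with the Cα contact
matrix $C$ (cutoff 6 Å, closed interval: pairs at exactly the cutoff are
contacts, since only pairs strictly farther are excluded).

The established MLCE practice keeps the most negative eigenvalue plus
additional informative eigenvectors, but the selection rule varies between
implementations, so the package declares its own deterministic,
spectrum-adaptive default: include
eigenvectors in ascending-eigenvalue order while the cumulative
$|\lambda|$ of included negative eigenvalues stays below 85% of the total
over all negative eigenvalues, minimum one. For a near-rank-1 spectrum this
reduces to the single most negative mode; $k$ is always recorded, and a
fixed integer can be passed instead.

Residue-level extraction (`extract_segments()`) scores each residue by its
most negative contact coupling — its strongest stabilising interaction.
`mode = "core"` keeps the tail fraction (default 10%) with the most
negative scores; `mode = "soft"` keeps the fraction whose strongest
coupling is weakest (closest to zero). Ties at the boundary are all
included. Kept residues are reported as maximal sequence-contiguous runs of
at least 3 residues, matching how such regions are quoted as sequence
ranges; an optional spatial merge of nearby runs exists but is off by
default. Soft spots are labelled candidate interface/unfolding-prone
regions — the package makes no in-vivo unfolding claim.

## Descriptors and conformational families

`rmsd_series()` superposes each frame on a fit selection (Kabsch
least-squares, via bio3d) and measures RMSD over a possibly different
selection. `rmsf_profile()` measures per-residue root-mean-square
fluctuation about the ensemble-average structure; the initial alignment
targets the ensemble's reference rather than the first frame so the result
does not depend on frame order. `cluster_conformations()` reproduces the
family-isolation protocol: align frames on the ordered
(secondary-structure) selection, compute pairwise RMSD over the disordered
selection without refitting, agglomerate hierarchically and choose the
cluster count by maximum mean silhouette over candidates (default 2–10).
Protocols of this kind rarely fix a linkage criterion or a representative
definition, so both are declared here: average linkage is the default
(stable against chaining on RMSD matrices; single/complete are flags) and
each family is represented by its medoid, the member minimising summed
within-cluster RMSD. Silhouette ties break toward fewer clusters, and a
degenerate all-identical ensemble returns K = 1 with a warning. Ordered
regions can be supplied as residue ranges or taken from `assign_sse()`, a
deliberately simple Cα-geometry heuristic (canonical i→i+4 helix and
extended i→i+2 distances) for when no reference assignment exists.

## The synthetic-ensemble generator

Microsecond trajectories of 200k-atom complexes are not desk-scale data,
so every stage is exercised against a statistical emulator with closed-form
ground truth — one Cα-like site per residue, frames drawn i.i.d. from a
Gaussian network whose per-axis displacement covariance is $\sigma^2
L^{+}$, the stiffness-weighted graph-Laplacian pseudo-inverse (the
elastic-network convention). Time stamps are bookkeeping, not dynamics:
every property the analyses consume here (distance variances, planted
responses, planted couplings) is a static-distribution property. The
generator's defaults are the study conditions of the test suite: site
noise σ = 0.5 Å (a typical Cα fluctuation scale), chain stiffness ~5
kcal/mol/Å², four 50-frame replicas per state stamped every 20 ns (the
1-μs production layout). A disconnected spring graph has no well-defined
covariance and errors out unless a weak global restraint is enabled.

The D-NEMD emulation translates "same initial velocities" into common
random numbers: both members of a branch pair share their noise draws
(`noise_sharing = 1`), so the perturbed-minus-unperturbed difference equals
the planted displacement exactly and recovery tests are exact;
`noise_sharing = 0` gives fully independent members, the null-calibration
case whose per-residue deviation has an analytic Maxwell mean
$2\sqrt{2v_r}\sqrt{2/\pi}$ with $v_r$ the per-axis site variance.

Planted energy matrices put a strongly coupled core block (mean entry
−10 kcal/mol) and a weakly coupled patch (couplings damped by 0.05) on a
zero-mean Gaussian background (SD 0.3 kcal/mol). Two fixture-design rules
were learned the hard way and are now deliberate: the planted patch must
sit strictly inside the default 10% extraction budget (a patch exactly
equal to the budget tests tie-breaking at the boundary, not recovery —
one intruder fragments the contiguous run), and a planted decoupled block
in the DF-difference fixture must cover a small fraction of residue pairs,
because top-decile enrichment is arithmetically capped at the inverse of
the block's pair fraction. With a zero-mean background, some background
residues are occasionally *genuinely* near-zero-coupled after low-rank
truncation; across repeated 20-matrix batches the mean soft-patch recall
averages about 0.90 (batch SD ≈ 0.06). That variability is a property of
the fixture's noise model, not of the extraction, and is left visible
rather than smoothed away.

What passing these tests does and does not show: the generator has no
time correlation, no anharmonicity, no solvent, and i.i.d. frames — it
validates the statistical machinery (estimators, subtraction, spectral
algebra, selection logic) exactly, but says nothing about force-field
adequacy or sampling convergence on real trajectories.

## Problem sizes and I/O conventions

The bundled demo is a 40-residue two-site model (coordination between
residues 1–8 and 33–40 present in one "ligand state", absent in the
other), 4 × 50 frames per state, a 10-pair D-NEMD set and a 50-residue
scale for recovery sweeps; suite and demo run in well under a minute on a
single core. Trajectory formats are DCD (read via bio3d; written by a
minimal CHARMM-convention writer, round-tripped against bio3d's reader in
the tests) and multi-model PDB, which keeps every fixture plain text. XTC
is not supported. Matrices and profiles are written as residue-labelled
TSV; per-residue scalars also as PDB B-factors (values must fit the
field's two decimals). `run_pipeline()` drives the stages from one YAML
config, hashes every output into a JSON manifest, and is byte-reproducible
under a fixed seed; `make_demo()` emits the complete synthetic study set
plus a ready-to-run config.

## Known limitations

Harmonic, i.i.d.-frame synthetic data cannot probe time-dependent response
shapes (only planted displacement schedules); the SSE heuristic is crude
next to a dihedral-based assignment and is meant only as a fallback; the
eigenvector-count rule is a declared substitute for an unstated published
criterion and should be fixed explicitly when comparing against other MLCE
implementations; quantization shades are relative to each matrix's own
range, so shades are not comparable across systems unless ranges are.
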