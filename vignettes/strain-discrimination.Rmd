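---
title: "Discriminating fibril strains from a chemical-shift assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating fibril strains from a chemical-shift assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftstrain)
library(dplyr)
```

## The problem

Tau and other amyloid-forming proteins aggregate into cross-β fibrils whose
protofilament core can adopt several distinct conformations ("strains" or
"folds"), often correlating with a specific disease. Solid-state NMR yields a
residue-by-residue chemical-shift assignment of an in-vitro fibril, and
cryo-EM has produced a panel of candidate core structures. The question this
package answers is: *which candidate structure is most consistent with the
assignment?*

The connection between the two data types is secondary structure. Cα and Cβ
chemical shifts are highly sensitive to backbone conformation, and backbone
torsions can be predicted from shifts (TALOS-N) or computed from coordinates.
`shiftstrain` quantifies assignment-versus-structure consistency with three
metrics, computed over the residues matched between the two sides:

* **Σ~CS~** (ppm) — the summed absolute Cα/Cβ shift difference between the
  assignment and shifts predicted from the candidate structure (ShiftX2
  output):
  Σ~CS~ = Σ~i~ |δCα~i~^Cal^ − δCα~i~^NMR^| + |δCβ~i~^Cal^ − δCβ~i~^NMR^|.
* **Σ~A~** (count) — the number of residues where the sign of the
  secondary-shift statistic S = ΔδCα − ΔδCβ differs between the two sides
  (S~i~^Cal^·S~i~^NMR^ < 0 scores 1, a product ≥ 0 scores 0). S is positive
  in helical and negative in extended conformation, and since all fibril
  cores are β-dominated, what this metric really compares is *kink
  placement* — the local departures from strand that distinguish folds.
* **Σ~ΨΦ~** (degrees) — the summed absolute per-residue difference between
  shift-derived (Φ,Ψ)^NMR^ and structure-derived (Φ,Ψ)^Cal^ torsions.

The per-residue diagnostic **Δαβ~i~** = |δCα~i~^Cal^ − δCα~i~^NMR^| +
|δCβ~i~^Cal^ − δCβ~i~^NMR^| localizes disagreement along the chain; it sums
to Σ~CS~ exactly.

Candidates are ranked per metric (minimum = rank 1, ties share the smaller
rank), and the report rows are sorted by ascending Σ~A~ with ties broken by
ascending Σ~ΨΦ~ and then structure id, the presentation convention used for
strain-comparison tables.

## Residue frame, matching, and ambiguity

All tables live in full-length 2N4R tau numbering (the tau(297–391) core
fragment spans residues 297–391), so residue labels like V309 or C322 carry
their conventional meaning; NMR-STAR depositions with sequence-relative
numbering are mapped via an `offset`. A rigid-core assignment is sparse:
`assignment_segments()` records the covered segments (V309–S324, G326–I328,
E338–E342, R349–N359, E372–H374), and one PGGG repeat could not be placed
uniquely (P332–G335 or P364–G367). `match_residues()` builds per-residue
eligibility flags for each metric and applies an `ambiguous_policy` to those
PGGG residues: `exclude` (default — the assignment cannot place them),
`assign-to-332`, `assign-to-364`, or `both`.

Three conventions in the metric definitions are genuinely open and are
therefore explicit parameters, with `metric_variants()` enumerating all
combinations so an external comparison can locate a reference's choices:

* **Circular vs naive angle differences.** A Φ pair of 170° vs −170° is a
  20° discrepancy on the circle but 340° as a naive absolute difference.
  Circular differencing (each term in [0, 180]) is the default because the
  naive value misrepresents wrap-around pairs; the naive mode is retained
  for sensitivity checks.
* **Partial vs strict atom matching in Σ~CS~.** By default a residue
  missing one of CA/CB on either side still contributes the other atom's
  term (maximizing use of a sparse assignment), with `n_cs` reporting
  coverage; strict mode drops such residues.
* **The zero branch of Σ~A~.** A sign product of exactly zero counts as
  agreement, following the two-branch definition (`≥ 0` → 0). The sign
  classifier's dead-band `epsilon_s` defaults to 0 ppm (strict sign); a
  nonzero value exists only for sensitivity analysis.

## Secondary shifts and the random-coil reference

`secondary_shifts()` subtracts a per-residue-type random-coil reference from
the Cα/Cβ shifts. The packaged default is the Wishart et al. (1995) set;
since different published reference sets differ by small per-residue-type
constants (which cancel partially in S and entirely in Σ~CS~), the table is
pluggable: any CSV with `residue_type, rc_ca, rc_cb` can be passed wherever
`rc` is accepted. Both the observed and every predicted table pass through
the same function with the same reference, so the two S series are on a
common scale. Glycine has no Cβ, hence no S value; it still contributes its
CA term to Σ~CS~.

## Torsions from structures

`read_structure()` extracts one chain's backbone (default chain A, the
single-protofilament convention for fibril cores; per-chain runs are
available by calling it per chain) from PDB or mmCIF, keeping the
highest-occupancy altloc (ties broken by altloc identifier order) and the
first model. `compute_torsions()` forms Φ(i) from C(i−1)–N(i)–CA(i)–C(i) and
Ψ(i) from N(i)–CA(i)–C(i)–N(i+1) under the IUPAC sign convention, reporting
angles on (−180, 180] with trans mapped to +180 to remove the ±180
ambiguity. Residues adjacent to a chain break (peptide C–N distance ≥ 2.5 Å)
or missing a backbone atom yield no angle, and only residues with both
angles defined are emitted. The torsion of four points is invariant under
rigid motion and under reversing the point order; mirror reflection flips
its sign — both properties are exercised in the test suite against an
independently coded acos-based oracle.

## The synthetic world

The synthetic module makes the full pipeline runnable and testable with no
downloads, emulating exactly the features the metrics can see:

* **Torsion programs** (`torsion_program()`, `tau_truth_program()`): a
  β-strand background (Φ = −135°, Ψ = 135°) over the tau(297–391) sequence
  with short kinks (Φ = −80°, Ψ = 0°). The default truth places four
  3-residue kinks at 317, 339, 352 and 369 — away from the ambiguous PGGG
  repeats so that ambiguity policies and kink recovery can be tested
  independently.
* **Backbones** (`generate_backbone()`): built atom by atom with fixed
  ideal geometry — bond lengths N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å,
  planar trans peptide (ω = 180°), and standard backbone bond angles
  (N–CA–C 111.0°, CA–C–N 116.2°, C–N–CA 121.7°; the builder's contract
  fixes lengths and ω, the angles are conventional single-conformation
  values). The construction realizes the program's torsions exactly, and
  `compute_torsions()` recovers them to better than 10^−6^ degrees — the
  module's core invariant.
* **Shift tables** (`forward_shift_model()`, `simulate_shift_table()`):
  δ = random coil + secondary-structure offset + Gaussian noise. Default
  offsets are strand (ΔδCα, ΔδCβ) = (−1.5, +2.0) ppm (so S = −3.5 < 0),
  helix (+2.6, −0.5) (S > 0), kink/coil (0, 0). These are simulator
  parameters chosen to satisfy the sign rule, not literature shift
  statistics. The default observed-table noise is 0.3 ppm per shift,
  about half the ~0.5 ppm RMSD typical of ^13^C shift prediction — i.e. an
  optimistic but realistic per-shift uncertainty for a well-resolved
  solid-state assignment.
* **Decoys** (`make_decoys()`): candidate structures differing from the
  truth only by translating each kink (default by 2–4 residues, drawn
  without replacement so decoys are distinct), mirroring the observation
  that fibril strains share strand locations and differ in fold.

What the generator does **not** emulate: per-atom prediction error
structure of real shift predictors, side-chain packing, inter-protofilament
contacts, spectral overlap or assignment ambiguity beyond the PGGG mask.
Passing the recovery test therefore shows the *metric logic* discriminates
kink placement under shift noise; it does not certify performance against
real predictor bias, which is bounded instead by the predictors' published
RMSDs (~0.5 ppm for ^13^C shifts, ~12° for Φ/Ψ).

## Numerical and design choices

* Exact identities are kept exact: Σ~CS~ is summed residue-by-residue in
  the same order as Δαβ so that Σ~i~ Δαβ~i~ = Σ~CS~ bit-for-bit, and all
  three metrics return exactly 0 on self-comparison.
* Degenerate dihedral input (three collinear points, cross-product norm
  ≤ 10^−9^ Å²) is an error, not an NA.
* The recovery experiment (`kink_recovery()`) uses 100 replicates of
  truth + 9 decoys over the 95-residue tau core; per replicate the decoy
  set and observed noise are redrawn from the replicate seed. "Recovered"
  means the truth heads the ranked report under the documented ordering
  (Σ~A~, then Σ~ΨΦ~, then id). At the default conditions (0.3 ppm noise)
  recovery is expected in ≥95/100 replicates, and at zero noise in
  100/100 with Σ~A~(truth) = 0. The noise-response check
  (`sigma_cs_noise_curve()`) uses 50 replicates per noise level on the
  grid {0, 0.2, 0.5, 1.0} ppm; mean Σ~CS~ is strictly increasing
  (Spearman ρ = 1) because each term is an absolute Gaussian deviation.
  These problem sizes keep a full run on one CPU to about a minute.
* All randomness flows through explicit seeds (`withr::with_seed`); no
  function touches the global RNG state.

## Worked example

```{r example}
dir <- file.path(tempdir(), "demo")
run_simulate(dir, n_decoys = 5, noise_sd = 0.3, seed = 42)

report <- run_compare(compare_config(
  assignment     = file.path(dir, "observed_shifts.str"),
  structures_dir = file.path(dir, "structures"),
  pred_shifts_dir = file.path(dir, "pred_shifts"),
  talos          = file.path(dir, "observed_torsions.tab"),
  out_dir        = file.path(dir, "out"),
  ambiguous_policy = "both"
))
report |> select(-delta_ab)
glance(report)
```

The truth structure heads the report with Σ~A~ = 0 and a near-zero Σ~ΨΦ~,
while every decoy pays for its misplaced kinks in all three metrics.
`autoplot(report)`, `plot_s_series()` and `plot_delta_ab(report)` give the
ranking, the per-residue S comparison, and the per-residue Δαβ bar chart.

For real data the same `run_compare()` call takes a BMRB NMR-STAR file, a
directory of PDB/mmCIF cores, ShiftX2 output per structure, and a TALOS-N
prediction table; running ShiftX2 and TALOS-N themselves is an external
prerequisite, documented rather than wrapped.

## Known limitations

* Σ~ΨΦ~ compares single-chain torsions; averaging over a fibril's chains is
  not implemented (fibril rungs are near-identical by construction of the
  deposited models).
* No significance testing is attached to metric differences; the metrics
  are descriptive rankings, and small gaps between candidates are within
  predictor uncertainty.
* The NMR-STAR reader covers the assigned-chemical-shift loop of v3
  depositions only; NEF is out of scope.
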