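---
title: "Consensus primer design and enzyme characterization with lipoprospect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus primer design and enzyme characterization with lipoprospect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipoprospect)
```

`lipoprospect` covers the computational arc of a gene-prospecting and
enzyme-characterization study: find conserved anchors in an alignment of
homologous lipases, turn them into degenerate PCR primers, and analyse the
recovered enzyme's pH/temperature response surface and kinetics. This
vignette documents the underlying models, the parameters that matter, the
numerical conventions, and what the synthetic-data tests do and do not
establish.

## Degenerate sequences and back-translation

A degenerate oligonucleotide is a string over the 15-letter IUPAC ambiguity
alphabet; each symbol denotes a non-empty subset of {A, C, G, T}, and the
oligo denotes the Cartesian product of its per-position sets. Degeneracy —
the number of concrete sequences in the pool — is the product of the set
sizes; complementation maps each set to its Watson–Crick image (so R↔Y,
K↔M, and W, S, N are self-complementary), making reverse complementation an
involution that preserves degeneracy.

Back-translation uses the **position-wise union rule**: each amino acid
maps to the single degenerate codon whose set at each position is the union
of the bases its codons use there. The rule is sound (every codon of the
residue matches) and minimal position-wise (no base can be removed without
excluding a codon), but deliberately over-degenerate for residues whose
codons span boxes: serine's six codons become `WSN`, which covers 16
triplets. That trade-off is what consensus-primer tables conventionally
print, and it is what this package reproduces; codon-usage-weighted or
split-pool designs are out of scope. Reverse primers are the reverse
complement of the back-translated motif, reported 5'→3'.

Conventions: sequences are upcased on parse and `U` is normalized to `T`;
gaps are a parse error (primers are ungapped); all positions in error
messages and reports are 1-based. Translation accepts concrete input only
and drops a terminal stop, so a 1242 bp open reading frame yields
1242/3 − 1 = 413 residues. The default genetic code is the standard table
(appropriate for Bacillus/Geobacillus chromosomal genes); other NCBI
tables can be selected by id.

Primer metrics report the Wallace rule Tm = 2(A+T) + 4(G+C) °C as a
min–max range over the expansion pool. The extremes are computed from the
per-position ambiguity sets (which bases can, or must, be G/C), which is
exact and avoids enumerating large pools; the test suite cross-checks this
against exhaustive enumeration on small primers. Nearest-neighbour
thermodynamics, dimer and hairpin screens are intentionally out of scope.
The genome-specific cloning primers used downstream of a first
amplification (concrete stretches with NcoI/HindIII tails) cannot be
derived from any conserved motif; `tail_primer()` supports the
tail-plus-site construction, and the motif-derived pairs ship as presets in
`lipase_primer_presets()`.

## Conserved blocks and cluster structure

Column conservation is the plurality frequency: the count of the most
common residue divided by the number of sequences, with gaps counted as
mismatches and never eligible as plurality (an all-gap column scores 0).
This is the simplest score that makes "conserved motif" operational;
entropy- or substitution-matrix-based scores could be slotted in later but
are not needed to anchor primers.

`find_conserved_blocks()` reports maximal runs of at least `min_len`
columns with conservation ≥ `min_cons` and per-column gap fraction below
1 − `min_cons`. Defaults: `min_len = 7` (useful primer anchors are 7–9
residues) and `min_cons = 0.8`. The family is split into short and long
clusters by the largest gap in sorted ungapped lengths — the operational
form of the 20–35 kDa vs 40–45 kDa molecular-mass split seen in family I.5
alignments — with ties going to the short cluster and a degenerate warning
when all lengths coincide. `shared_blocks()` re-tags blocks found in both
clusters when their spans agree within `span_tolerance` columns (default
2) and their plurality motifs are identical.

The nucleotide consensus builder emits a column only when its gap
frequency is below 0.5, uses the plurality base when it reaches the
plurality threshold (default 0.6), and falls back to the IUPAC union of
observed bases otherwise.

## The synthetic family generator

`sim_family()` emulates the alignment structure the discovery stage
assumes: a short cluster (default 6 sequences of 210 residues, ≈23 kDa)
and a long cluster (6 of 390, ≈43 kDa), conserved blocks planted verbatim
(shared blocks identically in both clusters), i.i.d. substitution noise at
`substitution_rate` (default 0.1) outside blocks over a uniform
20-residue background, and a contiguous terminal gap region padding the
short cluster.

One generator design choice deserves emphasis: **the two cluster
consensuses are drawn to differ at every shared-occupancy column outside
planted blocks.** Real inter-genus alignments are divergent in exactly
this sense, and the property is what makes conserved-block discovery on
the mixed family sharp: at substitution rates ≤ 0.1, within-cluster noise
columns still conserve at ≈0.9 — above any useful threshold — whereas
mixed-family noise columns sit near 0.5 because the two cluster
consensuses disagree. Planted shared blocks (conservation 1.0) are then
the only columns passing `min_cons = 0.8`, and recovery of their exact
spans is a sharp, repeatable test. Cluster-specific blocks are recovered
by per-cluster scans at strict thresholds on noisier families instead.
What these tests do **not** show: robustness to indel noise inside blocks,
phylogenetically correlated substitutions (no tree-based evolution is
simulated), or non-uniform residue backgrounds — real alignments are
harder in all three ways.

Seeding: one top-level seed; each generator uses an independent substream
seeded with (seed × 7919 + offset) mod 2³¹−1 (offsets: family 1, CCD 2,
MM 3, decay 4), so adding a generator never perturbs existing fixtures,
and identical specs give byte-identical outputs.

## Central composite designs and the response surface

The two-factor CCD comprises the 2² factorial corners (±1, ±1), four
axial points at distance α, and replicated center points — 11 runs with
the default 3 center replicates, five distinct levels per factor when
α ≠ 1 (α = 1 degenerates to a face-centred 3-level design and warns).
The default α = √2 makes the design rotatable for two factors. Natural
coordinates interpret the stated factor ranges as the **axial extremes**:
center = range midpoint, step = (hi − center)/α, so a pH range of 4.2–9.8
with temperature 16–50 °C gives pH levels {4.2, 5.02, 7.0, 8.98, 9.8} and
temperature levels {16, 20.98, 33, 45.02, 50}.

The model is fitted in natural units by QR-based least squares
(`stats::lm`; no normal-equation inversion), because the reference
polynomial for the LipJ esterase is printed in natural pH/°C units — its
stationary point lands at a physically meaningful pH. Here x is pH and y
is temperature; that assignment is inferred from the stationary point of
the reference surface (≈7.0 is a pH, ≈28 °C a temperature) and flagged
because the fitted equation itself does not label its symbols.
A rank-deficient design is an error naming the collinear terms. A
zero-variance response reports R² = 0 by convention, with a warning.

The ANOVA follows replicated-design RSM practice:

- **Pure error**: within-group SS over replicate groups, df = Σ(reps − 1).
  It is the model-independent noise estimate and the denominator of every
  F test.
- **Lack of fit**: SSE − SS_pe with df = n − 6 − df_pe.
- **Per-term SS are partial (drop-one)**: SSE(model without the term) −
  SSE(full model), 1 df each. On a CCD with axial points the quadratic
  columns are not orthogonal to the intercept, so sequential SS would not
  decompose additively; partial SS is also the convention under which the
  reference table's printed F values equal term MS / pure-error MS
  exactly.
- p-values come from the F survival function (`stats::pf`, upper tail);
  at df (1, 2) it has the closed form 1 − √(F/(F+2)), which the tests
  verify to 10⁻⁹.

The stationary point solves the 2×2 zero-gradient system; the Hessian
[[2b₁₁, b₁₂], [b₁₂, 2b₂₂]] classifies it (negative definite → maximum),
and points outside a supplied design region are flagged as extrapolation.
For the reference LipJ surface the solve gives a maximum at pH 7.022,
28.149 °C — within the wobble implied by the 4-decimal rounding of the
published coefficients of the reported optimum (pH 7.0, 28.13 °C). The raw
11 activity responses behind the reference table were never published, so
the fitted coefficients cannot be re-derived from data; what can be (and
is) verified are the table's internal identities — R² = 0.94557 and
adjusted R² = 0.89114 from the SS components, every F as MS/MS_pe, all
p-values — plus full-pipeline recovery on simulated responses. The printed
mean squares are rounded to five decimals, which propagates to ≈10⁻⁵ in
the recomputed p-values; the tests assert agreement at that level rather
than at the printed sixth decimal.

## Kinetics and activity summaries

`fit_mm()` minimizes Σ(vᵢ − Vmax·Sᵢ/(Km+Sᵢ))² by Levenberg–Marquardt
(damped Gauss–Newton, via minpack.lm) with positivity bounds, initialized
from a Hanes–Woolf linearization (S/v regressed on S) — preferred to
Lineweaver–Burk because it does not blow up low-substrate error.
Convergence uses relative tolerances of 10⁻¹² with a 200-iteration cap;
noiseless data are recovered to better than 10⁻⁶ relative error, and a
non-positive parameter escape is reported as a divergence error rather
than silently clipped.

Interfacial activation — the hallmark rate jump of true lipases at the
substrate micellar transition, absent in esterases — is operationalized as
a Hill screen, since reference descriptions of its absence are
qualitative: both v = Vmax·S/(Km+S) and v = Vmax·Sʰ/(Kʰ+Sʰ) are fitted,
and the verdict is "activated" only when ĥ > 1 + 0.3 **and** the Hill fit
improves the small-sample-corrected information criterion (AICc computed
from the least-squares SSR). The 0.3 margin keeps noise-level wobble of ĥ
around 1 from triggering false positives on 8-point curves.

Activity units are carried as opaque labels (1 U = 1 µmol p-nitrophenol
released per minute; U/g vs U/mg are never converted). Relative profiles
are 100·a/a_ref with the reference substrate at 100%; ion effects are
percentages of the untreated control (stimulation > 100%). Thermal
half-loss time interpolates log(residual) linearly in time between the
bracketing observations — exact under first-order decay, within 2% of
ln 2/k for ≥10-point sampling of an exponential — returning `NA` ("not
reached") when the series never falls to 50% and warning on non-monotone
series (first crossing used).

## Pipeline, formats, reproducibility

`run_pipeline()` executes motifs → primers → rsm → kinetics from a YAML
config that rejects unknown keys, and writes a manifest with an MD5
checksum per artifact; identical config and seed give identical manifests,
and verbosity never alters outputs. Formats are aligned FASTA/Clustal for
alignments (read via Biostrings), RFC-4180 CSV for tables (columns `pH`,
`temp_C`, `activity`; `S_mM`, `v`; `time_h`, `residual_pct`), TSV for the
primer report and JSON for structured results; numeric output uses fixed
precision rules (GC 3 decimals, Tm whole degrees) so written artifacts are
byte-stable. The thin command-line front end in `inst/cli/lipoprospect.R`
exposes each stage as a subcommand with exit codes 0/2/3
(success/bad input/numerical failure).

Problem sizes used throughout the test suite — 11-run designs, 8-point
kinetic curves, 12–40-sequence families of 100–390 columns, 100–200
replicate batches for the statistical-recovery properties — match the
scale of the experiments the package models, and keep the full suite
comfortably under a minute.

## Known limitations

- Back-translation is union-rule only; no codon-usage weighting, no
  CODEHOP-style consensus-clamp hybrids, no in-silico PCR.
- Conservation is plurality frequency; no entropy or similarity-matrix
  scoring, no profile HMMs, and alignments are consumed, never computed.
- The RSM module is strictly two-factor, second-order, with pure-error F
  tests; no Box–Behnken designs, ridge analysis, or desirability
  optimization.
- Kinetics covers MM and Hill initial-rate models only; no progress-curve
  analysis or inhibition constants.
- The decay generator is homoscedastic Gaussian; real residual-activity
  assays are often heteroscedastic near zero.
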