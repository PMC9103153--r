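---
title: "Methods: correlation-based ceRNA screening and its companion procedures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation-based ceRNA screening and its companion procedures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAscreen)
```

## The screening model and its assumptions

The screen asks a single question of an expression cohort: do the predicted
targets of a miRNA that can bind the lncRNA co-express with the lncRNA more
strongly than predicted miRNA targets in general? The underlying sponge
picture is purely correlational — the lncRNA titrates free miRNA, free miRNA
represses its targets, so lncRNA and targets rise together. The screen
therefore assumes:

* expression values are on a log-like scale where Pearson correlation is a
  sensible association measure (the package takes the matrix as given and
  performs no normalization; probe summarization, if the platform needs it,
  is the `collapse_probes()` step);
* sample columns are aligned across all genes — the matrix's column order
  *is* the pairing; readers never reorder samples;
* target predictions are trustworthy enough that requiring agreement of two
  databases removes most noise pairs; prediction quality itself is not
  modeled;
* miRNA abundance is unobserved. The screen never uses miRNA expression,
  only the *sets* of genes the miRNAs are predicted to repress.

Per candidate miRNA the statistic is a two-sided Welch t-test on absolute
correlations of its target set versus the pooled background (the union of
all candidates' evidence-intersected targets), BH-adjusted across
candidates. Two design choices here were genuinely open and are resolved as
follows:

* **Sidedness.** The test is two-sided, and the significance call
  additionally requires the targets' mean |r| to *exceed* the background's.
  This keeps the reported p interpretable as a pure location test while
  making the sponge-compatible direction an explicit, reported condition
  rather than folding it into a one-sided p. A consequence worth knowing:
  when strong sponging is present, null miRNAs' target sets fall *below*
  the signal-inflated background mean and can reach small two-sided p —
  the direction gate is what keeps them out of the network.
* **Threshold placement.** `alpha` applies to the BH-adjusted p-value, not
  the raw one; reporting adjusted values and thresholding them is the
  consistent pairing.
* **One common background.** A miRNA's own targets are *not* removed from
  the background when that miRNA is tested. This matches the "all potential
  target genes as background" formulation, and it has a quantifiable price:
  target and background samples overlap, so the true variance of the mean
  difference is smaller than the Welch estimate — at the default synthetic
  sizes (30 targets, 600 background genes) by the factor
  (1/30 − 1/600)/(1/30 + 1/600) = 19/21. The screen is therefore mildly
  *conservative* under the null; the null-calibration simulation in the
  test suite (2,000 replicate screens of the fully null generator) exhibits
  exactly this: a per-test type-I rate slightly below the nominal 0.05,
  with the BH false-discovery proportion controlled a fortiori. We document
  rather than "correct" this, because removing own targets from the
  background would change the estimand (each miRNA would face a different
  background) and break the single-background interpretation.
* **Gene-level membership.** Which genes count as network members is
  under-determined by the miRNA-level screen. The rule used: a gene joins
  the network if it is a target of at least one significant miRNA, its own
  lncRNA correlation is positive, and its per-gene p is below `alpha`.
  Positivity is required because the sponge model predicts positive
  lncRNA–target co-expression; genes are then ranked by r.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_sources` | 2 | databases that must agree on a miRNA–target pair |
| `alpha` | 0.05 | level applied to BH-adjusted miRNA p and per-gene p |
| `min_target_set` | 5 | measured targets required for a miRNA to be testable |
| `min_group_frac` | 0.10 | minimum share of samples per side of a survival cutoff |
| `collapse_method` | max-variance | duplicated-probe rule |

`min_target_set = 5` exists because a Welch test on a handful of |r| values
is unstable; miRNAs falling below it are reported in the map's `untested`
table rather than silently dropped. `min_group_frac = 0.10` prevents the
cutoff scan from "discovering" one-patient risk groups; the scanned p-value
is reported **unadjusted** for the multiplicity of the scan — a property the
test suite demonstrates by simulation (under a null marker its distribution
is stochastically smaller than uniform) — so it should be read as a
stratification device, not a calibrated test. Duplicate probes default to
the maximal-variance representative (ties to first occurrence) because
low-variance probes on array platforms are typically near the detection
floor; `mean` and `first` are available where that heuristic is wrong.

Degenerate inputs are errors, not guesses: a constant lncRNA row, a
background of fewer than two genes, zero variance in both Welch samples
with equal means, p-values outside [0, 1], negative survival times,
constant markers in the cutoff scan, out-of-range RNAscope sub-scores.
Genes with fewer than 3 complete sample pairs against the lncRNA (or
constant over them) are excluded from correlation with a logged count, and
missing values are carried as `NA` throughout — never as zero.

## What the synthetic generator emulates — and what it does not

`simulate_cerna_dataset()` draws, per sample, lncRNA `L ~ N(0,1)`; each
sponged miRNA's free activity is `a = m − θ·L` with `m ~ N(0,1)` (unsponged:
`a = m`); each target gene is `x = −β·a + ε`, `ε ~ N(0, σ²)`; null genes are
pure noise. Defaults — 50 samples, 20 candidate miRNAs, 5 sponged, 30
targets each, 500 null genes, θ = 0.5, β = 0.8, σ = 1 — describe a mid-size
tumor cohort with moderate sponging: the implied sponged-target correlation
is θβ/√(β²(1+θ²)+σ²) ≈ 0.30 at the defaults, a typical magnitude for
reported ceRNA pairs. The closed form follows from
Cov(x, L) = θβ and Var(x) = β²(1+θ²) + σ²; as σ → 0 it tends to
θ/√(1+θ²), and the generator's test verifies the sampled value against it.
Because a per-gene sample correlation at n = 50 has a standard deviation
near 0.11, that check — and any statement about expected correlations —
averages over all sponged targets of 20 seeded replicates rather than
trusting a single draw. For the same reason, recovery statements about the
planted miRNAs are statements in expectation across replicates: within one
dataset all targets of a miRNA share the realized latent `a`, so a miRNA's
whole target set can land close to (occasionally below) the background in
an unlucky draw even though its expected margin is large.

Prediction tables plant every true pair in 2–3 of three synthetic sources
and add decoy pairs, at twice the true-pair count, in exactly one source, so
the evidence-intersection step is exercised non-trivially (the intersection
must recover exactly the planted map).

The generator is linear-Gaussian by construction: no kinetic titration, no
count noise, no batch structure, no correlated null genes, no mixture of
tumor and adjacent tissue, and identifiers are opaque strings (no miRNA
family expansion). Passing tests therefore demonstrate that the statistics
are implemented correctly and behave as designed under the model's own
assumptions — not that real cohorts satisfy those assumptions. In
particular, correlated co-regulation unrelated to sponging (copy number,
immune infiltration) can inflate target-set correlations in real data and
is outside this generator's world.

`simulate_survival()` uses an exponential hazard `λ·hr^[expr > θ]` with
independent uniform censoring on (0, b), b solved numerically so the
expected censored fraction matches `censor_rate` under the baseline hazard
(approximate when hr ≠ 1). `simulate_qpcr()` plants fold changes under
per-sample additive CT offsets, which the ΔΔCT arithmetic must cancel
exactly — replicates are averaged on the CT scale before differencing, and
the control group's *geometric* mean fold change is 1 by construction.

## Numerical choices

* Correlation p-values use the exact t-transform with n − 2 df; |r| = 1
  maps to p = 0. Correlations use pairwise-complete samples; the per-gene
  `n` is reported alongside r.
* Standard statistics are delegated to their reference implementations
  (`stats::t.test`, `stats::p.adjust`, `survival::survfit`,
  `survival::survdiff`); the test suite verifies each against an
  independently coded textbook oracle at 1e−10 on ≥ 1,000 randomized
  inputs, so the delegation is checked, not assumed.
* Orderings are total and deterministic: miRNA nodes by adjusted p then
  identifier, genes by r descending then identifier, scan ties toward the
  median cutoff. Identical inputs and seed give byte-identical output
  tables.
* Simulation sizes used by the test suite — 2,000 null replicates for
  calibration, 200 for recovery, 100 cutoff scans at n = 200, 20 replicates
  for the closed-form check — are chosen so each Monte-Carlo standard error
  is several times smaller than the margin being asserted.

## Known limitations

* The screen detects co-expression enrichment, not causal sponging;
  orthogonal evidence (AGO2-RIP enrichment, reporter assays — whose
  arithmetic the quantification module covers) is what elevates a candidate
  to a mechanism.
* Overlapping target sets among miRNAs are tested independently; no
  overlap correction is attempted.
* The common-background design's mild conservatism (above) grows as a
  single miRNA's targets become a large fraction of the background; with
  few candidates the per-miRNA tests are also strongly dependent.
* The optimal-cutoff p-value is anti-conservative by construction and is
  deliberately left uncorrected, mirroring common practice with such
  scans; treat it as exploratory.
* Identifier matching is exact-string and case-sensitive. Case-folding was
  considered and rejected: the field's naming conventions distinguish
  entities by case alone (`miR-143` the miRNA vs `MIR143` the gene locus),
  so folding would merge identifiers that are not the same thing. Alias and
  family resolution are out of scope; inputs are expected to use one
  nomenclature consistently.
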