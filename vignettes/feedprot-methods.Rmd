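---
title: "Feedback protein inference: model, weighting scheme and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback protein inference: model, weighting scheme and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedprot)
```

## Overview

`feedprot` treats protein inference and peptide identification as one
coupled estimation problem. The input is a report of peptide-spectrum
matches (PSMs) — peptide sequence, Sequest preliminary score Sp, a
PeptideProphet-style posterior probability, assigned protein accessions,
and the calculated neutral peptide mass — together with the protein
database searched. The output is a protein list and a peptide list that are
mutually consistent: every reported protein is supported by the reported
peptides, and peptide probabilities reflect the evidence accumulated at the
protein level.

This vignette describes the model, the shared-peptide weighting scheme, the
iteration and its convergence behaviour, the synthetic benchmark generator,
and the choices made where the design was genuinely open.

## The protein model

For protein $k$ at iteration $n$, with $n_k$ currently selected constituent
peptides,

$$q_k^{(n)} = \Bigl[\,1 - \prod_{i=1}^{n_k}\bigl(1 - x_i^{(n-1)} w_{ik}
q_k^{(n-1)}\bigr)\Bigr]^{-\ln\!\left(n_k / N_k\right)}.$$

The bracket is a noisy-OR: the protein is supported unless every one of its
peptides independently fails, where peptide $i$ contributes only to the
extent that it is correctly identified ($x_i$), actually originates from
this protein ($w_{ik}$), and the protein survived the previous iteration
($q_k^{(n-1)}$). The exponent $-\ln(n_k/N_k) \ge 0$ penalizes large
proteins for which few theoretical peptides were observed: with full
coverage ($n_k = N_k$) the exponent is zero and any positive evidence gives
$q = 1$; with sparse coverage the bracket is raised to a large power and
shrinks.

Numerical conventions, chosen so the estimate is always defined and inside
$[0,1]$:

* $n_k = 0$ gives $q = 0$ (no evidence is never presence).
* $n_k = N_k$ with bracket $0$ — the $0^0$ corner — resolves to $0$, not
  $1$: zero peptide evidence must not produce a certain protein.
* $N_k$ is clamped to $\max(N_k^{\text{digest}}, n_k, 1)$; semi-tryptic or
  unusual identifications can make the observed count exceed the
  theoretical one, and the clamp keeps the exponent non-negative.
* The logarithm is natural by default. The base only rescales the exponent;
  it is exposed as `infer_config(log_base=)`.

$N_k$ is the number of distinct fully tryptic peptides of the protein —
cleavage after K or R, not before proline, at most two missed cleavages —
whose neutral monoisotopic mass lies inside the mass window observed in the
report (`infer_mass_window()`, simply the min and max reported mass; an
explicit window can be configured instead). Distinct sequences are counted
once even when a protein contains internal repeats, since $N_k$ models
distinct observable peptides. The proline rule and monoisotopic masses
match common search-engine practice and are both switchable
(`digestion_settings()`).

## Shared-peptide weights

A shared peptide's MS/MS intensity is assumed to be contributed by all of
its truly present parents. Its intensity $I_p$ is the sum of its matched
spectra's Sp scores after normalizing by the dataset-wide Sp maximum; Sp is
used because it is a signal-intensity-derived quantity already corrected
for peptide length by the search engine. Intensities are computed once from
the full report; only the weights and peptide counts change across
iterations.

For each parent $k$ of a shared peptide, the sibling average $I_b(k)$ is
the mean intensity of the parent's *other* currently selected peptides
(shared ones included — the model only requires that siblings come from the
same parent). Averaging over siblings damps peptide-to-peptide
detectability differences. The normalized distance

$$d_k = \frac{|I_p - I_b(k)|}{I_p}$$

measures how far the peptide's intensity sits from what protein $k$'s other
peptides would predict. With two parents $j, k$, the raw weight of parent
$k$ is $d_j$ — the distance to the *other* parent's siblings — so the
parent whose own siblings lie closer to $I_p$ receives the larger weight;
raw weights are normalized to sum to one. Unique peptides take weight 1.

Design choices in the degenerate corners, none of which are dictated by the
model itself:

* **More than two parents.** The raw weight of parent $k$ is the mean of
  $d_j$ over the other parents. This reduces exactly to the two-parent
  definition, is invariant under parent reordering, and preserves the
  closeness intuition with the smallest extension.
* **A parent with no siblings** gets $d = 1$: with no corroborating
  peptides, weight is pushed toward corroborated parents.
* **All distances zero, or $I_p = 0$:** uniform weights.
* Whether the denominator $I_p$ should be the raw or normalized intensity
  is immaterial — the scale cancels in the normalization — and the
  normalized value is used.

Because weights are recomputed from scratch each iteration over the
*active* parents only, a peptide becomes effectively unique (weight 1) the
moment all but one of its parents has been eliminated.

## The iteration

Initialization: every protein with identified constituent peptides starts
at $q^{(0)} = 1$ (equal prior chance of presence), and each distinct
peptide starts at the maximum PSM-level probability over its spectra — the
report gives probabilities per PSM, and the maximum is the natural
peptide-level aggregate.

Each iteration then runs: selection (probability ≥ `peptide_threshold`,
default 0.95, and at least one non-eliminated parent) → putative protein
list (union of parents, minus eliminated) → peptide counts $n_k$ and
weights → protein probabilities → replenishment (unselected peptides of
proteins with $q \ge$ `protein_threshold` re-enter regardless of their
current probability) → peptide probabilities $x_i = \sum_k w_{ik} q_k$ over
active parents, computed with weights re-derived on the augmented peptide
set → elimination → convergence check. Once replenished, a peptide's
probability is governed by the feedback formula and is re-evaluated against
the selection threshold at the next iteration, so replenishment is earned
anew each round. All iteration orders are sorted (accessions, sequences),
making runs bit-reproducible.

**Elimination.** A protein that is dropped for low probability but re-admitted
through peptides shared with positive proteins oscillates: its
putative-list membership history reads in → out → in. One completed
oscillation (configurable via `elimination_cycles`) eliminates the protein
permanently — its unique peptides leave the selected set and its shared
peptides' weights renormalize among the survivors in the same iteration.
Elimination is what makes the peptide list steady: without it, such
proteins would cycle forever.

**Convergence** requires the active protein set and selected peptide set to
be unchanged from the previous iteration and every protein probability to
move less than `q_tolerance` (default $10^{-6}$). The run stops at
`max_iterations` (default 100) with a warning otherwise; synthetic fixtures
typically converge in 3–6 iterations. Note one dynamic worth knowing: a
protein supported by a *single* peptide with $n_k/N_k = 1/2$ has update
$q \mapsto q^{2\ln 2} = q^{1.386}$ once feedback sets $x = q$, which decays
to 0 — single-hit proteins with low coverage fade out unless their peptide
keeps independent support. This is the model's built-in skepticism about
one-hit wonders, not an implementation artifact.

## Peptide–protein mapping

The index maps peptides to proteins either from the report's assignments
alone (default) or additionally by substring search of the database
(`map_by_fasta = TRUE`), since inferred protein sequences can legitimately
be used to locate low-confidence peptides the search engine assigned
elsewhere. Both maps are maintained as exact transposes. Peptides mapping
to no database protein are kept in the output as flagged orphans but can
never enter the iteration. Peptides are keyed by exact sequence; an
`equate_il = TRUE` switch rewrites I to L everywhere for instruments that
cannot distinguish the isobaric pair.

## The synthetic benchmark generator

Real benchmark datasets for this problem require running a search engine
and a PSM post-processor on raw spectra, so the package ships a generator
(`synthetic_config()`, `generate_proteome()`, `simulate_report()`) that
emulates the *design* of a standard-protein-mix study: a database with a
known present/absent split and engineered peptide sharing. Its defaults are
the package's reference study conditions:

* 20 present and 80 absent proteins of 150–300 residues, built from fully
  tryptic blocks (each ending in K/R, never followed by P) so every block
  is a clean zero-missed-cleavage peptide of usable mass;
* 30% of present proteins donate one block to another randomly chosen
  protein (present or absent), creating shared peptides — including the
  absent-protein-sharing-with-present configuration that exercises the
  elimination rule;
* each present protein draws a log-uniform abundance on 1–100; every block
  peptide of a present protein is observed with 1–5 PSMs whose Sp is the
  summed abundance of all present parents times log-normal noise (sd 0.3),
  so shared peptides accumulate intensity from every present parent exactly
  as the weighting model assumes;
* initial probabilities are Beta(9,1) for true peptides (median ≈ 0.93) and
  Beta(1,9) for false ones (median ≈ 0.07) — cleanly separated, as
  PeptideProphet posteriors are on well-behaved data;
* each absent-protein peptide appears as a false identification with
  probability 0.05, mirroring designs where false identifications map to
  known-absent sequences rather than shuffled decoys, which is what lets
  truth labels exercise the protein-level elimination machinery.

Everything is a deterministic function of the seed.

What the generator deliberately does **not** emulate: spectrum-level noise
structure, retention time, charge states, peptide detectability variation,
modified residues, semi-tryptic fragments, or poorly separated probability
distributions. Passing tests on these fixtures therefore demonstrates that
the estimator does what the model says under the model's own assumptions —
they do not certify performance on real instrument data, where initial
probabilities are noisier and intensity additivity holds only
approximately.

## Test problem sizes

The test suite cross-checks the digestion counts against brute-force
enumeration on 200 random sequences of length ≤ 50, the weight contract on
1000 random parent configurations, and the full loop against an
independently coded straight-line re-implementation on 100 random instances
of up to 5 proteins and 10 peptides; the end-to-end recovery check runs the
default 100-protein study. These sizes make the whole suite run in well
under a minute while leaving every code path exercised.

## Limitations

* No protein grouping: indistinguishable proteins (identical peptide sets)
  are scored independently, not merged, and no minimal-set parsimony is
  attempted.
* No protein-level FDR or decoy machinery; thresholds on $q$ are the only
  reporting control.
* Peptide detectability is handled only through sibling averaging, not
  modeled explicitly.
* The pepXML reader is a deliberate subset (spectrum queries, rank-1 hits,
  alternative proteins, Sp score, PeptideProphet probability); the TSV
  dialect is the canonical interface.
* Convergence is empirical, not proven: the elimination rule guarantees a
  steady peptide list on every fixture tried, and the suite verifies
  steady-state behaviour, but no formal fixed-point theorem is claimed.
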