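---
title: "Digital-rule extraction for functional-site prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital-rule extraction for functional-site prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitelogic)
```

## The model

`sitelogic` treats site prediction as two-level boolean logic. A sequence
window is one-hot encoded into binary variables — 4 bits per nucleotide
(A = 1000, C = 0100, G = 0010, T = 0001; a 14-nt window gives 56 variables)
or 21 bits per residue (the 20 standard amino acids in full-name
alphabetical order plus an "unknown" category; an 11-residue window gives
231 variables). Each labeled window is then one row of a partially
specified truth table: observed positives form the on-set, observed
negatives the off-set, and every input pattern never seen in training is a
*don't-care*. Two-level minimization compresses this table into a small
sum-of-products cover — an OR of AND-terms (*cubes*, written over
`{0,1,-}`) — and each cube reads directly as a rule such as

> If "Nucleotide 9 is A" and "Nucleotide 8 is A" and "Nucleotide 10 is T"
> then the window is a binding site.

The don't-cares are the machinery of generalization: the minimizer assigns
unseen patterns whichever output yields the simplest rules, exactly as a
black-box classifier extrapolates beyond its training set — but here the
extrapolation is a legible boolean formula. Anything matched by no rule is
negative (the implicit 0-output rule).

Because a full window induces more variables than a truth-table method can
carry (a complete table over 22 binary inputs already has
`r format(pla_table_rows(22), big.mark = ",")` rows), a linear soft-margin
SVM first ranks the variables by recursive feature elimination (RFE):
repeatedly fit, drop the variable with the smallest squared weight
$w_i^2$ (the standard surrogate for the margin change its removal causes),
and keep the top *k*. The retained variables keep their plain-language
meanings, so the final rules stay interpretable.

Finally, each rule is scored by its *popularity*: the number of positive
training patterns it covers (counting multiplicities of collapsed
duplicates). A test window's score is the sum over the rules it satisfies,
and a configurable cutoff (`cutoff_all_rules()`, `cutoff_top_fraction(f)`,
`cutoff_min_score(s)`) turns scores into calls, trading sensitivity for
precision: raising the bar can only remove positive calls.

## The two minimizers

`qm_minimize()` is exact. It tabulates all prime implicants
(Quine–McCluskey merging of patterns that differ in one position, the
axiom $A + \bar A = 1$), extracts essential primes, reduces the residual
covering problem by row/column dominance, and closes the remaining cyclic
core by branch-and-bound with a maximal-independent-rows lower bound. The
result is a minimum-cardinality cover; ties are broken toward the
lexicographically smallest cube list so output is unique. Memory and time
grow exponentially with width, so it refuses inputs beyond `exact_limit`
(default 16 variables). Within the training pipeline the don't-care set is
implicit (the complement of what was observed), which makes the exact
tabulation practical only well below that bound; the pipeline therefore
switches to the heuristic for the default *k* = 22.

`espresso_minimize()` is the heuristic counterpart and never enumerates the
don't-care space: it needs only the explicit on- and off-lists. It iterates
the classic loop:

* **EXPAND** — each cube is widened as far as possible against the off-set.
  The literals *kept* are chosen greedily: first by highest on-set
  agreement (the fraction of positive patterns sharing the literal, which
  preserves the cube's room to generalize), then by how many still-covered
  off-set patterns the literal excludes, with a caller-supplied preference
  order for ties (the pipeline passes the RFE ranking so the more
  informative variable wins). A final pass drops kept literals whose
  blocking work the others already do, least-shared first.
* **IRREDUNDANT** — cubes whose on-set contribution is covered by the rest
  of the cover are removed, smallest contribution first.
* **REDUCE** — each surviving cube shrinks to the smallest cube containing
  the on-set minterms only it covers, giving the next EXPAND a different
  starting point.

The loop stops when the cover size stops improving (or after `max_iters`).
Every intermediate cover covers the full on-set and avoids the off-set, so
correctness never depends on convergence; only minimality is heuristic, and
`length(espresso_minimize(f))` $\ge$ `length(qm_minimize(f))` always. We
initially implemented EXPAND in its simplest form — raising literals left
to right — but that form regularly strands literals on uninformative window
positions and inflates the genomic false-positive load; the
blocking-matrix form above is both the textbook formulation and visibly
better on synthetic data, so it is the default and only form.

## The training pipeline

`train_site_model()` chains the stages: encode → `rfe_rank(k)` →
`project_dataset()` → `clean_dataset()` → truth table → minimize →
`score_rules()`. Projection onto the top *k* variables routinely maps
distinct windows to the same reduced pattern; cleaning collapses duplicates
(keeping multiplicities for scoring) and removes or majority-resolves
contradictory groups — a contradiction-free table is a precondition of the
boolean axioms. DNA models scan sequence with `scan_sequence()` (one score
per start, `L − w + 1` windows on the forward strand; a prediction within
±2 nt of a true start counts as correct under the default matching
tolerance). Protein models score an 11-residue window around every S or T
with `classify_st_windows()`, padding truncated flanks with the unknown
symbol.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 22 | variables kept by RFE; mirrors the practical input limit of truth-table minimizers, and keeps rules small enough to read at once |
| `cost` | 1.0 | SVM soft-margin penalty; the ranking, not the decision boundary, is consumed, and rankings are stable across moderate `cost` changes |
| `tolerance` (SVM) | 1e-6 | solver termination; fixed for determinism |
| `exact_limit` | 16 | width bound for the exact minimizer |
| `heuristic_limit` | 22 | width bound for the heuristic minimizer |
| `policy` | `"drop"` | contradictions are deleted; `"majority"` keeps the majority label and drops ties |
| cutoff | `cutoff_all_rules()` | every rule-satisfying window is positive; tighten with `cutoff_top_fraction()` / `cutoff_min_score()` |
| matching tolerance | 2 nt | slack between predicted and true start counted as a correct site call |

## What the synthetic generators emulate — and what they do not

Real curated site collections cannot be redistributed here, so the package
ships seeded generators with the same statistical shape:

* `motif_spec()` + `implant_motifs()` — a 14-nt binding-site motif with a
  conserved 5-position core (defaults `6:G, 7:C, 8:A, 9:A, 10:T`), each
  core position substituted at rate 0.05, implanted at least `min_gap`
  apart in i.i.d. background DNA. This mirrors a study design of a few
  dozen verified sites hidden in ~20 kb of sequence with held-out sites
  scored at ±2 nt. Values chosen once: 60 sites in 20 kb keeps site density
  realistic while giving a 90/10 split enough training windows; mutation
  rate 0.05 reproduces the "similar but variable" character of real
  binding sites.
* `glyco_spec()` + `generate_glyco_dataset()` — 11-residue windows centered
  on S or T; positives draw flanking residues from positional preference
  weights (default: threonine strongly favored at −4, −2, +2, +4 and
  disfavored at +1, +3, +5, echoing the hydrophilic-enhancement flavor of
  known O-glycosylation neighborhoods), negatives draw uniformly.

What passing tests on these data do **not** show: real genomic background
is not i.i.d. (repeats, CpG structure, composition drift), real binding
sites have graded position-specific preferences rather than a fixed core,
and real glycosylation depends on structure the window never sees. The
generators validate the machinery — encoding, selection, minimization,
scoring, evaluation — not biological performance.

A related honesty note on interpretability: with ~54 positive and ~54
negative training windows, the training sample does not fully identify the
conserved core. Rules must sometimes block a chance-similar negative with a
literal outside the core, and the SVM occasionally ranks a background
variable above a weak core variable. On the default synthetic conditions
about 90–95 % of rule literals land on core positions, but the stricter
event "every literal of every rule on a core position" holds only in
roughly half to two-thirds of replicates. This is a property of the sample
size, not of the minimizer: no data-driven objective can prefer a core
literal that the sample makes indistinguishable from a background one.

## Numerical and design choices

* Minterm indices read the leftmost variable as the most significant bit;
  cubes are strings over `{0,1,-}` in window order.
* Exact-cover ties break toward the lexicographically smallest sorted cube
  list (`'-' < '0' < '1'`), so `qm_minimize()` output is unique.
* Single thresholds binarize with a strict `>`; with several thresholds a
  boundary value joins the enclosed interval (so `X = 0.5` under cuts
  `(.25, .75)` gives interval bits `010`).
* An S/T window at a protein end is padded with `X` rather than discarded —
  the 21st encoding category exists precisely for incomplete sequence.
* Prediction-to-truth matching is greedy one-to-one, nearest pair first,
  lowest position on ties; unmatched predictions are false positives,
  unmatched truths false negatives. Ratios with zero denominators are
  reported `NA`, never 0.
* Degenerate inputs: an empty on-set minimizes to an empty cover; an
  all-contradictory training set is an error; a rule covering no positive
  training pattern is kept but flagged with a warning and score 0.
* All generators take an explicit integer seed and are reproducible.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script exercise: the 4-variable worked
truth table and its 2-rule cover; 200 random partially-specified functions
of 3–10 variables (on-sets of a few dozen minterms — the regime the
pipeline produces, where every unseen pattern is a don't-care), with
brute-force minimality certificates at widths where exhaustive prime
enumeration is tractable; 10 seeded binding-site replicates (60 sites,
20 kb, k = 22); and one glycosylation model (300 + 300 windows, k = 20).
These sizes were chosen as the smallest that exercise every code path at
realistic dimensions.

## Known limitations

* Forward-strand scanning only; reverse-complement hits need a second scan
  of the reverse complement.
* Single-output minimization; no multi-valued logic or BDD back-end.
* The exact minimizer's branch-and-bound can be slow on dense on-sets at
  ≥ 12 variables even below `exact_limit`; the heuristic has no such cliff.
* Rule scores count training popularity, not statistical significance; a
  score-0 rule warning usually indicates a cover kept alive by don't-cares
  alone.
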