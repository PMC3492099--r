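# sitelogic

Interpretable boolean rules for predicting functional sites in molecular
sequences — transcription-factor binding sites (TFBS) in DNA and
O-glycosylation sites on serine/threonine residues in proteins.

Most sequence classifiers (SVMs, neural networks) predict well but explain
nothing. `sitelogic` takes the opposite route: it turns a set of labeled
sequence windows into a *partially specified boolean function* and applies
two-level logic minimization to extract a handful of human-readable rules
that perform the same classification.

The pipeline:

1. **One-hot encoding.** Each nucleotide becomes 4 bits (A = 1000,
   C = 0100, G = 0010, T = 0001), each residue 21 bits (20 amino acids in
   full-name alphabetical order + an "unknown" category), so every binary
   variable has a plain meaning such as *"Nucleotide 7 is/is not C"*.
2. **SVM-RFE.** A linear soft-margin SVM ranks the variables by recursive
   feature elimination (drop the smallest \(w_i^2\) each round) and keeps
   the top *k* (default 22, the practical width limit of truth-table
   minimizers).
3. **Logic minimization.** Observed positives form the on-set, observed
   negatives the off-set, and every unseen pattern is a don't-care. The
   table is minimized exactly (Quine–McCluskey prime implicants + an exact
   minimum-cover search) or heuristically (an ESPRESSO-style
   EXPAND/IRREDUNDANT/REDUCE loop) into a small sum-of-products cover —
   each cube is a rule like *"if Nucleotide 9 is A and Nucleotide 10 is T
   then the window is a site; everything else is not"*.
4. **Rule scoring.** Each rule's *score* is the number of positive training
   patterns it covers; a test window's score sums the rules it satisfies.
   Cutoffs (`cutoff_all_rules()`, `cutoff_top_fraction(f)`,
   `cutoff_min_score(s)`) trade sensitivity against precision.
5. **Prediction & evaluation.** Sliding-window genome scans (a hit within
   ±2 nt of a true start counts as correct) or per-S/T window calls, with
   sensitivity = 100·TP/(TP+FN) and PPV = 100·TP/(TP+FP).

Seeded synthetic-data generators (motif-implanted DNA; protein windows with
positional residue preferences) make the whole workflow testable without
any external databases.

## Worked example

The textbook 4-variable function whose outputs are 1 for patterns
{0000, 0010, 0011, 1000, 1010, 1011} and 0 for the rest reduces to two
rules:

```r
library(sitelogic)

f <- truth_function(4, on_set = c(0, 2, 3, 8, 10, 11),
                    off_set = c(1, 4, 5, 9, 12, 13))
qm_minimize(f)
#> <logic_cover> 2 cube(s) over 4 variables [quine-mccluskey]
#>   --1-
#>   -0-0
```

i.e. *output is 1 iff (C = 1) or (B = 0 and D = 0)* — variable A is
irrelevant. The same engine drives the genomic case. Below, 60 synthetic
binding sites (14 nt, conserved core at positions 6–10, 5 % per-position
mutation) are implanted in 20 kb of background; a model is trained on 54 of
them plus 54 random windows, and the sequence is scanned for the 6 held-out
sites:

```r
spec <- motif_spec()                      # core 6:G 7:C 8:A 9:A 10:T
bg   <- generate_background_dna(20000, seed = 11)
imp  <- implant_motifs(bg, spec, n_sites = 60, min_gap = 20, seed = 12)
sites <- vapply(imp$true_starts, \(s) substr(imp$sequence, s, s + 13), "")

set.seed(13); idx <- sample(60, 54)
train <- tibble::tibble(
  sequence = c(sites[idx], sample_negative_windows(54, seed = 14)),
  label    = rep(c(1L, 0L), each = 54))

model <- train_site_model(train, kind = "tfbs", k = 22)
tidy(model)
#> # A tibble: 4 × 3
#>   cube                   score conditions
#>   <chr>                  <dbl> <chr>
#> 1 ------1--00--000------    48 Nucleotide 7 is C and Nucleotide 10 is not C and Nucleotide 8 is not C and Nu…
#> 2 ----1----0----000-----    47 Nucleotide 6 is G and Nucleotide 10 is not C and Nucleotide 8 is not C and Nu…
#> 3 ---0--1--00---0-0-----    39 Nucleotide 7 is C and Nucleotide 8 is not C and Nucleotide 10 is not A and Nu…
#> 4 ------1-1-----0------0    38 Nucleotide 8 is A and Nucleotide 7 is C and Nucleotide 10 is not A and Nucleo…

hits <- scan_sequence(imp$sequence, model)
pred <- hits$start[apply_cutoff(hits$score)]
evaluate_predictions(match_predictions(pred, imp$true_starts[-idx], tolerance = 2))
#> # A tibble: 1 × 5
#>      TP    FP    FN sensitivity   ppv
#>   <int> <int> <int>       <dbl> <dbl>
#> 1     6  2387     0         100 0.251
```

Four rules, whose literals sit on the conserved core positions 6–10,
recover all six held-out sites. The PPV is low in absolute terms — a
handful of true sites against ~20,000 candidate windows — which is exactly
why the score cutoffs exist: `cutoff_min_score()` or
`cutoff_top_fraction()` raise precision at a quantified sensitivity cost.
`autoplot(hits, true_starts = imp$true_starts)` draws the score profile.

For proteins, `glyco_spec()` / `generate_glyco_dataset()` build S- or
T-centered window sets, `train_site_model(kind = "glyco")` learns rules
such as *"Amino Acid in Position −2 is T and Amino Acid in Position 4 is
T"*, and `classify_st_windows()` scores every S/T in a protein.

A command-line interface wrapping these functions is installed at
`exec/sitelogic` (subcommands `simulate-tfbs`, `simulate-glyco`, `encode`,
`minimize`, `rank`, `train`, `scan`, `classify`, `evaluate`; Berkeley PLA,
FASTA and TSV in/out).

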