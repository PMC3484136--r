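---
title: "Methods: hairpin classification with position-specific fixed-order Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hairpin classification with position-specific fixed-order Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirfom)
```

## The problem and the model

Animal pre-miRNAs are ~60–120 nt stem-loops excised by Drosha/DGCR8 and
processed by Dicer; genomes are full of hairpins that look superficially
similar but are never processed. `mirfom` treats recognition as a property
of the *secondary structure pattern around the mature miRNA*: if the
processing machinery reads a structural signature, then a position-specific
model of structure columns over the mature region should separate true
precursors from pseudo-hairpins, locate the mature window, and carry some
arm information — all from one scoring pass.

The hairpin is first reduced to a linear column string. Bracket matching
gives the pair table; the **main stem** is the root-to-hairpin-loop path of
the structure tree carrying the most base pairs, and every pair on a
discarded branch is demoted to an unpaired base (branch-rich plant
precursors then still present a single clean stem). Columns are emitted
loop→tail over the six-symbol stem-bulge-gap alphabet: `|`, `!`, `:` for
CG-, AU- and GU-class pairs, `o` for hairpin-loop columns, `x`/`-` for the
symmetric/asymmetric parts of internal loops and bulges.

Windows of W = 24 columns are scored by an order-D fixed-order Markov model
that is *position-specific*: the conditional distribution of the symbol at
window position $i$ depends on the $D$ previous symbols **and** on $i$
itself,

$$\log P(x \mid M) = \sum_{i=D+1}^{W} \log \hat P(x_i \mid x_{i-D..i-1},\, i),$$

with the initial context contributing probability 1 (the first $D$
positions are skipped; there is no context padding). Conditional
probabilities are smoothed counts,
$\hat P(\sigma\mid s,i) = (N(\sigma,s,i)+\alpha)/(\sum_{\sigma'}N(\sigma',s,i)+\alpha|\Sigma|)$.
A *True* model (one mature-covering window per annotated precursor) and a
*False* model (every window of every pseudo-hairpin — deliberately
asymmetric, with no class re-balancing) give the log-odds score `FOM`;
natural logarithms throughout, so scores are in nats.

## Assumptions

* Structures are nested (no pseudoknots) and pairs fall in the CG/AU/GU
  classes; degenerate bases (N, ambiguity codes) are rejected at input
  rather than guessed.
* The mature signature is local to a 24-column window and approximately
  position-stationary across precursors once windows are aligned — this is
  what sliding one shared model assumes.
* The feature score depends only on the whole molecule, so it shifts a
  hairpin's profile uniformly and can never move the peak; it only
  arbitrates the final threshold decision.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `D` | 3 | columns | context length; the model is fitted per (context, position) cell, so larger D needs exponentially more windows |
| `W` | 24 | columns | window width, matching the ~22–24 nt mature product |
| `alpha` | 1 | counts | add-α pseudocount; strictly positive probabilities, reduces to ML as α→0 |
| `feature_weight` | 50 | nats | weight of the logistic MFE-feature score; bounds the feature's influence at ≤ 50 nats |
| `valley_len` | 5 | offsets | minimum strictly-lower run after a peak |
| `threshold` | 11 | nats | decision cut on `FOM_plus`, inclusive ("reached" ⇒ ≥); `train_pipeline()` replaces it with a data-driven cut |
| `step` | 1 | columns | sliding step |

The shipped threshold of 11 is tied to the natural-log convention and to
training at the original scale (hundreds of precursors, thousands of
negative windows); retraining on other data should use the pipeline's own
chosen cut, which maximizes training accuracy over midpoints between
adjacent observed scores (ties towards the larger cut, favoring
specificity). With one record per class this lands strictly between the two
scores rather than on one of them.

## Numerical and convention choices

These conventions are fixed so that training and scanning always agree;
any consistent alternative would work, but consistency is what matters.

* **Loop folding.** A hairpin loop of $L$ bases folds at its midpoint into
  $\lceil L/2\rceil$ `o` columns; an odd middle base gets its own column
  (mapped on the 5′ side, counted once). Every nucleotide appears in exactly
  one column map — this conservation is asserted property-style in the
  tests.
* **Bulge layout.** In an internal region with $a$ unpaired 5′ and $b$
  unpaired 3′ bases, the $\min(a,b)$ symmetric `x` columns precede the
  $|a-b|$ asymmetric `-` columns, loop side first. Terminal single-stranded
  tails are encoded the same way (flag `include_tails`), so the scan truly
  runs loop→tail over the whole molecule.
* **Main-stem ties.** "Longest stem" counts base pairs, not nucleotide
  span; equal arms resolve to the 5′-most branch.
* **Peak rule.** Plateaus are collapsed before local-max testing; a peak
  qualifies if followed by ≥ `valley_len` consecutive strictly lower
  offsets before any score ≥ the peak reappears; the first qualifying
  peak's first plateau offset is reported. Monotone or very short profiles
  have no qualifying peak, and the global maximum is used as a flagged
  fallback — otherwise short-but-real hairpins could never be called.
* **Strand ties.** Equal strand log-scores resolve in the fixed order
  5p > 3p > both.
* **MFE indices.** Computed on the full structure (before main-stem
  reduction): dMFE = −MFE/n × 100, GC as a percentage, stems as maximal
  helices of ≥ 3 stacked pairs, MFEI4 on the signed (negative) MFE. The
  defining literature varies in sign/scale conventions; these defaults are
  recorded with the output.
* **Degenerate inputs.** Zero GC, zero pairs, zero stems or missing MFE are
  hard errors ("degenerate hairpin"), never silent division by zero; batch
  prediction catches them per record and continues.

## What the synthetic data emulate — and what they do not

`generate_hairpin()` builds sequence and dot-bracket jointly from the loop
outwards: 26–34 stem pairs, 4–8 nt loops, occasional one-column bulges
(rate 0.08), pair classes from a background mix, and a pseudo-MFE of
−(1.5 n~CG~ + 1.0 n~AU~ + 0.5 n~GU~) kcal/mol — a deterministic,
stacking-free stability surrogate. Positive records carry a planted
24-column window at a fixed offset whose pair classes follow an arm
signature: odd window positions share one deliberately aperiodic
dominant-class pattern (the true/false and offset signal — no shift of the
window aligns with itself), even positions carry one arm-specific dominant
class (CG/AU/GU for 5p/3p/both — the strand signal). Dominant classes have
probability 0.95: with ~21 scored transitions per window the per-window
score noise must stay well below the class separation, and softer biases
(0.8–0.85) measurably blur the two score distributions into overlap.

The generator emulates the *geometry and information structure* the method
assumes, not biology: no stacking thermodynamics, no sequence composition
biases, no miRBase-style annotation idiosyncrasies, no cross-species
variation. Passing the planted-signal study therefore shows the pipeline
recovers a recoverable signal end to end — it does not certify real-data
accuracy, which depends on how strongly real precursors carry the
structural signature.

For parameter-recovery testing, `deterministic_recovery_chain()` uses
deterministic transition rows over a two-symbol support with uniform
initial contexts. This is intentional: with 10⁴ windows spread over 8
contexts, any non-trivial stochastic row leaves per-cell standard errors of
~0.013, and the maximum over ~300 cells then exceeds a 0.02 max-norm bound
with high probability — a deterministic chain isolates what the bound is
meant to measure (correct count indexing plus the known smoothing bias
≤ 5/(N+6)), while a separate corpus test covers stochastic rows via
marginal frequencies and sign separation.

## Problem sizes

The test suite and acceptance script run entirely on synthetic data:
100 toy corpora for the Markov-core oracle (W ≤ 6, D ≤ 2, ≤ 5 segments),
10⁴ windows for parameter recovery, 500 fixtures for encoding conservation,
all ~10⁵ dot-bracket structures of ≤ 14 nt (≤ 4 pairs) for main-stem
selection, 1 000 random profiles for the peak rule, and a 200 + 200 hairpin
planted-signal study with 5-fold cross-validation. These sizes keep the
whole suite in the low minutes on one core while leaving the statistical
margins (e.g. recovery error 0.004 vs bound 0.02) wide.

## Known limitations

* Pseudoknots and suboptimal/ensemble structures are out of scope; one
  dot-bracket per hairpin.
* The strand model reads the same orientation-free SBG columns as the
  classifier, so on real data its signal is indirect (pair classes are
  unoriented); arm calling is the weakest of the three outputs.
* Windows need ≥ 24 columns; very short hairpins are reported as structured
  per-record failures rather than forced calls.
* The shipped logistic coefficients are fixed, fitted values; they are
  exposed via `feature_coefficients()` but the package does not refit them.
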