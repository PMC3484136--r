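# mirfom

Full-function recognition of microRNAs from candidate hairpins: given an RNA
stem-loop (sequence + secondary structure), `mirfom` decides whether it is a
genuine pre-miRNA, locates the ~22 nt mature miRNA inside the precursor, and
calls the arm (5p, 3p or both) that carries it. It is aimed at people
screening hairpin candidates — e.g. stem-loops pulled from genomic scans or
small-RNA-seq loci — who need more than a yes/no precursor call.

## The model

The predictor works on the *secondary structure pattern* of the hairpin, not
its primary sequence. Each hairpin is reduced to its **main stem** (the
root-to-loop helix path with the most base pairs; side branches are demoted
to loops/bulges) and rewritten, loop to tail, in a six-symbol
**stem-bulge-gap (SBG) alphabet**:

| symbol | meaning |
|---|---|
| `\|` | CG-class base pair |
| `!` | AU-class base pair |
| `:` | GU-class base pair |
| `o` | hairpin-loop column (loop folded at its midpoint) |
| `x` | symmetric part of an internal loop/bulge |
| `-` | asymmetric part (gap) |

A **position-specific fixed-order Markov model** of order D = 3 over windows
of W = 24 columns gives the probability of a window x under a model M:

    P(x | M) = prod_{i=D+1..W} P( x_i | x_{i-D..i-1}, i ),

with the initial-context probability fixed at 1 and add-alpha smoothing
(alpha = 1) over the alphabet. Two such models are trained — a *True* model
on the single window covering each annotated mature miRNA, and a *False*
model on every window of pseudo-hairpins — and a window is scored by the
log-odds `FOM = log P(x|True) - log P(x|False)` (nats).

Windows slide from loop to tail with step 1. Three minimum-free-energy
indices of the whole molecule (MFEI1 = dMFE/GC%, MFEI2 = dMFE/#stems,
MFEI4 = MFE/#pairs, with dMFE = -MFE/n x 100) enter through a fitted binary
logistic score, and the combined track is

    FOM_plus = FOM + 50 x logistic(-13.686 - 0.209 MFEI1 + 0.034 MFEI2 + 1.679 MFEI4).

The reported window is the first profile peak followed by a valley of at
least 5 offsets (global maximum as fallback); the hairpin is called a
pre-miRNA when its best `FOM_plus` reaches the decision threshold
(`>=`, default 11 for models trained at scale; `train_pipeline()` chooses a
data-driven threshold by best training accuracy). For positives, a third
Markov model over the same contexts emits strand labels, and
`argmax_st sum_i log P(st | x_{i-D..i-1}, i)` calls 5p/3p/both; the window
columns are mapped back to precursor coordinates on the called arm(s).

Because curated precursor collections cannot ship with the package, a
first-class synthetic module (`generate_dataset()`, `generate_hairpin()`,
`sbg_chain()`) builds seeded hairpins with planted mature-window signatures,
so training, scanning and evaluation are fully testable offline.

## Worked example

```r
library(mirfom)

ds    <- generate_dataset(n_pos = 100, n_neg = 100, seed = 11)
model <- train_pipeline(ds$positives, ds$negatives)
model
#> <mirfom_model> D=3 W=24 alpha=1, threshold 4.036
#>   training: sen 0.990, spe 1.000, acc 0.995 (100 pos, 100 neg)

predict_hairpin(model, ds$positives[[1]])
#> <mirna_prediction> pos0001: pre-miRNA (plus 23.830 vs threshold 4.036)
#>   best window at column 5 (global-max fallback), strand 3p
#>   mature 3p: 34-57

cv <- kfold_cv(ds$positives, ds$negatives, k = 5, seed = 12)
round(cv$mean, 3)
#>   sen   spe   acc
#> 0.970 0.980 0.975
```

The model separates planted precursors from background hairpins (training
accuracy 0.995; the data-driven threshold 4.04 nats sits in the score gap),
recovers the planted mature window (column 5, the generator's planted
offset; the valley rule falls back to the global maximum on these short
profiles), calls the correct arm, and maps the window to precursor
coordinates 34–57 — exactly the record's annotated 3p mature region.
Held-out 5-fold performance stays near perfect on this separable synthetic
set.

A thin command-line front end over the same functions ships in
`inst/cli/mirfom.R` (`train` / `predict` / `evaluate` on Vienna + annotation
files).

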