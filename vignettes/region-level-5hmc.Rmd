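---
title: "Region-level 5hmC prediction from k-mer embeddings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-level 5hmC prediction from k-mer embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the models implemented in `rna5hmc`, the assumptions
behind them, the parameters that matter, and the design decisions taken where
the method leaves room. It states no empirical numbers beyond what the test
suite and `scripts/acceptance.R` compute themselves.

## The task and its resolution

hMeRIP-seq reports 5hmC at region resolution: a peak interval on a transcript
says "somewhere in these hundreds-to-thousands of nucleotides there is
modification", not which cytosine carries it. The benchmark this package
builds therefore labels whole regions. Positives are peak sequences read
strand-aware (minus-strand intervals are reverse-complemented before the
T-to-U transliteration, so every sequence reads 5'-to-3' on its transcript).
Negatives are sampled from the non-peak remainder of the same peak-carrying
transcripts and cropped to exactly the length of their partner peak
(one-vs-one), which removes both composition drift between expressed and
non-expressed regions and any length signal — a classifier cannot win by
reading sequence length alone.

Coordinates follow the BED convention (0-based, half-open) throughout; the
method itself is convention-agnostic, but one convention had to be fixed and
BED is what the input files use.

## k-mer embeddings

For each word length k the genome corpus — selected chromosomes split into
consecutive non-overlapping 10-kb fragments — is turned into a token stream
of overlapping k-mers, and a skip-gram model with negative sampling is
trained on it. Each k gets its own independent model: the encoder never adds
or compares vectors of different k (means are taken within k, concatenation
across k), so nothing is gained by forcing all word lengths into one joint
space, and per-k training keeps each model's vocabulary homogeneous.

Tokens containing N are dropped from the stream rather than mapped to a
sentinel, keeping the vocabulary inside the 4^k words over ACGT that the
embedding table indexes.

Training hyperparameters (all exposed):

| parameter  | default | role |
|---|---|---|
| `dim`      | 100     | embedding dimension; the per-k feature block size |
| `window`   | 10      | maximum context distance; the effective window per position is drawn uniformly from 1..window, as in word2vec, which downweights distant context |
| `epochs`   | 10      | passes over the corpus |
| `negative` | 5       | negative samples per observed (center, context) pair |
| `alpha`    | 0.025 → 1e-4 | linearly decayed SGD learning rate |

The trainer (C++, single-threaded) uses its own xorshift RNG seeded from the
`seed` argument, so results are bitwise reproducible and training does not
disturb R's random stream. The sigmoid is looked up from a 1024-entry table
on [-6, 6] and the vectors are single precision — the standard word2vec
arithmetic; reproducibility is exact because the operation order is fixed.

There is no installed R implementation of word2vec-style training in this
stack, and the embedding step is close enough to the method's substance that
it is implemented here rather than delegated.

## Sequence encoding

A sequence of length l yields l−k+1 overlapping k-mers; their embedding
vectors are averaged and the per-k means concatenated in ascending k. Two
readings of the per-k pooling were possible — a raw sum, or the mean — and
the mean is implemented: inputs span more than an order of magnitude in
length, and a sum would make the feature norm grow linearly with l, swamping
composition with length. The mean maps every region into the same bounded
feature space.

Out-of-vocabulary tokens (N-containing, or k-mers absent from the training
corpus) are skipped *and the divisor reduced accordingly*, so the result is
always the mean of the vectors actually used. The alternative — dividing by
l−k+1 regardless — would shrink features of N-rich sequences toward zero,
conflating assembly quality with composition. A sequence with no usable
token at some k cannot be encoded and is reported by id in one aggregated
error.

Lookup canonicalizes RNA to the DNA alphabet (U→T, uppercasing) because the
embedding corpus is genomic DNA; the encoder therefore accepts RNA strings
directly.

## The classifier

The SVM uses the RBF kernel exp(−γ‖e_i−e_j‖²) via libsvm (`e1071`). Features
enter unscaled, so γ acts on raw feature distances exactly as the kernel
formula states. Hyperparameters come from an exhaustive grid over
c = 2⁻⁵, 2⁻³, …, 2¹⁵ and γ = 2⁻¹⁵, 2⁻¹⁴, …, 2⁻⁵ — log₂ exponent steps of 2
and 1 respectively, which is the only reading of the published step sizes
("2 and 2⁻¹") consistent with an 11-value γ range and with reported optima
on odd exponents. Selection maximizes cross-validated accuracy (the
selection metric is configurable); ties break toward smaller c, then smaller
γ — the less complex model. The full score table is returned for mesh plots.

Tuning is *not* nested inside the evaluation protocol: the grid search runs
once on the full training set and the chosen (c, γ) is then assessed by
repeated cross-validation with fresh fold shuffles. This matches the usual
practice of reporting "optimal performance" for this family of predictors
and is the package default; nested evaluation can be assembled from the
exported pieces when unbiased generalization estimates are required — the
non-nested estimate carries a modest optimism, which is visible in the
chance-level baseline the acceptance analysis reports.

Binary cross-entropy is provided in its standard form,
−mean(y·log h + (1−y)·log(1−h)), with predictions clipped to [ε, 1−ε]
(ε = 1e-12) so exact 0/1 inputs stay finite. A gain-ratio score
(information gain over intrinsic value, entropies in bits, degenerate splits
scoring 0) supports feature analysis. A convolutional network and a full
C4.5-style pruned tree are deliberately out of scope for this package: the
SVM is the supported classifier, and no deep-learning stack is part of the
package's dependency footprint.

## Evaluation

Confusion-matrix metrics follow the exact formulas: Sen = TP/(TP+FN),
Spe = TN/(TN+FP), Acc = (TP+TN)/total, and
MCC = (TP·TN − FP·FN)/√((TP+FN)(TN+FN)(TP+FP)(TN+FP)). When any factor of
the MCC denominator is zero (a constant prediction or a one-class truth),
MCC is reported as 0 with a `mcc_degenerate` flag — the common convention;
an error would make batch evaluation brittle and any other value would claim
information that is not there. The counts are coerced to doubles before the
product, which overflows 32-bit integers already at a few hundred samples
per cell.

ROC and PR curves sweep the unique score values; tied scores collapse into
one threshold. AUROC is the trapezoidal area (equal to the Mann–Whitney
pair-counting statistic for tie-free scores, which the tests verify); AUPR
uses step interpolation (precision times recall increment — the average
precision form), which does not over-credit the sawtooth of the raw PR
curve.

The protocol is repeated stratified cross-validation, default 10 repeats of
5 folds. Folds are stratified because the benchmark is class-balanced by
construction and stratification keeps every fold that way. Within one
repeat, held-out predictions of the 5 folds are pooled and metrics computed
once on the pool (per-repeat pooling); mean and standard deviation are then
taken across the 10 repeats. Pooling per repeat avoids the instability of
per-fold confusion tables at small n; reporting spread across repeats (not
across all 50 folds) answers "how much does the estimate move when the
partition changes", which is the question repetition asks.

## Separability and visualization

The J-score is the Fisher criterion scalarized by traces:
J = tr(S_b)/tr(S_w), where S_b is the outer product of the class-mean
difference and S_w the summed centered scatter of both classes. The defining
equations produce matrices while the score is reported as a scalar; the
trace ratio is the standard scalarization, equals the hand-computable
"squared mean distance over total within-class variance", and inherits
translation and rotation invariance (both verified in tests). Zero
within-class scatter raises an explicit infinite-separation flag instead of
dividing by zero.

PCA projections fix the sign of each component (largest-magnitude loading
positive) so repeated runs are identical. t-SNE is implemented exactly
(O(n²) affinities, perplexity by bisection, early exaggeration, momentum
gradient descent) because no t-SNE package is available in this R stack; for
the few hundred points a feature map plots, the exact algorithm is the
appropriate choice anyway. Perplexity defaults to 30 and is reduced
automatically to (n−1)/3 for small inputs.

The complement-symmetry report quantifies what is usually only shown
visually: after 2-D PCA of an embedding table, each k-mer is paired with its
complement and its reverse complement, and the score is the Pearson
correlation between a token's second principal coordinate and the negated
coordinate of its partner (mirror arrangement about the first axis ⇒ score
near 1). Self-paired palindromic tokens are listed but excluded from the
correlation. The score's definition is this package's own construction.

## The synthetic fixture: what it emulates and what it does not

The generator reproduces the *structure* of the real benchmark: several
chromosomes (default 4 × 100 kb, GC 0.43, i.i.d. nucleotides), 50
transcripts each carrying exactly one peak, strands assigned at random, peak
lengths drawn from a truncated lognormal (meanlog = log(800), sdlog = 0.8,
clipped to 200–8000 nt) — right-skewed, as real region-length distributions
are, while spanning the full published range. Transcripts are sized as twice
the peak length plus 300–2000 nt slack so a disjoint, same-length negative
always exists by construction.

Positives are made learnable by planting a fixed 100-nt element at one
random position inside each peak (strand-aware), with probability
`motif_rate`. One immunoprecipitated fragment is on the order of 100–200 nt,
so a single element of that scale is the minimal realistic analogue of the
modified context a real peak contains; a planted ~10-nt motif would be
informationally invisible after mean-pooling a multi-kilobase region, and a
signal on every base would be trivially separable. `motif_rate = 0` gives an
exact null in which the two classes are statistically identical.

What the fixture does *not* emulate: real genome composition (repeats,
isochores, codon structure), transcript architecture (introns, isoforms,
UTRs), peak-calling noise, or distributed low-level enrichment across the
whole peak. Passing the recoverability tests therefore shows the pipeline
can extract a localized compositional signal under realistic length
dilution — it does not certify performance on real hMeRIP data, whose
signal structure is richer and noisier.

Fixture pipelines train embeddings in a reduced configuration — k = 3..5,
dimension 20, window 5, 3 epochs on the ~400-kb fixture genome — so that a
complete run (genome → embeddings → encoding → grid search → repeated CV)
finishes in seconds while exercising every stage; the full k = 3..8 /
dim = 100 configuration is the package default for real use. The evaluation
sizes used by the test suite and the acceptance script (3–5 repeats of
5-fold CV on 100 samples, 10 null fixtures, 50 sequences per resolution
length) were chosen as the smallest sizes at which the checked properties
are stable.

## Resolution analysis

To probe how short an input the region-trained model tolerates, negative
sequences of fixed lengths are sampled from the non-peak portions of the
peak-carrying transcripts, excluding (by interval subtraction) both the
peaks and the benchmark negatives, so the probe set shares no region with
anything the model saw. Only specificity can be measured — there are no
known positives at arbitrary lengths — and the expected picture is high Spe
near training-scale lengths and degradation an order of magnitude below,
where the mean-pooled features of short background sequences become noisy
enough to cross the decision boundary. Lengths that no pool region can host
are skipped with a warning rather than silently truncated.

## Degenerate inputs and numerical conventions

- Intervals must satisfy 0 ≤ start < end; out-of-bounds extraction and
  unknown chromosomes are errors, not clipped.
- Peaks whose host transcript offers no feasible negative placement are
  dropped *with their pair* and a warning, preserving one-vs-one matching.
- A peak overlapping several transcripts is assigned to the one with the
  greatest overlap, ties to the leftmost start (deterministic).
- Duplicate peak intervals are kept (and noted); deduplication is a data-
  cleaning decision the caller should make explicitly.
- Embedding table I/O uses the word2vec text format; read(write(x)) is exact
  to float round-trip (~1e-6 per component, 9 significant digits written).
- All stochastic steps (genome generation, negative placement, fold
  shuffles, window sampling, negative sampling in SGD, t-SNE init) are
  seeded; two runs with equal seeds agree bitwise.

## Known limitations

- The embedding trainer is single-threaded by design (determinism over
  speed); genome-scale corpora at k = 8, dim = 100 take correspondingly
  longer than the reduced fixture configuration.
- Mean pooling discards positional information entirely; the model cannot
  localize the modification within a region, only label the region.
- The non-nested tuning default slightly inflates cross-validated scores;
  the null-fixture baseline quantifies that inflation empirically.
- Negative sampling assumes the non-peak portions of peak-carrying
  transcripts are truly unmodified; undetected peaks would contaminate the
  negative class.
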