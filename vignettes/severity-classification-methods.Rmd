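---
title: "Methods: CNN severity classification of psychiatric evaluation records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNN severity classification of psychiatric evaluation records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevcnn)
```

## The problem

Initial psychiatric evaluation records are judged for the severity of
positive-valence symptoms (reward-seeking abnormalities: mania, substance
abuse, obsessive-compulsive disorder, depression) on an ordinal four-class
scale: ABSENT < MILD < MODERATE < SEVERE, with integer scores 1..4. The
records mix three text formats — narrative prose under section headings,
attribute–value lists, and question–answer templates — and the original
corpus for this task is access-restricted. This package therefore couples a
seeded synthetic-record generator with the full modelling and evaluation
stack, so that every behaviour of the pipeline is testable end to end on
data whose properties are known by construction.

## The model family

A record is tokenised and embedded as a word matrix $w_{1:n} = w_1 \oplus
w_2 \oplus \dots \oplus w_n$, $w_i \in \mathbb{R}^d$. A convolution filter
of region size $h$ spans $h$ consecutive word rows and the full embedding
width; at window $i$ it produces $c_i = f(w \cdot x_{i:i+h-1} + b)$ with
$f$ = ReLU, yielding a feature map $c = [c_1, \dots, c_{n-h+1}]$. Three
poolings are implemented:

* **1-max**: $\hat c = \max(c)$ — one value per filter;
* **parallel**: several region sizes, each with its own filter bank, pooled
  outputs concatenated;
* **chunk-max**: the map is split into $l$ contiguous chunks and each chunk
  is max-pooled, $\hat c_i = \max(c_{i1}) \oplus \dots \oplus
  \max(c_{il})$, preserving coarse positional order.

The pooled vector (length = maps × chunks summed over regions) passes
through optional dropout and a fully connected 4-way softmax. Word
representations cover five regimes: fixed one-hot rows ($d = V$, frozen),
random-init 200-d uniform (±0.05) and 300-d Glorot-uniform, and pretrained
word2vec vectors either static (frozen) or dynamic (fine-tuned). Words
missing from a pretrained file — and any word on a forced-OOV list, used to
break unwanted similarity among question/answer tokens — get seeded random
rows.

## Metrics

Per-class MAE is the mean ordinal distance $|p(x_i) - y_i|$ over records of
one gold class; MMAE is the unweighted mean over the four classes
(imbalance-proof); NMAE divides each class's deviations by the largest
deviation possible for that class, $\max(y_i - 1, |C| - y_i)$ =
(3, 2, 2, 3), and subtracts from 1. The literature this package follows
states class scores as 0..3 in prose but the NMAE normaliser is coherent
only on 1..4; internal scores are 1..4, which leaves MAE/MMAE unchanged
(only differences enter) and reproduces the published NMAE values from the
published per-class MAEs. Cross-validation aggregates metrics per fold and
then averages; stratified folds balance every class within ±1 record, and a
fold can therefore never lack a class when `k` does not exceed the smallest
class count (enforced).

## The synthetic world

The generator's defaults restate the documented world: 433 records at class
proportions 14.08/38.33/25.4/22.17%, apportioned by largest-remainder
rounding with ties broken by class order (reproducing the published counts
61/166/110/96 exactly). Each record has a headed narrative, 3–4
attribute–value lines, and a questionnaire of 10 fixed template questions
rendered as `question? : answer` lines.

Class signal enters in two ways, both scaled by `cue_strength` (default
0.7, chosen so baseline MMAEs land in the realistic 0.2–0.7 range rather
than at either degenerate extreme): narrative cue tokens drawn from
per-class disjoint lexicons, and template answers
(Yes/No/None/Uncertain) whose distribution shifts with severity. With
probability `adjacent_share` (default 0.2) a cue leaks from an ordinally
adjacent class — this is what reproduces the adjacent-class confusion
structure of real severity annotations. At `cue_strength = 0` the text is
class-independent by construction. Several template questions deliberately
embed cue tokens verbatim ("mild", "severe", "crisis", ...): unnormalised,
those tokens appear in every record and dilute the narrative signal, which
is precisely the mechanism by which question normalisation helps every
model. Record length is a config knob (`n_sentences`); no fidelity to a
real length distribution is claimed. Noise defaults are light (2% token
fusions, 2% misspellings); every fusion the generator emits joins a
lowercase-to-uppercase or digit-to-letter pair, so the refinement rules
invert it exactly.

What a green test on this world does **not** establish: absolute MAE levels
comparable to the restricted corpus, robustness to real clinical
spelling/OCR noise, negation, or section semantics. The generator has no
negation, no cross-record patient structure, and vocabulary two orders of
magnitude smaller than real notes.

## Preprocessing decisions

* Question short forms are assigned **corpus-globally** by first appearance
  (the wording "in order of appearance" does not fix the scope): identical
  questions must share one token across records for Q-tokens to be
  informative features.
* The merged-token pattern `\d[A-z]` in the source is an ASCII-range quirk;
  it is interpreted as digit-followed-by-any-letter. Splitting is applied
  exhaustively, so refinement is idempotent.
* Spell correction is a pluggable whole-word table (bundled 20-entry
  frequency table) rather than an external spell-checker dependency; the
  build stays hermetic.
* Case is preserved through refinement (the split rules depend on it);
  vocabulary construction can lowercase via a flag, default off.

## Numerical and training decisions

* **Reserved index.** The vocabulary contract fixes $V$ = distinct tokens
  + 1, so a single reserved index serves both padding and OOV. Padding
  windows are masked out of pooling (a window that is entirely padding
  never contributes), so the shared index only carries OOV signal
  mid-sequence. One consequence: with right-padding, valid window positions
  are `1..min(len, max_length - h + 1)`.
* **Sequence length.** Right-pad/truncate to the 95th percentile of
  training-record lengths by default (the source is silent on length
  handling); truncation keeps the prefix.
* **Chunk remainder.** For a length-$m$ map and $l$ chunks, sizes are
  $\lceil m/l \rceil$ for the first $m \bmod l$ chunks, then
  $\lfloor m/l \rfloor$ — remainder to the earliest chunks, fixed so the
  test oracle can implement the same policy independently.
* **Optimiser.** The source states learning rates (0.001; 0.1 for
  chunk-max) but not the optimiser, loss, or batch size. Loss is 4-class
  cross-entropy; batch size defaults to 32. The default optimiser is Adam
  rather than plain SGD: with the stated rates and small-magnitude
  initialisations (uniform ±0.05 embeddings), plain SGD moves the
  parameters far too slowly to fit even perfectly separable data within the
  stated 150-epoch budget, while Adam's per-parameter scaling makes 0.001
  behave as those rates conventionally do in the frameworks of that era.
  SGD remains available (`train_config(optimiser = "sgd")`).
* **Ties.** Softmax argmax ties resolve to the lower severity — a reporting
  convention only.
* **Degenerate inputs.** A record shorter than the region size still
  convolves (its trailing windows overlap padding); a record with fewer
  valid windows than `chunk_count` raises an explicit error. Training
  aborts with a diagnostic on non-finite loss. `train_config()` enforces a
  positive learning rate per its contract; the zero-learning-rate
  invariance property is exercised by mutating the config object directly.

## Scaling of the shipped checks

The heavier behavioural checks run at reduced but honest scale so the suite
stays within a desktop-CPU budget: the separable-recovery check trains 60
of the allowed 150 epochs (it converges long before 60), and the
normalisation-effect check uses 10 generator seeds × 80 records × 4 folds ×
20 epochs. Thresholds are the stated ones; only problem size was scaled.

## Known limitations

Pure-R training loops cap practical corpus sizes at a few thousand records;
there is no GPU path. The gain-ratio tree is a compact stand-in for C4.5
(no error-based pruning), and the "SVM" baseline is a ridge-penalised
multinomial linear model — both are explicitly plumbing around the CNN
contribution, not re-implementations of those classifiers. Hunspell-style
context-aware correction is out of scope; the correction table is exact
whole-word lookup. No negation handling or section recognition is
attempted.
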