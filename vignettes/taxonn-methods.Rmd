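---
title: "Classifying long reads from canonical k-mer profiles: models and methods"
author: "taxonn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying long reads from canonical k-mer profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Taxonomic classification assigns sequencing reads to the organisms they came
from. For error-prone long reads (Oxford Nanopore, PacBio CLR), alignment-based
classifiers are sensitive but slow, and exact k-mer-matching classifiers are
fast but brittle: a read with several percent errors loses most of its long
exact k-mers, and reads from species absent from the reference database tend to
be misassigned or dropped. `taxonn` implements the alternative explored by
neural-network classifiers: represent a sequence by its **canonical short-k-mer
frequency profile** and let a small feed-forward network learn, from error-free
genome subsequences, features that transfer both to noisy reads and to novel
congeneric species.

Two properties make short canonical k-mer profiles a good encoding for this
setting. First, a single base error perturbs only k windows of the profile, so
for small k (default 6) the profile of a read at 90% accuracy is still close to
the profile of its source genome — the "distribution shift" between error-free
training data and noisy test reads stays small. Second, canonicalisation (every
k-mer is folded onto the lexicographic minimum of itself and its reverse
complement) makes the encoding strand-symmetric, so reads from either strand
produce identical features. The profile is also read-length agnostic, which a
fixed-input network needs.

## The feature space

For k-mer length $k$ there are $4^k$ DNA k-mers and
$(4^k - P)/2 + P$ canonical ones, where $P$ is the number of
reverse-complement palindromes ($P = 4^{k/2}$ for even $k$, $0$ for odd).
For $k = 6$: 2080 features. `buildKmerIndex(k)` enumerates this space with
integer 2-bit arithmetic; `kmerProfile()`/`kmerProfileMatrix()` count windows
with `Biostrings::oligonucleotideFrequency()` and fold the $4^k$ columns onto
canonical positions.

Handling of the edges of real data is deliberately permissive:

* windows containing any non-A/C/G/T character are skipped and do not count as
  valid windows (long reads with sparse Ns keep the rest of their signal);
* parsing is case-insensitive and U is read as T (soft-masked FASTA, RNA
  alphabet);
* profiles are **normalised to frequencies** (counts divided by valid windows)
  by default. On fixed-length training sequences raw counts and frequencies
  are equivalent up to a constant, but at inference the last chunk of a read
  may be shorter, and normalisation keeps such profiles on the same scale. Raw
  counts remain available (`normalize = FALSE`).

k beyond 12 is rejected: the dense canonical vector (8.4M features at k = 12)
is the practical ceiling of this representation.

## Training data from genomes, not reads

Models are trained on fixed-length subsequences sampled from reference
genomes. `sampleSequences()` draws `round(coverage * G / L)` windows of length
`L` (default 1000) at uniformly random offsets with replacement — coverage is
a sampling rate, not a tiling — on the forward strand only (canonical
profiles make the strand irrelevant, which the test suite verifies exactly).
Multi-contig genomes are sampled within contigs, proportionally to the number
of valid offsets, so no training sequence spans a contig junction.
`buildTrainingSet()` profiles the sample and labels each row at species or
genus rank, with classes ordered by sorted taxon id so label maps are
reproducible.

Defaults follow the regime where performance saturates in practice: 1 kbp
subsequences at 5x coverage per genome for training, with a smaller
independently-seeded sample (here 1x) as the validation set for early
stopping. The validation set is error-free by default; callers can corrupt it
explicitly if they want noise-matched early stopping.

## The synthetic taxonomy

`simulateTaxonomy()` provides a fully controlled stand-in for a reference
database. One ancestor genome per genus is drawn i.i.d. from the base
composition; each species genome is derived from its genus ancestor by
independent per-site substitution at rate $d$ (to one of the three other
bases, uniformly). Genomes of different genera are therefore unrelated
(~75% mismatch), while two congeneric species differ at an expected
$2d(1 - 2d/3)$ fraction of sites — about 3.9% at the default $d = 0.02$,
i.e. roughly the ANI neighbourhood of congeneric bacterial species.

What this emulates: a taxonomy with known within-genus structure, enough
shared genus-level signal for out-of-database generalisation experiments
(`holdoutSplit()` removes species per genus), and exact ground truth.
What it does **not** emulate: real genomes' skewed base and k-mer
composition, repeats, mobile elements, indel divergence, or shared content
across genera. Passing the end-to-end tests therefore shows the machinery is
correct and the generalisation mechanism works under controlled divergence —
it does not by itself predict performance on RefSeq-scale real data. Note one
consequence: with i.i.d. uniform ancestors all genera share the same
*expected* profile, so the network must learn genome-specific k-mer
fluctuations; in this respect the synthetic task is, if anything, harder than
separating real genera with distinct compositional signatures.

## The error model

`corruptSequence()` applies an i.i.d. per-base error model: each base is
selected for an event with a fixed probability; the event is a substitution
(to a uniformly chosen different base), a single-base insertion after the
position, or a deletion, with mix 0.5/0.25/0.25 by default. There are no
homopolymer-aware errors, no quality strings, and read lengths are preserved
in expectation (symmetric insertion/deletion weights).

"Median accuracy" is the calibration target: the realized **alignment
identity** of the corrupted read to its original, measured as
$1 - d_{\mathrm{edit}}/L$ with a unit-cost global edit distance (compiled in
`src/`, since a few hundred 5 kb x 5 kb dynamic programmes must run in
seconds). A subtlety dictates the internal event rate: at high error density
the optimal alignment realizes some event pairs more cheaply than their
nominal cost — an adjacent deletion+insertion collapses into one substitution
(or, with probability 1/4, into a match), and chance coincidences offer
cheaper paths. Large-sample simulation puts the shortfall at
$\kappa \cdot e^2$ edits per base with
$\kappa(s) = 0.06 + 4.987\,s - 9.387\,s^2$, $s = p_{ins} p_{del}$ (anchored
at measured values for pure-substitution, default, and pure-indel mixes).
`calibratedEventRate()` inverts $e - \kappa e^2 = 1 - a$ so that the realized
identity equals the target $a$; without this correction a target of 0.80
would produce reads at ~0.813 identity. The quadratic model is fit for the
long-read regime (accuracy at or above roughly 0.7); below that the
uncorrected rate is used. The consequence to keep in mind: the *event count*
at accuracy 0.90 over 1 kbp averages ~103.6, not 100 — the simulator promises
identity, not event rate.

## The classifier

A three-layer feed-forward network: two hidden affine layers, each followed
by ReLU and dropout, then an affine output layer with softmax. The loss is
cross-entropy; we use the mean over the batch rather than the raw sum so the
learning rate does not need retuning with batch size. Training is mini-batch
Adam (default learning rate 1e-3) with He-uniform initialisation, fully
seeded (initialisation, shuffling, dropout masks), and **early stopping**:
after each epoch the validation loss is computed in evaluation mode, and when
it has failed to improve for `patience` (default 5) consecutive epochs,
training stops and the weights of the best validation epoch are restored.
Degenerate inputs (single class, non-finite loss) raise immediately with the
epoch reported.

Architecture defaults: hidden widths `c(1024, 512)` as the small preset and
`c(2048, 1024)` as the doubled large preset for databases with hundreds of
classes; dropout 0.3. Exact widths are free parameters — the shape (3 layers,
doubling for the large database) is what matters. The analytic gradients are
verified against central finite differences to below 1e-5 relative error in
the test suite; implementation is plain R matrix algebra, which on a BLAS
handles the dense profile-matrix products efficiently.

For the scaled-down experiments in this package's tests and acceptance
script we use a `c(128, 64)` preset with learning rate 3e-3, batch 128 and at
most 40–60 epochs: with 18 small genomes and 6 genus classes (12,000 training
rows), the full-size preset adds nothing but runtime, and the higher learning
rate compensates for the small magnitude (~1/L) of normalised frequency
features. Problem sizes used there: 6 genera x 3 species, 200 kbp genomes,
2% within-genus divergence, 5x training coverage, 20 noisy 5 kbp reads per
species at accuracy 0.95.

## Classifying long reads

Reads are segmented into consecutive non-overlapping chunks of
`chunkLength` (default 1000, matching the training length). The final
remainder is kept only if it is at least `minLastChunk` (default 500) bases —
shorter fragments have sparse profiles that add vote noise; a read shorter
than `minLastChunk` is reported `too_short`/unclassified. Each chunk is
profiled and passed through the network; each chunk votes for its argmax
class; the class with most votes wins, ties broken by the highest **mean
probability across all chunks** among the tied classes, residual exact ties
by lowest class index (determinism). The confidence score is the winning
class's mean probability over all chunks, and a read is reported
`UNCLASSIFIED` when the score falls below `probThreshold` (default 0.5).

Interpreting the 0.5 cutoff on the mean probability (rather than on the
fraction of agreeing votes) keeps the score on the same scale as the
tie-break quantity; the alternative semantics is available via
`scoreMethod = "vote_fraction"`. The vote rule is verified exhaustively
against a brute-force restatement over all configurations of up to 4 chunks
and 3 classes on a quarter-step probability grid.

## Evaluation protocols

**Read level** (`readLevelMetrics()`): per taxon, sensitivity is the
proportion of its reads predicted as it (unclassified reads count as
misses); precision is the proportion of reads predicted as it that truly are;
F1 is the harmonic mean; taxa never seen in the truth contribute to
precision only, and macro averages are unweighted means over truth taxa.

**Community level** (`buildMockCommunity()`, `communityMetrics()`):
pseudo-mock communities draw a uniformly random number of species (default
20–34) with **log-distributed relative abundances** — abundance of the
i-th ranked species proportional to $10^{-i\Delta}$ with $\Delta$ set so the
most/least abundant ratio is 100 (the "log-distributed" phrase fixes no
formula; a log-spaced ladder is the plainest reading and creates the
rare-taxon regime the detection thresholds probe; the scheme is a parameter).
Reads (default cap 100,000) are allocated multinomially and drawn without
replacement within per-species pools; exhausted pools are taken whole with a
recorded warning. A genus is called present at threshold $p$% when its
cumulative classified reads reach $p$% of all reads — at 100,000 reads the
0.001/0.1/1% thresholds require 1/100/1000 reads — and detected sets are
nested across thresholds by construction. `stratifyByGenusSize()` groups
out-of-database species by the number of in-database congeners (exactly one,
two or three, more than three), the axis along which novel-species
sensitivity varies most.

## Numerical and design notes

* Coordinates are 0-based half-open internally (sampling offsets); exported
  tables state this.
* Softmax is computed with row-max subtraction; `log` is clamped at 1e-12 in
  the loss.
* `sample()`'s scalar-first-argument surprise is avoided everywhere a range
  can be degenerate.
* Checkpoints are a directory of weight arrays plus JSON metadata; loading
  re-derives the expected input dimension from k and refuses mismatched or
  incomplete checkpoints.
* Determinism contracts are tested: same seed, same training log, same
  sampled sets, byte-identical corrupted reads.

## Known limitations

* The error model is i.i.d.; real ONT error is context-dependent
  (homopolymers) and the identity calibration is validated for accuracies
  ≥ 0.8.
* The synthetic taxonomy has no indel divergence and no compositional
  structure across genera (see above for why this is a conservative choice
  for the classification task).
* Community metrics cover detection only; abundance-estimation accuracy
  (L1, Bray–Curtis) is out of scope.
* No GPU path; the intended scale for this implementation is
  tens-to-hundreds of classes, not the multi-thousand-class regime.
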