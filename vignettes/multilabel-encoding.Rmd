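---
title: "Multi-label BILOU encoding and structured labeling of disorder mentions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-label BILOU encoding and structured labeling of disorder mentions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multibilou)
```

## The problem

Disorder mentions in clinical notes are not always neat contiguous spans.
A mention may be discontiguous — *tricuspid … leaflets … thickened* —
with its tokens split into segments separated by breakpoints, and several
mentions may overlap within one sentence, either sharing tokens (*Abdomen
nontender* and *Abdomen nondistended* share *Abdomen*) or nesting inside
another mention's span without sharing any token. A tagging scheme that
assigns one atomic tag per token cannot represent these structures
losslessly, which caps the recall of any sequence labeler built on top of
it.

## The label model

Every token carries a single unsigned binary label of width
4 × capacity (24 bits at the default capacity 6). The four regions hold
the BILU roles — from the right: Unit (bits 1–6), Beginning (7–12), Last
(13–18), Inside (19–24) — and bit *i* within a region is channel *i*. One
(role, channel) pair is a *sub-label* with exactly one set bit; a token's
*final label* is the bitwise OR of all its sub-labels. Class O is the
all-zero label; classes U/B/L/I have all set bits in one region; class C
(set bits in two or more regions) marks tokens playing several roles at
once, e.g. last token of one mention and beginning of another.

Encoding assigns roles per mention (U for unit-length mentions, otherwise
B/I…/L over the mention's tokens — gap tokens inside a discontiguous span
get no role), groups mentions into overlap clusters, and hands out
channels 1, 2, 3, … within each cluster, resetting to 1 for every new
cluster. Decoding extracts sub-labels per set bit, gathers each channel,
and reads it as a BILOU sequence in which class-O gaps are allowed inside
an open B…L span — that is how discontiguous mentions come back out.

Two assumptions delimit the scheme. Mentions never cross sentence
boundaries, so channels are scoped to the sentence. And at most `capacity`
mentions may mutually overlap; larger clusters are an error at encode
time, and the remedy is widening the scheme (`label_scheme(capacity)`
scales the width to 4 × capacity; widths up to 52 bits keep labels exactly
representable as doubles, which caps `capacity` at 13).

### Design choices the label algebra had to make

* **Overlap relation.** Two mentions overlap when their `[min, max]`
  token-span intervals intersect — not only when they share tokens. A
  mention nested inside another's span must sit on its own channel, or the
  channel's BILOU sequence becomes ambiguous at decode time; interval
  intersection is the weakest relation that guarantees unambiguous
  channel-wise decoding, and it matches how span-nested mentions are
  counted as overlapping in corpus statistics.
* **Channel order.** Encoding honors the caller's mention order within a
  cluster. The mention set returned by decoding is invariant under channel
  permutation, so the order is a presentation detail;
  `canonicalize_mentions()` provides a deterministic (first token, last
  token) order when none is intended.
* **Repair rules for malformed predictions.** A statistical model can emit
  label sequences no encoder would produce. Decoding repairs rather than
  rejects: a dangling B emits the tokens it gathered; an L with no open B
  becomes a unit mention; a stray I is dropped; a second B on an open
  channel emits the open mention and starts a new one. These choices
  maximize recall without inventing token boundaries that were never
  predicted.
* **Rendering.** Bit strings print as four comma-separated groups with the
  I region leftmost, and tokens are indexed 0-based internally (1-based
  only in human-readable output).

## Baseline schemes

The BIOHD and BIOHD1234 encoders implement the head/non-head baseline
family: a *head* is a maximal token run shared by two or more mentions,
other segments of complicated mentions are D segments, and the 1234
variant codes each D segment's combination direction (nearest head left,
nearest non-head left, nearest head right, nearest non-head right, checked
in that priority order; a D segment with candidates in several directions
is flagged ambiguous in the report). The published descriptions of these
schemes are brief, so this implementation is a fixed, documented
approximation of the quoted definitions; to keep the audit honest,
`biohd_encode()` round-trips its own tags through `biohd_decode()` and
reports a sentence as unrepresentable whenever the decode does not
reproduce the annotation — which covers both the structural two-head case
and subtler failures. The multi-label scheme is a strict superset: every
sentence the baseline encodes round-trips in both schemes, and the
two-head structures round-trip only as multi-labels.

## Features

Per token the extractor emits binary indicator features over centered
windows: bag of words (window 5), POS (window 7), capitalization normal
form (window 5, all letters uppercased), case pattern (window 3, letters
and digits mapped to `A`/`a`/`0`), and word-cluster id (window 3).
Windows are centered because only the sizes are fixed by convention;
positions beyond the sentence edge emit boundary sentinels, so the key
count per token is constant (23 at the defaults). Bag-of-words features
are word identities, not frequencies — a window position contributes one
key. Cluster lookup lowercases first, since distributional clusters
induced from raw clinical text are case-noisy, and out-of-vocabulary words
map to a sentinel id. POS comes from a small deterministic rule tagger by
default (closed-class lexicon, digit/punctuation rules, suffix rules);
corpora may carry their own POS column and any tagger function can be
substituted. Contextual information is realized by the windows themselves;
no extra conjunction features are generated.

## The sequence labeler

The labeler is a linear chain model over the *observed* decimal labels:
the alphabet is the sorted set of distinct labels in the training corpus
plus class O, never the full 2^24 space — with 24-bit labels only a few
dozen distinct values ever occur, and restricting prediction to them is
what any practical sequence package does with such an encoding. Scores are
emission weights on the sparse features plus label-bigram transition
weights, decoded exactly by Viterbi (ties toward the lower label index).

Training is an averaged online large-margin learner: each sentence is
decoded with a Hamming cost added to every non-gold label (cost-augmented
decoding), a perceptron-style update is applied on mistakes, and the
returned weights are the average over all iterates. Once a full pass makes
no update, no later pass can (the cost-augmented decode is deterministic
in the unchanged weights), so training stops early and the untouched
passes are credited to the average exactly. The defaults — 30 epochs,
shuffling, unit cost — are chosen so that a separable corpus trains to
convergence well within the epoch budget; everything is reproducible from
the seed, and models persist as versioned JSON (alphabet, feature names,
dense weight matrices, configuration).

## Evaluation

Mention-level precision, recall and F1 are computed from corpus-wide
TP/FP/FN with each quantity defined as 0 when its denominator is 0 (the
defining ratios never face that case on real scoring runs, but the
convention is made explicit). Matching is greedy and one-to-one per
sentence: each prediction, in order, consumes the leftmost still-unmatched
gold it matches; without the one-to-one constraint a single prediction
could match two golds in the relaxed modes. Strict mode requires token-set
equality; left/right modes require only the matching boundary, with no
additional category-agreement requirement. A strict match implies both
relaxed matches, so strict F1 never exceeds left or right F1. Mention
categories follow the precedence overlapping > discontiguous > contiguous,
with overlap judged by the same interval relation as the encoder — one
definition, used everywhere.

## The synthetic corpus generator

The licensed clinical corpora this method targets cannot ship with the
package, so the generator emulates their *structural* make-up: the default
category mix (88.45 / 5.06 / 6.49 per cent contiguous / discontiguous /
overlapping), the breakpoint split for discontiguous mentions
(94.31 / 5.69 per cent for 1 / 2 breakpoints), the overlap-multiplicity
distribution over 2–6 mutually overlapping mentions
(66.57 / 27.35 / 3.87 / 1.38 / 0.83 per cent) and the span-length
distribution (46.36 / 28.31 / 14.16 / 4.25 / 3.05 per cent for spans 1–5,
3.87 per cent for 6 or more, realized as 6–9). Because one overlap
cluster of k mentions contributes k overlapping mentions, the per-group
probability of drawing an overlap cluster is the configured per-mention
proportion divided by the expected cluster size (≈2.43); the per-mention
mix then matches its targets in expectation, and at 10,000 generated
mentions the empirical proportions land within sampling error of them.

Overlap clusters are built from three geometric patterns: a *star* (one
head token shared by all cluster members, tails to its right), a *chain*
(two mentions sharing a middle token, which produces a class-C label) and
a *nested unit* (a unit mention covered by another mention's span without
token sharing). Discontiguous mentions have single-token segments with
background tokens filling the gaps; the span-length distribution is
enforced for contiguous and discontiguous mentions, while cluster
patterns fix their own spans by construction.

The disorder sub-vocabulary is disjoint from the background vocabulary
and further partitioned into structural-role pools (contiguous-mention
words, unit words, discontiguous first/middle/last words, cluster heads
and tails per channel). Lexical identity therefore cues the role and
channel a token plays, making the corpus linearly separable — by design,
so that learning checks have a known target: the labeler must reach
perfect held-in F1, and held-out F1 stays high because held-out sentences
reuse the same finite vocabulary in new combinations. This is also the
honest statement of what passing tests show: the encoding, inference and
learning machinery are correct and the pipeline is lossless end to end.
They do not show clinical-grade accuracy — real corpora have ambiguous
lexical cues, unseen words, inconsistent annotations and far weaker
separability, and labels for the same surface mention can differ with
context (a mention encoded alone uses channel 1 where the same mention
inside a cluster uses a higher channel), which is a known sparsity
limitation of the scheme itself.

The companion `generate_cluster_lexicon()` stands in for distributional
word clusters: a deterministic assignment of the vocabulary to K = 700
clusters (the cluster count the word-representation feature is designed
around) in which disorder words are concentrated in a few clusters of
their own at the default purity of 1, so the cluster feature carries
signal for words unseen in training.

## Problem sizes and numerical checks

The test suite pins the worked examples bit-for-bit, verifies
`integrate ∘ extract` as the identity on 10^5 random labels, checks the
classifier against an independent per-bit region scan over the entire
2^24 label space, round-trips encode/decode over 10^4 generated sentences
covering multiplicities 2–6 and breakpoints 1–2, compares Viterbi with
exhaustive path enumeration on all instances up to 6 positions × 6 labels,
and trains on a 2,000-sentence corpus (held-in strict F1 must equal 1.0,
held-out at least 0.9). These sizes keep the default run deterministic
and desk-scale while exercising every code path; all stochastic checks fix
their seeds.

## Known limitations

Mentions crossing sentence boundaries are out of scope. The scheme's
label sparsity grows with overlap multiplicity (tokens belonging to many
mentions are rare, so their many-bit labels are hard to learn). The BIOHD
implementation is an approximation of a sketched scheme, suitable for
representability auditing rather than as a faithful reimplementation of
the original systems. The rule POS tagger is deliberately small; plug in
a real tagger or supply gold POS columns for serious use. And the
generator's separability is a feature for testing, not a claim about
clinical text.
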