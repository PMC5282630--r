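# multibilou

Recognition of disorder mentions in clinical narratives, including the
complicated ones: mentions whose tokens are **discontiguous** (several runs
separated by breakpoints, as in *tricuspid ... leaflets ... thickened*) and
mentions that **overlap** each other, either by sharing tokens (*Abdomen
nontender* / *Abdomen nondistended*) or by nesting inside another mention's
span. Single-tag-per-token schemes such as BIO or BILOU cannot carry this
structure; this package implements a multi-label extension that can, plus
everything needed to use it: feature extraction, a structured sequence
labeler, evaluation, corpus statistics, a synthetic corpus generator, file
IO and a command-line tool. It is aimed at clinical/biomedical NLP
practitioners who need lossless span encodings for nested and disjoint
concept extraction.

## The multi-label scheme

Every token receives one 24-bit label split into four 6-bit **regions**,
one per BILU role, printed I,L,B,U left to right:

```
d6 d5 d4 d3 d2 d1 , c6 c5 c4 c3 c2 c1 , b6 b5 b4 b3 b2 b1 , a6 a5 a4 a3 a2 a1
    I (inside)          L (last)           B (beginning)        U (unit)
```

The six bit positions within a region are **channels**: the i-th mention of
a cluster of mutually overlapping mentions uses channel *i* (the channel
counter resets to 1 whenever a mention overlaps none of the earlier ones).
Each (role, channel) pair is a single-bit **sub-label**; a token's **final
label** is the bitwise OR of its sub-labels. The all-zero label is class O;
set bits confined to one region give class U/B/L/I; set bits in two or more
regions give class C — a token playing several roles at once. Up to six
mutually overlapping mentions per sentence are encoded losslessly, and the
capacity is a parameter (`label_scheme(capacity = …)` scales the width to
4 × capacity). Final labels convert to decimal class ids for training a
linear structured sequence labeler with exact Viterbi inference; predicted
decimals convert back to bit patterns and decode channel-by-channel into
mention sets.

Mention-level scoring follows
`Precision = TP/(TP+FP)`, `Recall = TP/(TP+FN)`,
`F1 = 2·P·R/(P+R)`, in strict mode (exact token-set match) and relaxed
left/right modes (matching left or right boundary only). BIOHD and
BIOHD1234 baseline encoders are included with a representability audit:
sentences with two head segments (runs of tokens shared by several
mentions) have no baseline encoding but round-trip exactly as multi-labels.

## Worked example

```r
library(multibilou)
toks <- tokenize_clinical("Abdomen is soft, nontender, nondistended, negative bruits.")$token
mentions <- list(c(0, 9),  # Abdomen bruits
                 c(0, 4),  # Abdomen nontender
                 6)        # nondistended
labels <- encode_sentence(toks, mentions)
data.frame(token = toks, label = format_label(labels),
           decimal = labels, class = classify_label(labels))
#>           token                       label decimal class
#> 1       Abdomen 000000,000000,000011,000000     192     B
#> 2            is 000000,000000,000000,000000       0     O
#> 3          soft 000000,000000,000000,000000       0     O
#> 4             , 000000,000000,000000,000000       0     O
#> 5     nontender 000000,000010,000000,000000    8192     L
#> 6             , 000000,000000,000000,000000       0     O
#> 7  nondistended 000000,000000,000000,000100       4     U
#> 8             , 000000,000000,000000,000000       0     O
#> 9      negative 000000,000000,000000,000000       0     O
#> 10       bruits 000000,000001,000000,000000    4096     L
#> 11            . 000000,000000,000000,000000       0     O
```

*Abdomen* begins two overlapping mentions, so bits b1 and b2 are both set
(decimal 192); *nontender* ends the channel-2 mention (bit c2), *bruits*
ends the channel-1 mention (bit c1), and the unit mention *nondistended*
sets bit a3 on channel 3. Decoding recovers exactly the three mentions:

```r
decode_labels(labels)
#> [[1]] <mention> tokens {0,4} (1-based: 1,5), span 5, 1 breakpoint(s)
#> [[2]] <mention> tokens {0,9} (1-based: 1,10), span 10, 1 breakpoint(s)
#> [[3]] <mention> tokens {6} (1-based: 7), span 1, 0 breakpoint(s)

evaluate_mentions(list(decode_labels(labels)), list(mentions), "strict")
#> <eval_report> mode strict: TP 3 FP 0 FN 0
#>   precision 1.0000  recall 1.0000  F1 1.0000
```

A full pipeline — generate a synthetic annotated corpus, train the
labeler, predict and score — is available programmatically
(`generate_corpus()`, `train_tagger()`, `predict_tagger()`,
`evaluate_mentions()`) and from the shell via the installed
`exec/multibilou` script (`simulate`, `encode`, `decode`, `train`,
`predict`, `evaluate`, `stats`, `audit-baseline`).

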