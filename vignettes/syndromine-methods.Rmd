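---
title: "Methods: two-track mining of syndrome-associated genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-track mining of syndrome-associated genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syndromine)
```

## The scientific question

Traditional Chinese medicine groups patients by *syndrome* (zheng), a
diagnostic pattern over symptoms, and treats different diseases that share
a syndrome with the same method. If this has a molecular footing, two
diseases sharing a syndrome — here the Qi-deficiency-and-blood-stasis
syndromes of coronary heart disease and of stroke — should share
syndrome-associated genes. `syndromine` operationalises the question as
literature mining: given an abstract corpus per syndrome, a curated gene
dictionary (emulating the 1,435-gene neuro-endocrine-immune set), and a
protein-relation knowledge base (emulating a STRING export), two
independent tracks each nominate a gene set per syndrome, the tracks are
matched by intersection, and matched sets are intersected across
diseases.

## The decomposition track

**Recognition.** Abstracts are split into sentences (terminal punctuation
with an abbreviation blocklist) and tokenized by a rule-based English
tokenizer (whitespace/punctuation split, internal hyphens kept, so
"IL-10" is one token). The original workflow tokenized with a Chinese
segmenter; the method is segmenter-agnostic dictionary matching, so an
English tokenizer substitutes. Token n-grams are matched longest-first
against dictionary surfaces (symbols and synonyms). Matching is
case-insensitive by default, except that all-caps surfaces of up to
`exact_short_max = 3` characters must match verbatim: short symbols such
as "INS", "MET", "AR" or "C3" collide with common English words, and the
exact-case exception keeps precision high. The threshold is a plain
argument, so the behaviour is fully configurable. Titles are excluded by
default (`include_title = TRUE` adds them); only title, abstract and
keywords are modelled per record.

**Relation extraction.** Every unordered gene pair co-mentioned in at
least one abstract forms one globally deduplicated *bag* whose instances
are all of its sentence-level co-mentions across the corpus; a pair whose
genes never share a sentence anywhere falls back to document-level
instances (each gene's first mention sentence, concatenated). Bags are
flagged 1 exactly when the pair is in the knowledge base — distant
supervision in place of manual labels. The sparse multi-instance
classifier is deliberately simple and deterministic: per-instance
features (windowed bag-of-words around and between the two mentions, a
token-distance bucket, presence of a relation-cue verb), an L1-penalised
linear instance scorer, log-sum-exp pooling to a bag logit, logistic loss
on bag flags, trained by proximal gradient descent (ISTA) from a zero
initialisation. No randomness is consumed, so identical inputs give
identical weights; the `seed` argument exists so stochastic classifiers
can be plugged in behind the same surface. The feature map is fit on
training bags only; unseen tokens at prediction time hash to one reserved
out-of-vocabulary feature. The decision threshold defaults to 0.5.

Network edges are taken from model predictions by default
(`edges_from = "model"`); `edges_from = "flags"` instead uses the raw
knowledge-base flags. Both readings are defensible — the published
pipeline is ambiguous on this point — and the switch makes the choice
explicit rather than silent.

**Scoring.** On the resulting undirected network, four per-gene indexes
are computed and each max-scaled so top genes score exactly 1: degree CD;
betweenness CB (raw geodesic counting, then divided by its maximum, which
absorbs any normalisation constant and stays defined on two-node graphs);
closeness CC (Freeman-normalised within each connected component, then
divided by the network maximum); and eigenvector centrality CE per
component, scaled to component maximum 1. The composite indicator is

$$\mathrm{CMI} = C_D \cdot C_B \cdot \frac{1}{C_C} + C_E.$$

Numerical guards: when $C_B = 0$ the product term is taken as 0 whatever
$C_C$; since closeness is computed within components, $C_C = 0$ can only
occur for an isolated node, where $C_B = 0$ holds too, and $C_C = 0$ with
$C_B > 0$ raises an error rather than dividing by zero. A single-node
network gets the documented degenerate contract CD = CB = CC = 0, CE = 1.

The network is decomposed by Louvain modularity maximisation — the
community algorithm is not pinned down by the method description, and
Louvain is the field default — on a vertex ordering fixed by sorting node
symbols, under a set seed, so partitions are reproducible. Each
sub-network of size $N$ with expert relevance score ZJW (a free
nonnegative input, default 0; its scale and elicitation are left to the
analyst) gets $SW = N + \mathrm{ZJW}$, min-max normalised across the
sub-networks of one network to ZSW. When all SW coincide (including a
single sub-network) every ZSW is set to 1, consistent with published
rankings in which all top rows carry ZSW = 1. The final score is
$GW = \mathrm{CMI} + \mathrm{ZSW}$, an exact identity on every emitted
row. Centralities are computed on the whole network, not per sub-network,
because the published rankings order genes across the full gene set.

## The combination track

Symptom classifications have three groups — main, Qi deficiency, blood
stasis — plus *fixed terms* that enter every combination; groups hold
*options*, each one or more terms that travel together (the published
stroke combinations pair, e.g., respiratory abnormality with lassitude,
and the pairing rule is not stated, so the printed options are encoded in
the classification rather than derived). Combinations are the Cartesian
product of one option per group, ordered main, Qi, fixed, blood — the
published layout. Symptoms whose hit rows contain no gene at the
`min_hits` threshold are pruned into `removed_terms` before enumeration;
emptying a whole group is an error.

A combination's gene set is the **union** of its symptoms' gene sets, and
the core genes are the **intersection** of those sets across
combinations. Union-within is the reading of "genes existing in each
combination" that is consistent with the published per-syndrome set sizes
(hundreds of genes); intersection-within is available via
`within = "intersection"`.

## Integration

Matching decomposition and combination per syndrome is exact set
intersection, as is the cross-disease shared set. Over-representation
analysis uses the exact hypergeometric upper tail
(`phyper(k - 1, K, N - K, n, lower.tail = FALSE)`) with
Benjamini–Hochberg adjustment across sets; raw p-values are also emitted
since the original analysis reported unadjusted values. Empty matched or
shared sets are reported, not errors — a valid outcome on arbitrary
corpora.

`run_pipeline()` records seeds and a configuration hash sufficient to
re-run bit-identically. Stage timings are carried only as a non-serialised
attribute and excluded from the written JSON report, so reports from
identical configurations are byte-identical — determinism is treated as
part of the scientific contract.

## The synthetic study conditions

The generator emulates exactly the statistical structure the pipeline
assumes, with defaults chosen once as the standard study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 20 | dictionary size |
| `n_abstracts` | 400 | corpus size per syndrome |
| `kb_density` | 0.2 | fraction of gene pairs in the knowledge base |
| `comention_rate_kb` | 0.3 | per-abstract co-mention probability, KB pairs |
| `comention_rate_bg` | 0.02 | the same for background pairs |
| `cue_rate` | 0.9 | cue-verb probability on true-relation sentences |
| `n_symptoms` | 12 | symptom vocabulary size |
| `hits_lambda` | 2 | Poisson mean of symptom-gene hit counts |

Abstracts are templated subject–verb–object sentences with gene slots
plus gene-free filler: the recognition and relation stages consume token
streams, not prose, so fluency buys nothing. The 15:1 ratio of planted
to background co-mention rates keeps the planted signal recoverable;
cue verbs appear only on knowledge-base co-mention sentences. A fixed
20% of symptoms are forced to all-zero hit rows, reproducing the pruning
path for unmapped symptoms. Each generator draws from its own stream
derived from the master seed by stable sub-seeding, so adding a generator
never perturbs another, and identical configurations serialize
byte-identically. The two-syndrome bundle additionally *guarantees* a
planted shared signal: chosen genes are chained into knowledge-base
pairs, each chained pair receives three extra cue-bearing abstracts per
corpus, and planted genes get at least one hit for every mapped symptom —
so the end-to-end recovery test exercises the pipeline, not generator
luck.

What passing tests on these corpora do **not** show: robustness to real
abstract language (anaphora, symbol ambiguity across organisms and gene
families, hedged relation language), to dictionary incompleteness, or to
literature-scale corpus sizes. The original study's corpus-dependent
counts (tens of thousands of documents, per-syndrome gene counts, KEGG
p-values) depend on database snapshots and are out of scope; the
published top-gene tables, symptom classifications, per-symptom gene
counts and the 46-gene shared list are shipped as reference worked
examples instead (`chd_reference_ranking()` and friends). Two caveats on
those tables are worth recording: several stroke rows do not satisfy the
CMI formula when recomputed from their printed (rounded) centrality
columns — plausibly unrounded internal values — so formula checks use
only the self-consistent rows; and one printed hub value (1.01) exceeds
1 under any max-scaling, so the hub column is taken as given rather than
re-derived.

## Problem sizes and numerics in the test-bed

The suite verifies bag generation against brute-force pair enumeration on
100 random corpora (4–7 genes, 8–20 abstracts each), centralities against
exhaustive shortest-path enumeration and dense eigendecomposition on a
seeded sample of 200 graphs of at most 8 nodes, planted-relation recovery
as mean held-out AUC over 10 seeds of the standard conditions, and
enrichment p-values against direct tail summation to 1e-12 on universes
of at most 50 genes. These sizes were chosen as the smallest at which the
oracles remain exhaustive while the statistics (binomial 99% acceptance
intervals computed by direct summation, 3-standard-error mean checks)
have useful power. Floating-point comparisons use 1e-9 for identities
computed in double precision and 1e-6 where an iterative eigensolver is
compared against a dense one.

## Known limitations

* Dictionary NER cannot disambiguate a symbol used for a different entity
  (no organism or family context), and precision guarantees hold only on
  the synthetic filler vocabulary, which is constructed to avoid
  dictionary surfaces.
* The multi-instance classifier is linear with hand-designed features; it
  honors "sparse multi-instance learning" without claiming to reproduce
  any specific published learner, whose hyperparameters and features are
  unspecified.
* Expert sub-network scores (ZJW) are free inputs; nothing constrains
  their scale, and rankings respond linearly to them through ZSW.
* Symptom matching is contiguous token matching; paraphrases and
  umbrella terms ("perspiration" vs "sweating") must be resolved upstream
  by the term map.
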