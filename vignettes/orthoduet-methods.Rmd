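---
title: "OrthoDuet methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OrthoDuet methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

OrthoDuet infers multi-species ortholog groups by combining two
species-pair pipelines — a graph pipeline built on bidirectional best
hits (BBH) with essential-subset alignment reduction, and a domain
pipeline built on paragraph-vector embeddings of domain architectures —
followed by a rule-based merge and Markov clustering. This vignette is
the package's account of the underlying models, the parameters that
matter, the numerical choices, and what the synthetic fixtures do and
do not demonstrate.

## 1. The graph pipeline

### BBH and essential subsets

For proteomes A and B, a pair (a, b) is a seed ortholog when b is the
top-scoring hit of query a in the alignment A-B and a is the
top-scoring hit of query b in B-A. The reduction rests on one
observation: a protein with no hit at or above the bitscore threshold
*t* in the first alignment direction cannot appear in any BBH. After
the full A-B alignment, the package keeps

* `ess(A)`: queries of A with at least one hit scoring ≥ *t*, and
* `ess(B)`: targets of B appearing in at least one such hit,

and aligns only `ess(B)` against `ess(A)` for the reverse direction.
Orthology is then declared when b is best for a in full A-B and a is
best for b in `ess(B)`-`ess(A)`.

With a *symmetric* scorer (score(a, b) = score(b, a), which holds for
the built-in toy engine and approximately for real local aligners) the
full-alignment BBH set is always contained in the essential-alignment
set, and the two coincide whenever every per-query best hit of the full
tables reaches *t*. Both properties are checked exhaustively in the
test suite on 200 random synthetic pairs of up to 50 proteins per side,
and `compareBBHDefinitions()` exposes the comparison to users. The
extra pairs the essential set can contain arise when a query's global
best target falls below *t*: restricted to the essential subset, its
best hit may become reciprocal. We keep these pairs — they are
supported by above-threshold reciprocal evidence by construction.

**Threshold `bitscoreThreshold` (t, bits; default 40).** The classical
InParanoid-lineage cutoff. Raising *t* shrinks the essential subsets
and both BBH sets monotonically (tested property); it never adds
pairs.

**Best-hit ties.** All targets tying a query's maximal bitscore are
flagged best. A tie can therefore yield several reciprocal seed pairs;
downstream Markov clustering resolves them. This keeps reduction
deterministic without an arbitrary drop rule.

### Choosing the first alignment direction

The two directed alignments of a pair can take very different times,
and the reduction only pays off if the *full* alignment run first is
the faster one. Two mechanisms are provided:

* **Heuristic (default).** The proteome with more residues is the
  query of the full alignment. Exact ties (same residue and protein
  counts) fall back to lexicographic proteome-id order, reported as
  `tie_break` so callers can see that the choice carried no signal.
* **Trained model.** `trainDirectionModel()` fits boosted decision
  stumps (gradient-boosted trees of depth 1, via xgboost) on eight
  features per pair: query/target protein counts, residue counts, mean
  lengths, plus the size and count folds (larger over smaller, always
  ≥ 1). Samples are canonically oriented — the proteome with fewer
  residues leftmost — so features are invariant under argument swap. A
  sample is labeled 1 when the canonical direction was the strictly
  faster one; ties are labeled 0, a fixed convention that keeps
  training deterministic.

Hyper-parameters are grid-searched over ensemble sizes
{50, 100, 200, 400} and learning rates {0.1, 0.5, 1.0} with 10-fold
cross-validation; training is single-threaded with a fixed seed, so two
trainings from the same samples and seed give identical predictions (a
tested contract). The package ships no pre-trained weights: the
heuristic is the default, and the timing simulator in the fixtures
module plus `writeDirectionSamples()`/`saveDirectionModel()` form a
complete training harness for users with real timing data. Boosted
stumps fit this problem well: the generative boundary
"query_count × target_residues smaller" is additive after a log
transform, which an additive ensemble of stumps can approximate
directly.

### Inparalog clustering

Each seed pair (a, b) is extended with within-species duplicates: x of
species A joins when its intra-proteome score against the seed reaches
the seed score (the mean of the two directed seed bitscores), with
confidence

    conf(x) = (score(x, a) − seedScore) / (selfScore(a) − seedScore)

clipped to [0, 1]; seeds carry confidence 1. When the denominator is
degenerate (missing or non-positive) the confidence is set to 1 rather
than dropped — a protein scoring above the seed's own self-score is at
least as close as the seed. A protein qualifying for several clusters
goes to the one giving it the highest confidence (ties:
lexicographically smallest seed), and seed proteins never join other
clusters as inparalogs, so each protein appears in at most one cluster
per species pair (tested invariant).

## 2. The domain pipeline

### Architectures and documents

Profile-search hits are kept when bitscore ≥ 30 **and** profile
coverage ≥ 75%, both inclusive. Overlapping hits on one protein are
resolved greedily by descending bitscore (deterministic; on two-hit
cases equal to exhaustive non-overlap maximization, which is tested).
Remaining domains, ordered by start coordinate, become words; uncovered
runs strictly longer than four residues — termini included — become
words carrying their length in amino acids. Coordinates are 1-based
inclusive, the profile-search convention.

Gap lengths are rendered raw (one word per distinct length), the
literal reading of length-words; `architectureDocument(gapBinWidth =)`
optionally bins them because raw lengths fragment the vocabulary on
large corpora. The default (1 = off) was chosen once and is not
revisited by any test.

A document enters the training corpus when its architecture covers at
least 70% of the protein (inclusive); duplicates collapse to a single
training entity, and every protein mapping to a corpus document shares
that document's embedding. Proteins below the cutoff have no embedding
and take no part in domain orthology (tested invariant).

### DBOW embeddings

Embeddings are trained fresh at every run ("on the fly") on the
deduplicated corpus with the distributed bag-of-words paragraph-vector
objective: each document vector is optimized by SGD to predict the
words the document contains. Parameters: dimension 100, 200 epochs,
context window 2 (recorded for provenance; pure DBOW predicts all words
of the document), minimum word frequency 1 — domain vocabularies are
tiny compared to natural language, so every word is worth training —
and a single worker with a fixed seed, making training deterministic.

One deliberate departure from common word2vec practice: the output
layer uses the **exact softmax** over the vocabulary instead of
negative sampling. Negative sampling approximates the softmax gradient
to make web-scale vocabularies tractable; architecture vocabularies
(hundreds to a few thousand words) make the exact gradient affordable,
and removing sampling noise makes the cosine landscape stable across
seeds. On the planted-fusion corpus the fused document "D1 g D2" sits
at cosine ≈ 0.93–0.96 to each single-domain document "D1"/"D2" while
unrelated documents fall near or below zero, comfortably separated by
the 0.5 threshold. The learning rate decays linearly from 0.025 to
1e-4 over all updates; document vectors initialise uniformly in
(−0.5, 0.5)/dim and word output vectors at zero.

### Prefilter, similarity and cluster extraction

Before any cosine is computed, a pair of architectures is rejected when
any of four symmetric rules fires: one protein more than 3× the length
of the other (strict); coverages differing by more than 0.25 in
absolute fraction; one architecture with more than double the domains
of the other (strict); no shared domain accession. Symmetry of all four
rules is property-tested on 1,000 random architecture pairs.

Surviving pairs with cosine ≥ 0.5 (inclusive) populate a sparse
species-pair matrix. For every non-empty row and every non-empty
column the maximal entry is selected (ties: lexicographically smallest
partner id), and the union of selected pairs is grouped into clusters
as connected components of the selected-pair graph — the simplest
deterministic grouping consistent with row/column maxima selection;
the exact grouping topology was an open design point and this choice
is ours.

## 3. Merge, ortholog graph and Markov clustering

Graph-based predictions are treated as the more reliable: they are
never modified or removed. Each domain cluster d is merged by three
cases: (1) no overlap with any graph cluster — accept d whole only if
every member covers ≥ 75% of its protein and every attested pair has
equal domain counts, else reject it entirely; (2) full overlap — keep
the graph clusters untouched; (3) partial overlap — insert each novel
protein with coverage ≥ 75% into the graph cluster containing its
highest-cosine partner (ties: lexicographic), dropping the rest. Case
3's "highest-cosine partner" rule is our determinization of the
underspecified multi-cluster scenario: it is local and needs no global
optimization.

The ortholog graph connects every within-cluster protein pair. Edge
weights: product of the two members' confidences for graph-provenance
members (seed-seed edges get 1); the attesting cosine for
domain-inserted members and domain-attested pairs; for within-cluster
pairs of a pure domain cluster that were not directly scored, the
cluster's minimum attested cosine (a conservative floor); the maximum
when several tables attest one edge. Whether to feed confidences or
uniform weights to clustering was open; we default to
confidence/cosine weights because they carry the only quantitative
evidence available, and the weight scheme is recorded in the manifest.

Markov clustering is implemented natively on sparse matrices: add
self-loops (weight 1), column-normalize, then alternate expansion
(matrix squaring) and inflation (entry-wise power, default 1.5,
followed by column renormalization), pruning entries below 1e-5, until
the largest entry change is below 1e-6 or 100 iterations. Clusters are
the connected components of the limit matrix's support; every node is
assigned exactly once, and group ids are ordered by each group's
lexicographically smallest member, making output order deterministic.
The numerical knobs (pruning 1e-5, tolerance 1e-6, cap 100) are fixed
because determinism requires *some* fixed choice; they match widely
used MCL implementations. Partitions are cross-checked against an
independent dense-matrix implementation on 50 random graphs per run of
the acceptance script, and are invariant under node relabeling and
edge-list permutation (tested).

Degenerate inputs: an empty graph yields an empty group set; an
isolated node becomes its own group; inflation ≤ 1 is an error.

## 4. What the synthetic fixtures emulate — and what they do not

`generateProteomes()` draws ancestral families (lengths uniform in
[0.6, 1.4] × meanLen), mutates them independently into each species by
uniform random substitution at the stated per-species fraction of
sites, duplicates genes within species at the stated rate (planting
inparalogs), and realizes fusion events by replacing a species' copies
of two families with their concatenation joined by a 10-aa linker.
`synthDomainHits()` assigns each family one synthetic Pfam-style
accession covering all but two residues per terminus, and fused
proteins both component domains separated by the linker-induced gap, so
architecture coverages exceed 75% by construction. All generators are
pure functions of (spec, seed); byte-identical regeneration is tested.

The uniform substitution model has no indels, no rate heterogeneity, no
codon structure and no compositional bias; it exists to modulate
shared-k-mer scores monotonically with divergence, which is exactly
what the essential-subset mechanism responds to. Passing tests on these
fixtures therefore demonstrates the *logic* of the reduction, the
merge, and the fusion recovery — not alignment quality on real
sequences, nor calibration of the 0.5 cosine threshold on real Pfam
architectures, nor classifier transfer to real aligner timings (the
shipped default remains the size heuristic for that reason). The toy
scorer (distinct shared 3-mers × 2 pseudo-bits, symmetric by
construction) likewise enables exact oracle tests; it is not a
production aligner, and real runs should use the blast/mmseqs/diamond
adapters.

Timing simulations draw per-proteome stats (protein counts 500–5,000,
mean lengths 250–450 aa) and times as
`rule(query, target) × (1 + e)`, e uniform in ±0.2 — a noise level in
the range of repeated wall-clock measurements on shared machines. The
default rule (time ∝ query protein count × target residues) has one
quirk worth knowing: because residues = count × mean length, its Bayes
boundary reduces to comparing mean protein lengths, so the achievable
accuracy is far from 100% at this noise level; the acceptance script
reports the model's held-out accuracy next to the rule's Bayes accuracy
and the majority baseline. Problem sizes throughout (200 pairs of ≤ 50
proteins, 3,000 timing samples, 50 MCL graphs, three-species
end-to-end runs) were chosen as the smallest sets on which the checked
properties are non-trivial and stable across seeds.

## 5. Orchestration choices

`runPipeline()` is single-threaded and derives every stage seed from
the one user seed; identical configuration and seed reproduce all
outputs byte for byte (tested, and asserted again by the acceptance
script). We decided against cross-run caching of per-pair intermediate
results: at the scales this package targets the recomputation is
cheap, and a content-addressed cache would complicate the determinism
contract for little gain. The JSON manifest records package version,
seed, thresholds, inflation, engine, mode and per-pair direction
sources, and fully determines a run with the built-in engine.

## 6. Known limitations

* Document embeddings are order-sensitive: domain shuffling or other
  rearrangements push cosines down and such pairs are rejected;
  order-invariant or attention-based comparisons are out of scope.
* Each protein carries one architecture-level orthology; per-domain
  assignment is not modeled.
* The greedy overlap resolution is not optimal weighted interval
  scheduling; with many mutually overlapping hits it may keep a
  lower-total-score set.
* The essential-subset containment guarantee assumes a symmetric
  scorer; real aligners are only approximately symmetric, and the
  guarantee degrades with score asymmetry.
* No e-value model: the toy engine emits pseudo-bits only, and all
  thresholds are bitscore-based.
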