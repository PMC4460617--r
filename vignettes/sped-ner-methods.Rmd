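---
title: "Hybrid dictionary-based entity recognition with SPED: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid dictionary-based entity recognition with SPED: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spedner)
```

## The problem

Dictionary-based named-entity recognition locates mentions of biomedical
entities — proteins, genes, diseases, chemicals — by matching text spans
against a precompiled term list. It needs no training data and yields
concept identifiers for free, but it has two chronic weaknesses: short
names generate false positives, and spelling variation defeats exact
matching. A protein name like *EGR-1* appears in running text as `Egr-1`,
`Egr 1`, `egr-1`, `egr 1`, `EGR 1` — all the same entity, none an exact
string match for the dictionary form.

spedner implements a hybrid pipeline that attacks both weaknesses:

1. **Candidate generation** — approximate lookup of every token-aligned
   span against a trie over dictionary surfaces, under a weighted edit
   distance whose cost table makes case and separator edits cheap.
2. **Candidate ranking** — the Shortest Path Edit Distance (SPED), a
   normalized piecewise string metric with a common-prefix re-scorer,
   applied to candidates that are not exact (normalized) matches.
3. **Mention merging** — nested candidate mentions are collapsed using
   contextual cues: same start, same entity category, noun-phrase POS
   pattern, and stemmed-token prefix containment.

## Normalization and the variant family

`normalize_term()` is the keystone convention: lowercase, hyphens and
underscores to spaces, whitespace collapsed, edge punctuation stripped.
It is the *minimal* map that sends the whole printed variant family of a
name like `EGR-1` to one key (`"egr 1"`), and it is idempotent, so keys
can be re-normalized safely. Porter stemming (implemented in-package,
`porter_stem()`) is deliberately **off** for dictionary keys — stemming
gene symbols is meaningless and occasionally destructive — and **on**
inside the merging stage, where `receptors` and `receptor` should compare
equal.

## The weighted edit distance and its cost table

Candidate generation measures closeness by a weighted Levenshtein
distance (`weighted_edit_distance()`). The default `cost_table()` is:

| operation | cost |
|---|---|
| substitution (general) | 1.0 |
| substitution, case-only (`E` vs `e`) | 0.1 |
| substitution within the separator class `-`, space, `_` | 0.1 |
| insertion/deletion (general) | 1.0 |
| insertion/deletion of a separator | 0.2 |

The variant families above differ almost exclusively in case and
separators, so those operations must be cheap; the exact weights are a
design choice of this package (no published values exist for them), set
so that the full `EGR-1` family sits within distance 0.4 of its
dictionary form while a single real letter edit costs 1.0. The default
lookup threshold `max_cost = 0.6` admits the family and rejects real
edits; both are configurable. The lookup itself is a cost-pruned
depth-first traversal of a trie over the dictionary keys (C++): a branch
is abandoned as soon as the minimum of its dynamic-programming row
exceeds the threshold, which is sound because all costs are non-negative.
The test suite asserts exact set equality between this traversal and a
brute-force scan over every entry.

## SPED: the Shortest Path Edit Distance

SPED scores a string pair `(s, t)` in four steps:

1. **Partition** both strings into pieces of length `L`
   (`partition_string()`); the last piece absorbs any remainder, so its
   length lies in `[L, 2L-1]`.
2. **Box scores**: every piece pair `(u, v)` is scored by the mean
   character-mismatch indicator over all `|u| x |v|` character pairs
   (`box_score()`), a value in `[0, 1]`.
3. **Alignment graph**: the piece grid becomes a weighted DAG — diagonal
   edges into cell `(i, j)` carry that cell's box score
   (substitution/match), horizontal and vertical edges carry a gap cost
   (deletion/insertion), and a source vertex joins `(1, 1)` diagonally.
   The minimum-weight source-to-bottom-right path is divided by the
   number of edges traversed (`shortest_path()`), yielding a normalized
   score.
4. **Prefix re-scoring**: if the two strings share a character prefix of
   length `p`, the score is reduced by `min(p, cap) * w * (1 - score)`
   and clamped to `[0, 1]` (`prefix_rescore()`), mirroring the
   Jaro-Winkler prefix credit on a distance scale.

### Numerical and design choices

* **The all-pairs box score is kept as printed.** For multi-character
  pieces the mean over *all* character pairs gives identical pieces a
  non-zero score (`box_score("ab", "ab") = 0.5`). An aligned-positions
  variant that scores identical pieces 0 is provided as
  `weight_fn = "aligned"`, but the all-pairs definition is the default:
  where a formula is stated, we implement the statement rather than a
  conjectured correction.
* **Unequal piece lengths** (the remainder-absorbing last piece): the sum
  runs over all `|u| x |v|` pairs and is divided by `|u| x |v|`, which
  reduces to the square-piece formula when lengths agree and keeps scores
  in `[0, 1]`.
* **Tie-breaking**: among minimum-weight paths the one traversing the
  most edges is reported. This minimizes the normalized score,
  deterministic by construction.
* **Defaults `L = 1`, `gap_cost = 1`**: under these, SPED reduces to an
  edge-normalized grid edit distance; the un-normalized path weight is
  then bounded below by the Levenshtein distance (every path encodes an
  edit script constrained to align the first characters) and above by the
  Hamming distance for equal-length strings (the all-diagonal path). Both
  bounds are property-tested against independent oracles (`adist()`,
  direct mismatch counting). No preferred piece length is published for
  the method; `L` is exposed and `tune_gap_cost()` implements the
  "learning phase" for the gap cost as a grid search maximizing the
  separation between matching and non-matching training pairs.
* **Prefix cap 4** follows the Jaro-Winkler convention; without a cap,
  long shared prefixes would drive the adjusted score below 0 (the
  formula subtracts `p * 0.1 * (1 - score)` unboundedly). Scores are
  clamped to `[0, 1]`.
* **Empty strings**: two empty strings score 0, exactly one empty scores
  1. The source formulation does not treat empty inputs; these are the
  package's declared conventions.
* **Prefix on raw forms**: inside the pipeline, SPED compares
  *normalized* forms, but the common-prefix length is measured on the
  *raw* span and surface, so that case-variant prefixes still earn the
  credit.

One behavioral consequence of edge normalization worth knowing: against a
long dictionary surface, a candidate span padded with context tokens can
score *lower* than the minimal span, because extra aligned characters
dilute the per-edge cost. The span cap (`max_span_tokens`, default 5) and
the merging/overlap stages are what keep this in check; for dictionaries
of long multi-word names a tighter span cap is advisable.

## The pipeline and its arms

`extract_entities()` scans all token-boundary-aligned spans of up to
`max_span_tokens` tokens. For each span with candidates:

* an exact **normalized** match short-circuits selection with score 0 —
  no SPED is computed (this mirrors the perfect-match exit of the
  published algorithm, applied per span);
* otherwise candidates are SPED-scored and those at or below
  `sped_accept_threshold` (default 0.3) survive;
* the best candidate wins by lowest score, then source priority, then
  longest surface, then lexicographic order — fully deterministic.

Four arms reproduce the experimental contrasts: `all` (everything),
`context_only` (exact matching plus merging, no SPED), `sped_only`
(soft matching without merging), and `exact_only` (verbatim raw-surface
lookup — the first-generation baseline). Cross-span conflicts among
same-type overlapping mentions are resolved keeping the lowest score,
then the longest span; the published rules only cover same-start nesting,
so this extension is the package's own and is applied identically in all
arms.

Merging (`merge_mentions()`) absorbs a shorter mention into a longer one
when all four conditions hold: same start; same entity type; every
overlapping token tagged NOUN/ADJ/NUM (numerals and adjectives occur
legitimately inside biomedical noun phrases — a pure-NOUN mode is a
flag); and the shorter mention's stemmed token sequence is a prefix of
the longer's. "Similar lexical properties" has no published definition;
stemmed-prefix containment is the weakest relation under which "merge
shorter into longer" is well-defined. The procedure iterates to a fixed
point and is idempotent, order-independent, and subset-preserving —
all property-tested.

The default POS tagger is deliberately a deterministic rule tagger
(closed-class word lists, digit and suffix rules, NOUN default) so the
package needs no model downloads and behaves identically everywhere; any
tagger honoring the one-tag-per-token contract can be injected.

## Dictionaries

Dictionaries are tibbles of (surface, normalized, entity type, source,
concept id) with a source-priority attribute. Two tabular dialects are
read: a plain TSV of terms and types, and a MeSH-tree-style two-column
table mapping each term to a dot-separated tree number whose leading
letter selects one of the 16 standard top-category labels
(`mesh_categories()`), so *Rheumatic Diseases* under `C17.300` becomes an
entry typed *Diseases*. Native MeSH/UMLS/GENIA distribution formats are
out of scope; the tabular dialects stand in for them. Merging
dictionaries keeps conflicting types from different sources — the caller's
source priority decides at extraction time, matching how multi-source
dictionaries are actually combined when no conflict policy is published.

## What the synthetic generator emulates — and what it does not

`synth_dictionary()` draws gene-symbol-like surfaces (short
consonant-heavy uppercase blocks, hyphen-digit suffixes, occasional
two-word names) across three sources; `synth_corpus()` embeds 1–5 such
terms per passage between filler tokens from a fixed 50-word neutral
vocabulary (filtered against the dictionary so fillers can never collide
with keys), and rewrites each embedded term as one of its case/separator
variants with probability `variant_rate`. Everything is seeded and
byte-reproducible.

This emulates exactly one phenomenon: surface spelling variation of
dictionary terms in otherwise neutral text. It does **not** emulate
ambiguous short names, nested or coordinated entities ("A and B
receptors"), unseen synonyms, abbreviations, tokenization noise, or the
domain shift between curation sources and literature. Passing the
synthetic recovery checks therefore demonstrates that the machinery is
correct (perfect recovery of verbatim terms; strictly higher recall than
a verbatim-lookup baseline under variation; monotone recall in dictionary
size) — it does not predict benchmark scores on real corpora, which in
the source experiments required licensed full-size resources.

Default study conditions used by the acceptance checks: 200 passages,
variant rates 0 and 0.3, a 60-term three-source dictionary, fixed seed;
SPED properties on 10,000 random pairs of length at most 12; lookup
exactness over 20 random dictionaries of up to 1,000 entries with 100
queries at 3 thresholds each. These sizes make every check rerun in
about a minute on one core while keeping each estimate's sampling noise
well below the effects asserted.

## Evaluation

Scoring is strict: a prediction counts only if span boundaries *and*
entity type match a gold mention one-to-one, the convention of the
shared-task corpora this format family comes from
(`count_matches()`, `ner_metrics()`; any 0/0 is defined as 0).
`read_iob2()`/`write_iob2()` round-trip the token-per-line IOB2 dialect
(sentences reconstructed with single spaces — original spacing is not
recoverable from the format and is not needed for strict scoring in
token space), with strict or lenient handling of dangling `I-` tags.
`kfold_split()` provides seeded, balanced passage folds; folds are over
passages because the published description does not state how its
cross-validation interacted with the fixed test partitions.

## Known limitations

* The trie operates bytewise; non-ASCII text is matched byte-by-byte
  (costs default to "general" for multi-byte characters).
* Sentence segmentation is out of scope; passages are the unit of input.
* The rule tagger is a floor, not a ceiling — plug a trained tagger for
  serious context modeling.
* Edge-normalized SPED's preference for longer spans against long
  surfaces (discussed above) is inherent to the published normalization.
* Five alternative box-weight assignments are alluded to in the source
  material but never defined; only the printed one (and the aligned
  variant) are implemented, behind the `weight_fn` contract.
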