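---
title: "Methods: co-occurrence distance trees for drug repositioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence distance trees for drug repositioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litmine)
```

## The model

`litmine` estimates how strongly two biomedical concepts are associated
from how often their names co-occur in the same abstract, and chains
those associations into disease → … → drug paths. The statistical
object is the abstract-level incidence: a term either occurs in an
abstract or it does not, and repeated mentions count once. Whole
abstracts (not sentences) are the co-occurrence window; this trades
precision for recall, which suits a screening tool whose output is
audited by a human anyway (every edge carries its supporting PMIDs).

For a code pair the association coefficient is max-pooled over all term
pairs of the two codes, and the distance is `-ln` of that maximum. The
additivity of these distances along a path rests on an independence
approximation: P(A∩B∩C) ≈ P(A)·P(B|A)·P(C|B). It is a first
approximation in the same spirit as treating multistep reactions as
independent steps; the package *measures* how well it holds (see the
agreement statistic) rather than assuming it silently. The root's own
marginal P(A) is deliberately not part of any distance: distances are
relative to a fixed root, so a constant factor would shift all
candidates equally.

Three coefficients are implemented. Conditional probability uses only
the source frequency as denominator, so frequent, unspecific target
terms get deceptively short edges. The Dice index and Otsuka–Ochiai
(cosine) coefficient feed both frequencies back; cosine is the default
because its distances concatenate most consistently (this is also what
the package's own comparison harness shows on synthetic corpora, below).
For the asymmetric conditional coefficient, edges store both directions
and tree growth consumes the "new code given connected code" direction.

## Stemming with biomedical specificity

Both search terms and abstracts are normalised by a wrapper around the
Snowball English (Porter2) algorithm; the engine is implemented in the
package from the published algorithm (regions R1/R2, steps 0–5,
exceptional forms) because no stemming library is part of this
package's dependency set, and it is cross-checked in the test suite
against a frozen 600-word oracle table. The wrapper adds three rules:

* **Abbreviation protection.** Tokens of ≥2 characters that are all
  upper-case letters or digits (`SARS`, `ACE2`, `RNA`) are returned
  unchanged. Mixed-case tokens (`CoV`) are *not* protected — either
  convention is defensible, so the predicate is an injectable function
  argument. Note that digit-containing
  abbreviations (`ACE2`) are protected under the default predicate;
  this is a deliberate widening of "upper case abbreviations".
* **Case preservation.** The first character is upper-cased (so
  sentence-initial and mid-sentence spellings unify) and no other
  character changes case. The base algorithm runs on a lower-cased
  copy to decide *what* to excise; the excision boundary is then
  re-applied to the original-case token, so `CoVs` keeps its internal
  capitals. Characters the algorithm introduces (the `-e` restored in
  `hoping` → `Hope`) are appended in lower case.
* **Protected suffix regions.** Excision never removes or cuts into
  the rightmost `-ase`/`-ose`/`-ine`/`-sis` region: a plural `-s`
  after `-ase` is removed, the `-ase` itself is kept (`kinases` →
  `Kinase`, `glucose` → `Glucose`, `analysis` → `Analysis`). One
  visible consequence: `protease` stays `Protease`, because deleting
  its final `-e` would cut into the region. The region list is a
  function argument.

Two consequences of the base algorithm are worth knowing. First,
Snowball's step 1a explicitly leaves `-us` and `-ss` untouched, so
`coronavirus` stems to `Coronavirus` — no naive `-s` stripping happens.
Second, raw Snowball is not idempotent on a handful of words (its
exception map produces `earli` from `early`, and a second application
strips the `-li`). Idempotence is a hard requirement here — an indexed
stem must be a fixed point, or dictionary and abstract could disagree —
so `stem_word()` iterates to a fixed point (`early` → `Ear`). The
deviation from single-pass Snowball is confined to those exception
words.

Tokenisation splits on every character that is not a letter or digit.
Hyphens split (`SARS-CoV-2` → three tokens), which maximises matching
across hyphenation variants. Greek letters and all-digit tokens pass
through unchanged.

## From KEGG fields to search terms

Only the NAME and DEFINITION fields of KEGG flat-file records are
read. Fields are split at `;`, `,`, `:` and parentheses; fragments that
are registry labels (JAN, USAN, INN, TN, USP, JP17, NF, …) or
stop-words are dropped. The stop-word list is open-ended in nature, so
it is an argument with defaults covering frequent salt/form words
(hydrochloride, hydrate, sodium, sulfate, …); likewise the
configuration-marker list (`D-`, `L-`, `(R)-`, `alpha-`, `cis-`, …)
stripped from term heads. Every transformation is **additive**: both
`Chloroquine hydrochloride` and `Chloroquine` become terms, so the
abstract search cannot lose recall to normalisation. Terms whose stem
is shorter than 3 characters (and not a protected abbreviation) are
dropped by default — single letters match ubiquitously; the threshold
is an argument.

## Index, edges, tree

The inverted index maps each distinct stemmed term to the sorted set of
PMIDs whose abstract contains it as a contiguous stem phrase; all
frequencies and intersections used by the coefficients come from these
posting sets. Code-level frequencies are *not* precomputed: coefficients
operate on term-level postings and codes are max-pooled, so a rare
synonym never dilutes a common one. Candidate code pairs are discovered
by joining the index (only codes that actually share an abstract are
paired); `min_support` (default 1) filters edges by best-pair
co-occurrence count, and each edge retains its supporting PMIDs because
single-paper links deserve human review.

Tree growth connects codes one by one in nondecreasing order of
*cumulative* distance from the root — shortest-path-tree semantics —
because the method sums distances along tree paths and compares the sums
with direct distances; a nearest-neighbour (edge-local) attachment rule
is kept behind `method = "edge"` for comparison. Ties break
lexicographically by code so runs are reproducible. Pairs with zero
coefficient are simply absent edges; depth is reported but never capped.

For the direct-vs-indirect comparison, a candidate's indirect distance
is the shortest-path distance with the direct root–candidate edge
removed. Only candidates attached directly under the root need a
recomputation: a simple path from the root can contain the direct edge
only as the whole one-hop path.

The agreement statistic over the first *k* ranked candidates having
both distances is the mean and standard deviation of
(D_id − D_d) / sd(D_d), with the sample (n−1) standard deviation; rows
lacking either distance are skipped, not counted. It is scale
invariant, so it compares coefficient methods fairly even though their
absolute distance scales differ.

## The synthetic corpus generator

The generator emulates the two real inputs — a KEGG-style dictionary
and a MEDLINE XML corpus — with planted, exactly known co-occurrence
structure. Each abstract samples **one event**: a planted code pair
(with its stated joint probability), a single code (topping its
marginal up), or background only. Marginals and pairwise joints are
therefore exact by construction, and unlisted pairs never co-occur —
which is what lets a planted disease–protein–drug chain have strictly
zero direct disease–drug co-occurrence. The price is that no abstract
mentions more than two planted codes; since all statistics used by the
method are pairwise, nothing the pipeline estimates is distorted by
this simplification. Mentions are realised as synonym phrases (drawn by
usage weight) inserted among pseudo-word noise tokens, with stem-safe
plural and first-letter case inflections to exercise the stemmer end to
end; noise words are filtered so that their stems never collide with
dictionary terms, and synonym stems may not collide across codes.

What the generator does *not* emulate: real abstracts' grammar, shared
nonspecific vocabulary between concepts (the source of the "improper
connections" that real runs need manual curation for), correlated
mentions of more than two concepts, and temporal dynamics. Passing
tests on synthetic corpora therefore validate the *estimator and
ranking machinery*, not the curation burden of real literature.

`expected_coefficient()` gives the population value of the max-pooled
code-level coefficient implied by a spec (term-level probabilities are
code marginal × synonym weight; synonyms that stem-collide merge their
weights), and `expected_distance_se()` a conservative delta-method
standard deviation of the estimated edge distance from the binomial
variances of the joint and both marginals (the positive covariances it
drops only shrink the truth). These power the statistical tolerance
bands in the tests: an estimate is required to sit within 3 of these
standard errors of its population value.

### Study corpora

Two fixed corpus specifications are exported; their parameters are the
package's reference conditions and are not tuning knobs.

`spec_planted_chain()` (n = 5000 abstracts): disease H00001 → protein
K00001 → drug D00001 with joints 0.035 and 0.025 over marginals
0.12/0.08/0.05, zero direct disease–drug probability, plus a control
drug reachable both directly and through a metabolite. Sizes were
chosen so the planted drug's indirect rank key beats every competitor
by a margin that is large relative to 3 binomial standard errors at
n = 5000 — recovery is then a sharp pass/fail property, not a coin
flip. With two synonyms per code the expected coefficients include the
√(w·w′) max-pooling attenuation.

`spec_heterogeneous()` (n = 5000): nine drugs reach the root through
three proteins of very different literature frequency (marginals 0.04,
0.10, 0.28); joints are chosen to make the world exactly multiplicative
for the code-level cosine coefficient (j_RD = j_RP·j_PD/m_P, i.e.
conditional independence through the protein), and link strengths are
deliberately mixed so that true direct distances span ≈2.8–4.3 — the
agreement statistic normalises by sd(D_d), so a corpus whose direct
distances were all equal would make that normaliser pure noise. Every
code also carries a rarely used synonym (weights 0.04–0.06).

Why this design separates the methods: a short derivation shows that at
*code* level, conditional probability and cosine order all root-to-code
paths identically and give *identical* direct-vs-indirect differences
(intermediate marginals enter both once; endpoint terms cancel in the
difference), so any observed separation must come from **term-level
max-pooling**. That is exactly where the methods differ: the
conditional coefficient's denominator is the source term's frequency
alone, so a rarely used synonym with a handful of occurrences produces
wildly unstable ratio estimates that the max then selects; the cosine
coefficient damps rare terms by the square root of both frequencies.
On this corpus the spread of the normalized difference is consistently
smaller for Otsuka–Ochiai than for conditional probability, with Dice
between — the qualitative ordering the comparison harness asserts.

## Numerical choices

* Coefficient ties during max-pooling break by lexicographic term
  order; node-insertion ties by code order; both make runs
  deterministic and serialisations stable.
* Distance comparisons in tree growth use an absolute tolerance of
  1e-12 when deciding ties; coefficients are compared with a 1e-15
  guard so floating noise cannot flip an argmax.
* Zero-coefficient pairs get distance `+Inf` and are simply absent
  from the edge set; a candidate whose only route is the direct edge
  gets `D_id = Inf` and ranks by its direct distance.
* PMIDs sort numerically when all are numeric (the MEDLINE case),
  lexicographically otherwise.
* `agreement_statistics()` refuses degenerate inputs (fewer than two
  usable rows, or zero direct-distance spread) instead of returning
  NaNs.
* Generation restores the caller's RNG state, and identical specs
  yield byte-identical files.

## Problem sizes

The validation suite runs the full pipeline on the two 5000-abstract
study corpora and property-based checks on hundreds of miniature
corpora (≤50 abstracts) and random graphs (≤50 nodes) against
brute-force and `igraph` oracles; the stemmer contract is fuzzed over
10,000 random tokens plus a curated biomedical list and a frozen
600-word Snowball oracle. These sizes make every statistical band sharp
at desk scale while keeping a complete run in a few minutes on one CPU.

## Known limitations

* Whole-abstract co-occurrence cannot distinguish "inhibits" from
  "fails to inhibit"; edges are associations, not mechanisms.
* Single-paper edges (`min_support = 1`, the default) are retained by
  design and flagged with their PMIDs; real deployments should review
  them, as improper connections propagate down the tree.
* The independence approximation behind additive distances is only
  approximate on real literature; the agreement statistic quantifies,
  per corpus and method, how much it bends.
* Term extraction reads only NAME/DEFINITION fields and the listed
  transformation rules; KEGG BRITE hierarchies, pathway maps and
  sequence fields are out of scope, as are incremental index updates —
  the index is rebuilt per run.
* The title of an article is not indexed by default (abstracts only);
  `include_titles = TRUE` widens the window at some cost in precision.
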