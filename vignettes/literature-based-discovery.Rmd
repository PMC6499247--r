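---
title: "Co-occurrence literature-based discovery: model, metrics and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence literature-based discovery: model, metrics and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbdgraph)
library(data.table)
```

## The model

Literature-based discovery (LBD) looks for plausible but unreported
associations between biomedical concepts by connecting disjoint parts of
the literature. In the ABC model, if concept A is repeatedly associated
with B, and B with C, but A and C never co-occur, the implicit A–C link is
a candidate discovery. `lbdgraph` implements the co-occurrence formulation
of this model over *entities* rather than strings: every mention in the
text is grounded to a database or ontology identifier (MeSH, ChEBI,
Protein Ontology, NCBI Taxonomy, hallmark categories), and the search
graph has one node per identifier, not per surface form. The mention level
(every occurrence, with offsets) is retained alongside, so any edge can be
traced back to the sentences supporting it.

Formally we work with a simple weighted graph $G = (N, E)$ whose nodes are
entity identifiers. An edge $(i, j)$ exists iff the two entities co-occur
in at least one sentence, and carries a weight $w(i,j)$ computed by a
configurable metric from the pair's contingency counts. Two query modes
are supported, both over paths of exactly two edges:

* **Closed discovery** — given $a$ and $c$, rank the intermediates
  $B = \{b : (a,b) \in E, (b,c) \in E\}$ by an *aggregation function*
  $f_g(w(a,b), w(b,c))$ (one of min, avg, max, sum).
* **Open discovery** — given $a$, rank the candidates
  $C = \{c : (a,c) \notin E,\ \exists b\}$ by an *accumulation function*
  $f_c$ (sum or max) over the $f_g$ path scores of all intermediates.

Longer paths are rejected at the interface: complexity grows exponentially
and two-edge chains are the standard ABC setting. Edges are undirected;
the model cannot express the direction of causality, which is a known
error source of co-occurrence LBD in general.

## Counting

The unit of co-occurrence is the **sentence**. A pair co-occurs in a
sentence iff each entity has at least one grounded mention there, counted
once per sentence regardless of mention multiplicity. From a corpus the
package aggregates, per pair: sentence co-occurrence count $n_{ab}$,
marginal sentence counts $n_a$, $n_b$, the document analogues $d_{ab}$,
$d_a$, $d_b$, and corpus totals $N_{sent}$, $N_{doc}$. Ungrounded
mentions stay in the mention-level data but contribute nothing to the
graph.

One point the sentence-centric definitions leave open is what "the pair
co-occurs in a document" means. The default dialect counts a document when
the pair shares at least one of its sentences (consistent with the
sentence-level metrics); a laxer `anywhere` dialect counts a document when
both entities appear in it at all. Both are available in
`aggregate_counts()`. **Exclusion is deliberately stricter than either**:
when a snapshot excludes a pair (the evaluation's A–C exclusion), a
document is removed if both entities appear anywhere in it, because the
protocol's guarantee — no surviving document contains both A and C — is
only met by the strict reading.

## The eight metrics

With $P(a) = n_a/N$, $P(b) = n_b/N$, $P(ab) = n_{ab}/N$
($N = N_{sent}$), and the 2×2 table $O_{11} = n_{ab}$,
$O_{12} = n_a - n_{ab}$, $O_{21} = n_b - n_{ab}$,
$O_{22} = N - n_a - n_b + n_{ab}$ with expectations $E_{ij}$ from the
margins:

| metric | definition | range |
|---|---|---|
| `count` | $n_{ab}$ | positive integer |
| `doc_count` | $d_{ab}$ | positive integer |
| `jaccard` | $n_{ab} / (n_a + n_b - n_{ab})$ | $(0, 1]$ |
| `scp` | $P(ab)^2 / (P(a)P(b))$ | $(0, 1]$ |
| `npmi` | $\ln\frac{P(ab)}{P(a)P(b)} \big/ (-\ln P(ab))$ | $(-1, 1]$ |
| `chi_squared` | $N (O_{11}O_{22} - O_{12}O_{21})^2 / (n_a n_b (N-n_a)(N-n_b))$ | $\ge 0$ |
| `t_test` | $(P(ab) - P(a)P(b)) \big/ \sqrt{P(ab)(1 - P(ab))/N}$ | unbounded |
| `llr` | $2 \sum_{ij} O_{ij} \ln(O_{ij}/E_{ij})$ | $\ge 0$ |

Numerical conventions, chosen once and frozen:

* natural logarithms everywhere;
* `npmi` at $P(ab) = 1$ is defined as 1 (the $0/0$ perfect-association
  limit);
* `llr` uses $0 \ln 0 = 0$;
* `t_test` uses the Bernoulli variance $P(ab)(1 - P(ab))$
  (collocation-statistics convention) rather than the cruder $P(ab)$
  approximation, and is 0 when the variance vanishes;
* degenerate margins (an entity in every sentence) force exact
  independence; the $0/0$ chi-squared limit is defined as 0. No valid
  count vector raises an error;
* all counts are promoted to double before multiplication — the
  chi-squared denominator overflows 32-bit integers at literature scale;
* signed metrics (`npmi`, `t_test`) are never clamped at zero; ranking
  handles negative weights as ordinary values.

All statistical metrics read sentence counts; only `doc_count` reads
document counts. Test oracles re-evaluate each closed form independently
(plain arithmetic plus `chisq.test` as an external route) and the
discovery pipeline is checked against exhaustive triple enumeration
(`discovery_oracle()`) for all 8 metrics × 4 $f_g$ × 2 $f_c$ on seeded
random graphs.

## Defaults and tie-breaking

Unconfigured queries run with **metric = jaccard, $f_g$ = min and (open)
$f_c$ = sum**, the combination that performed most consistently across
both discovery settings in the system evaluation this design follows.
`fg = "sum"` is accepted beyond the interactive trio so that pure
frequency scoring (both functions sum) is expressible.

Candidate ranking sorts by descending score with ties broken by ascending
entity identifier. The tie rule is a package convention: no published
convention exists, and deterministic ranks are a prerequisite for
reproducible evaluation. For the same reason the sentence splitter is
rule-based (terminal punctuation + whitespace + capital/digit, with an
abbreviation guard list) rather than learned: reproducibility outweighs
marginal accuracy, and upstream sentence counts are unreproducible anyway
without knowing the original splitter.

## Identifier generalization

Grounded gene identifiers are often species-specific, splitting one
conceptual gene across homolog nodes. `apply_id_mapping()` applies a
user-supplied single-step source→target table (e.g. NCBI Gene → Protein
Ontology at the homolog-abstracting level). The mapping is applied once,
with no transitive chasing — pre-composing chains is the caller's job,
which keeps the semantics auditable. For grounded identifiers in a source
namespace that lack an entry, the default policy keeps them as their own
nodes; the `drop_unmapped_from_graph` policy un-grounds them instead
(mention-level data retained, graph excluded), matching the behaviour of
systems that ship a near-complete mapping. The default differs because no
mapping table is bundled here: silently dropping most of a namespace on a
sparse user table would be destructive. `mapping_coverage()` reports the
fraction of distinct source identifiers covered.

## The evaluation protocol

`run_case()`/`grid_evaluate()` replicate the time-slicing protocol used to
score LBD systems on historical discoveries:

1. cutoff at `discovery_year - 5`, **inclusive** ("literature up to five
   years before" the discovery report);
2. remove every document in which A and C co-occur (document-level,
   strict);
3. open mode: query A, find the rank of C among candidates; closed mode:
   query (A, C), find the rank of B;
4. summarize each configuration by the **median rank** (middle value;
   mean of the two middle values for even counts). Targets that are not
   retrieved are excluded from the median and reported as counts, not
   assigned a sentinel rank — the reference evaluation retrieved all its
   targets and never faced the choice.

Two case fixtures ship in `inst/extdata/`: five cancer-biology triples
(with a *synthetic* placeholder discovery year, flagged in the filename,
because the true years live in references not available to this package)
and five classic indirect-association pairs with their documented report
years.

## The synthetic-data generator

`corpus_spec()`/`generate_corpus()` state a world in which counting and
ranking are exactly checkable:

* **deterministic mode** emits one template sentence per requested
  co-occurrence or solo event, so aggregated counts equal the
  specification exactly; one sentence per document by default (sentence
  and document counts coincide), with a `sentences_per_doc` knob to force
  the two apart;
* **sampled mode** draws per-entity Bernoulli inclusion per sentence,
  reproducibly from a seed;
* `plant_discovery()` adds an A–B–C structure: `ab_count = bc_count = 100`
  by default, the co-occurrence threshold used when curating evaluation
  triples ("at least 100 publications" for each of A–B and B–C), zero A–C
  co-occurrence before the cutoff, optional A–C events after it.

Template sentences embed real surface forms at recorded offsets, so the
offset bookkeeping of the ingestion path is exercised, but no attempt is
made to imitate the language statistics of abstracts: a green test
establishes correct counting, scoring, slicing and ranking on controlled
structure — not NER quality, not grounding quality, and not the
performance figures of any full-literature system. Corpus-scale results
(median ranks over tens of millions of citations, mapping-coverage
percentages, corpus statistics) are out of reach at desk scale by
construction and are deliberately not asserted anywhere.

## Known limitations

* Co-occurrence only: no relation extraction, no directionality, no
  negation handling.
* Paths of length two only.
* The exact reference formulations of the metrics live in supplementary
  material not available to this implementation; the standard closed
  forms above are this package's binding definitions, validated against
  independent re-evaluations rather than against that supplement.
* The bundled cancer-case fixture carries synthetic discovery years.
* No YAML configuration (JSON only): no YAML parser is available in the
  supported dependency set.
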