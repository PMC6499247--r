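# lbdgraph

Literature-based discovery (LBD) over entity co-occurrence graphs, for
biomedical text-mining and knowledge-discovery work. Given a corpus of
annotated titles and abstracts (PubTator pipe/TSV format or an internal
JSON-lines format), `lbdgraph` builds a graph whose nodes are grounded
entity identifiers (MeSH, ChEBI, Protein Ontology, taxonomy, hallmark
categories) and whose edges record sentence-level co-occurrence, then
answers the two classic ABC-model queries:

* **closed discovery** — given concepts *a* and *c*, rank the
  intermediates *b* with edges to both, scored by an aggregation function
  `fg(w(a,b), w(b,c))`;
* **open discovery** — given *a*, rank concepts *c* at graph distance
  exactly two, accumulating path scores with `fc` (sum/max) over all
  shared neighbors.

Edge weights `w(i,j)` come from one of eight association metrics computed
from the pair's contingency counts (`n_ab`, `n_a`, `n_b`, `N`): raw
sentence and document counts, Jaccard index, symmetric conditional
probability (SCP), normalized pointwise mutual information (NPMI),
chi-squared, a collocation t statistic, and the log-likelihood ratio
(LLR). Defaults are **Jaccard, fg = min, fc = sum**. The package also
implements the standard time-sliced evaluation protocol (snapshot at a
cutoff year, document-level A–C exclusion, rank of the expected node,
median-rank grids over all metric × scoring-function combinations) and a
synthetic-corpus generator that plants A–B–C structures with exact counts,
so the entire stack is testable without external data.

See `vignettes/literature-based-discovery.Rmd` for the model, formulas and
design decisions.

## Worked example

The two-path illustration: a strong edge w(a1,b1) = 10 realized as 10
co-occurrence sentences, three weaker edges of weight 2.

```r
library(lbdgraph)

spec <- corpus_spec(
  entities = data.frame(entity_id = c("a1", "b1", "b2", "c1"),
                        entity_type = "Gene",
                        surface = c("alpha", "betaone", "betatwo", "gammaone")),
  pairs = data.frame(id1 = c("a1", "a1", "b1", "b2"),
                     id2 = c("b1", "b2", "c1", "c1"),
                     count = c(10L, 2L, 2L, 2L)))
corpus <- generate_corpus(spec)
#> <lbd_corpus> 16 documents, 16 sentences, 32 mentions (32 grounded)

graph <- build_graph(aggregate_counts(corpus))
#> <lbd_graph> 4 nodes, 4 edges (N_sent=16, N_doc=16)

closed_discovery(graph, "a1", "c1", scoring_config("count", fg = "sum"))
#> <closed_result> a=a1 c=c1 metric=count fg=sum: 2 candidate(s)
#>     rank     id score  w_ab  w_bc
#> 1:     1     b1    12    10     2
#> 2:     2     b2     4     2     2

open_discovery(graph, "a1")          # package defaults: jaccard / min / sum
#> <open_result> a=a1 metric=jaccard fg=min fc=sum: 1 candidate(s)
#>     rank     id     score n_paths
#> 1:     1     c1 0.2857143       2
```

Reading the numbers: with the count metric and `fg = sum`, b1 scores
`w(a1,b1) + w(b1,c1) = 10 + 2 = 12` and b2 scores `2 + 2 = 4`, so b1 is
the top intermediate linking a1 to c1. Under the defaults, each two-edge
path a1–b–c1 is scored by its weaker Jaccard edge
(`min(0.714, 0.143) = 0.143` via b1, `min(0.143, 0.333) = 0.143` via b2)
and the two path scores are summed: c1 scores `0.286` from 2 supporting
paths. c1 is an *open* candidate precisely because it has no direct edge
to a1.

The same pipeline is scriptable end to end:

```sh
Rscript exec/lbdgraph generate    --spec spec.json --out corpus.jsonl
Rscript exec/lbdgraph query-closed --corpus corpus.jsonl --a a1 --c c1 \
        --metric count --fg sum --out result.json
Rscript exec/lbdgraph evaluate    --cases inst/extdata/swanson_discoveries.tsv \
        --corpus corpus.jsonl --out report
```

Subcommands: `ingest`, `map-ids`, `build`, `resolve`, `query-open`,
`query-closed`, `evaluate`, `generate`. Result files embed the resolved
configuration for provenance.

## Evaluation protocol

`run_case()` scores a historical discovery (A, B, C, year) by restricting
the corpus to years ≤ `discovery_year − 5`, removing every document in
which A and C co-occur, and reporting the rank of the expected node
(C in open mode, B in closed mode); `grid_evaluate()` produces the median
rank for every metric × fg (× fc) combination. Case fixtures mirroring
the standard cancer-discovery and classic indirect-association evaluation
triples ship in `inst/extdata/` (the cancer set with synthetic placeholder
years — see the vignette).

Full-literature results (median ranks over ~27M citations, corpus
statistics, mapping-coverage percentages) are **not** reproducible at this
scale and are not claimed; the test suite instead verifies the machinery
on planted synthetic discoveries, where the expected node must come back
at rank 1 under the default configuration.

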