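# belminer

Semi-automated extraction of causal biological knowledge from article text
into BEL (Biological Expression Language) networks.

Biomedical findings are published as prose; systems-biology analyses need
them as computable causal triples. `belminer` implements a curation
workflow in R that takes cleaned article passages through dictionary-based
named-entity recognition and trigger-pattern event extraction to BEL
statements of the form

```
subject  predicate  object        e.g.   p(HGNC:CYP4A11) -> bp(GOBP:angiogenesis)
```

each backed by an evidence sentence, a PMID and context annotations
(species, tissue, cell, disease). Validated BEL documents (BEL Script or
XBEL) compile into a **knowledge assembly model (KAM)** — a directed
multigraph over canonical BEL terms with causal edges (`increases`,
`decreases`, `directlyIncreases`, `directlyDecreases`, `causesNoChange`)
and non-causal edges connecting alternative forms of one entity (gene →
RNA → protein, complex → component). The package also provides the
analyses used to characterize such networks: degree reports, hub detection
(degree above the mean), a log-log scale-free fit, network comparison,
evidence-sentence overlap and curation-efficiency metrics, plus
deterministic generators of synthetic corpora and random graphs so the
whole pipeline is testable offline.

The heavyweight commercial components of production pipelines (dictionary
tagger, SVM event extractor, the interactive curation GUI) are *not*
reimplemented; rule-based stand-ins with identical I/O contracts take
their place, and a programmatic curation-edit API (accept / reject /
modify / assemble fragments / annotate, with automatic re-validation)
covers the curation step.

## Worked example

From a raw evidence sentence (with a PDF line-break artifact) to a
network:

```r
library(belminer)

sentence <- clean_text(
  "capillary vessel counting showed that CYP4A11 transfection signifi-\ncantly increased microvessel density")
#> "capillary vessel counting showed that CYP4A11 transfection significantly increased microvessel density"

dicts <- bundled_dictionaries()          # HGNC / GOBP / CHEBI excerpts
(mentions <- ner(sentence, dicts))
#> # A tibble: 2 × 6
#>   start   end matched_text        namespace id           bel_class
#> 1    38    45 CYP4A11             HGNC      CYP4A11      gene_protein
#> 2    83   102 microvessel density GOBP      angiogenesis process

events <- extract_events(sentence, mentions)
(stmt <- event_to_statement(events[1, ]))
#> <bel_statement> p(HGNC:CYP4A11) -> bp(GOBP:angiogenesis)
```

The trigger "increased" produced a positive-regulation event whose cause
(the nearest preceding mention) and theme (the nearest following one)
became subject and object; "microvessel density" was normalized to its
preferred identifier `GOBP:angiogenesis` by the dictionary. Put this
statement in a document together with the nested manual-style annotation
of the same finding and compile:

```r
doc <- bel_document(
  name = "example",
  namespaces = c(HGNC = "-", GOBP = "-", CHEBI = "-"),
  blocks = list(bel_block(
    bel_evidence(sentence, pmid = "21120482", section = "results"),
    annotations = list(Species = "10090"),
    statements = list(
      stmt,
      parse_statement(
        "p(HGNC:CYP4A11) -> (sec(a(CHEBI:'20-HETE')) -> bp(GOBP:'blood vessel development'))")))))

(k <- compile_kam(doc))
#> <kam> 5 nodes, 4 edges (3 causal, 1 non-causal); 1 source document(s)

tidy(k)
#> # A tibble: 4 × 6
#>   source                target                               relation     causal structural evidence_count
#> 1 p(HGNC:CYP4A11)       bp(GOBP:'blood vessel development')  increases    TRUE   FALSE      1
#> 2 p(HGNC:CYP4A11)       bp(GOBP:angiogenesis)                increases    TRUE   FALSE      1
#> 3 sec(a(CHEBI:20-HETE)) a(CHEBI:20-HETE)                     hasComponent FALSE  TRUE       0
#> 4 sec(a(CHEBI:20-HETE)) bp(GOBP:'blood vessel development')  increases    TRUE   FALSE      1
```

The nested statement contributed its inner edge
(`sec(...) -> bp(...)`), an outer edge from the subject to the inner
object, and one inferred non-causal edge linking the secretion term to the
chemical it secretes. `node_census(k)` tabulates nodes over the 15 BEL
functions, `edge_census(k)` splits edges into causal and non-causal,
`degree_report(k)` / `find_hubs(k)` / `scale_free_check(k)` analyse
topology, and `export_xgmml(k, "net.xgmml")` writes the network for
Cytoscape.

Curation-efficiency arithmetic from a recorded comparison of the
semi-automated and manual arms:

```r
curation_metrics(data.frame(
  arm = c("semi_automated", "manual"),
  minutes = c(395, 613), statements = c(234, 191),
  annotations = c(112, 46)))
#>   arm            minutes statements annotations min_per_statement min_per_statement_annotation
#> 1 manual             613        191          46               3.2                          2.6
#> 2 semi_automated     395        234         112               1.7                          1.1
```

— the semi-automated arm curates a statement in roughly half the manual
time.

A thin command-line front-end over these functions is installed at
`inst/scripts/bel-workflow.R` (subcommands `pipeline`, `compile`,
`analyze`, `fixtures`). The methods vignette
(`vignettes/belminer-methods.Rmd`) documents the grammar subset, the
extraction stand-ins, the compilation rules and the design decisions.

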