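---
title: "From free text to causal networks: methods behind belminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From free text to causal networks: methods behind belminer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(belminer)
```

## The curation problem

Most biomedical knowledge is locked in free-text articles. Semi-automated
curation workflows convert such text into the Biological Expression Language
(BEL): subject--predicate--object triples such as
`p(HGNC:CYP4A11) -> bp(GOBP:angiogenesis)` ("the CYP4A11 protein abundance
increases angiogenesis"), each carried by an evidence sentence, a PubMed
identifier and experimental-context annotations (species, tissue, cell,
disease). Validated BEL documents compile into a knowledge assembly model
(KAM): a directed multigraph whose nodes are canonical BEL terms and whose
edges are causal (`increases`, `decreases`, `directlyIncreases`,
`directlyDecreases`, `causesNoChange`) or non-causal (links between
alternative forms of one entity, such as a transcript and its protein, or
correlative associations). belminer implements this workflow end to end in
R, together with the analyses used to characterize the resulting networks:
degree distributions, hub detection, scale-free fits, network comparison,
evidence overlap and curation-efficiency metrics.

## The BEL subset and its grammar

The grammar covers fifteen term functions — six single-argument
abundance/process functions (`a`, `p`, `r`, `g`, `bp`, `path`), two grouping
functions (`complex`, `composite`) and seven wrappers (`act`, `pep`, `kin`,
`cat`, `tscript`, `deg`, `sec`) — and nine relationships. This is the
closure of what curated vascular-disease networks actually use, not the full
OpenBEL language; protein modifications, variants and translocations are out
of scope. Structural constraints enforced by the validator:

* single-argument functions take exactly one `NAMESPACE:value`;
* `complex`/`composite` take either one namespace value (a named complex) or
  at least two member terms;
* wrappers take exactly one inner term which must be a molecular abundance
  (`a`, `p`, `r`, `g`, `complex`, `composite`). A process cannot be secreted
  or carry kinase activity, so `kin(bp(...))` is a violation;
* term nesting is at most two levels, statement-object nesting at most one
  (the only style seen in practice is `A -> (B -> C)`).

The parser is a hand-written recursive-descent parser: the grammar is tiny
and exact character offsets in error messages matter during curation.
Long-form names (`proteinAbundance`) are accepted on input; short forms are
canonical on output. Namespace keywords are case-insensitive on input and
upper-case canonically; values are case-sensitive and quoted exactly when
they contain characters outside `[A-Za-z0-9_-]`. PDF-derived text carries
Unicode smart quotes, dashes and ligatures; these are normalized to ASCII
before parsing, so the printed form
`sec(a(CHEBI:'20-HETE'))` with curly quotes parses to the same AST as its
ASCII rendering. Validation returns violations as data (a tibble), never as
exceptions: the curation loop must be able to show them to a user and
refuse an edit without aborting.

Two serializations are supported, with full read/write round-trips: BEL
Script (a line-oriented `SET`/`DEFINE` dialect) and XBEL (an XML dialect
with elements for the header, namespace declarations, annotation
definitions, statement groups, evidence, annotations and one level of
nested statement objects; terms are embedded as canonical BEL text). The
machine-only companion produced alongside XBEL — entity text locations and
alternative namespace candidates, which cannot be coded in BEL but matter
for the curation interface — is emitted as a documented JSON sidecar.

## Text processing and the extraction stand-ins

`clean_text()` repairs what PDF conversion breaks: hyphenation across line
breaks, in-paragraph newlines, control characters, ligatures and smart
punctuation. It is idempotent, and all downstream offsets (0-based,
half-open) refer to the cleaned text. Only abstract, methods and results
sections are retained for extraction — introductions and discussions mostly
restate results and hypotheses, diluting causal evidence. Sentence
segmentation protects common abbreviations ("et al.", "Fig.", "e.g.") and
decimal numbers.

Production curation pipelines use a commercial dictionary tagger and an
SVM-based event extractor for these two stages. Both are replaced here by
deliberately simple rule-based components with the *same output
contracts*, so every downstream stage is fully testable and an adapter can
swap real taggers in later:

* **NER** is token-boundary-anchored longest match against TSV dictionaries
  (HGNC, GOBP, ChEBI and so on). Overlaps resolve by longer span first,
  then dictionary priority order. Tokens of four characters or fewer match
  case-sensitively (gene symbols such as `FAS` must not match "fas"),
  longer tokens case-insensitively; this policy is configuration, not
  hard-coded. Synonym collisions (one surface form, two identifiers) are
  rejected when the dictionary loads, not silently resolved at match time.
* **Event extraction** scans for regulation triggers (defaults: increase,
  induce, promote, upregulate, enhance for positive regulation; decrease,
  inhibit, reduce, suppress, downregulate for negative, with simple
  inflections). The theme is the nearest mention after the trigger, the
  cause the nearest mention before it; events never cross sentence
  boundaries. A trigger with no theme yields nothing; a trigger with no
  cause yields an event that converts to a relation--object fragment for
  later assembly. Negated triggers ("did not increase") yield no event by
  default; an optional mode maps them to `causesNoChange`. The conservative
  default reflects that negative evidence is rarely what a curator wants
  auto-asserted.

Recall evaluation counts a found mention as correct when sentence, span,
namespace and identifier all match the gold standard; per-dictionary recall
is gold-matched over gold, with precision reported alongside.

## Conversion, documents and curation edits

Positive and negative regulation map to the *indirect* causal relations
(`->`, `-|`): a sentence-level extractor cannot establish directness, so
the direct forms (`=>`, `=|`) are reachable only through curation edits.
Entity classes select term functions (gene/protein → `p`, chemical → `a`,
process → `bp`, complex → `complex`, family → `p`). Documents are built
with one evidence block per statement-bearing sentence, deterministic
ordering (passage order, sentence span, statement serialization), and a
sidecar record per statement. Curation edits — accept, reject, modify,
assemble two matching fragments, set an annotation — always operate on a
copy (the original document is preserved), and every surviving statement is
re-validated; an edit that would introduce an invalid statement is refused
together with the validator's violation list. Assembly consumes exactly one
subject--relation and one relation--object fragment whose relations agree
and produces one complete statement.

## KAM compilation

Each distinct canonical term becomes one node; identical terms in different
documents unify by key. Complete statements become edges keyed by
(source, target, relation); duplicates merge, accumulating evidence
(document, PMID, sentence). Fragments do not compile. For a nested
statement `A rel (B rel2 C)` the compiler emits the inner edge `B rel2 C`
and an edge `A rel C` from the outer subject to the inner object. The
latter policy was a genuinely open design point: the alternative (linking
`A` to the nested subject `B`) is defensible, but the outer annotation is
*about* the downstream entity, and choosing the inner object makes the
semi-automated (`p(X) -> bp(angiogenesis)`) and manual
(`p(X) -> (sec(...) -> bp(blood vessel development))`) annotation styles of
the same finding agree on connecting the protein to the downstream process.
The rule is isolated in one place so the policy can be changed.

Non-causal edges arise by structural inference over the realized nodes,
with each rule independently switchable: `complex -> member`
(`hasComponent`), wrapper term -> inner abundance (also `hasComponent`,
the closest structural relation in the nine-relation inventory),
`r(X) -> p(X)` (`translatedTo`) and `g(X) -> r(X)` (`transcribedTo`)
whenever both forms of one `namespace:value` are present. This is how a
corpus of purely causal statements still yields a network whose non-causal
edges connect alternative forms of the same biological entity. Inferred
edges carry no evidence and never override a statement-derived edge with
the same key. Self-edges are retained and counted once. Compilation is
order-independent (nodes, edges and evidence are canonically sorted) and
merging KAMs is idempotent, with the empty model as identity.

## Topology and comparison analyses

Degree is computed on the undirected simple-graph projection by default
(parallel edges collapsed, self-loops contributing two), matching the
convention of the Cytoscape Network Analyzer; directed and multigraph modes
sit behind arguments. Hubs are exactly the nodes whose degree strictly
exceeds the mean degree — ties at the mean are excluded. The scale-free
check fits a least-squares line to log10(frequency) versus log10(degree)
over degrees of at least one, again following the log-log-regression
practice of the desktop tool rather than maximum-likelihood power-law
estimation; the verdict is scale-free when the exponent lies in [-4, -1]
and R^2 >= 0.7 (configurable), and *indeterminate* — a value, not an
error — when fewer than ten distinct degree values exist.

Evidence overlap between two curation arms normalizes sentences
(lower-case, punctuation stripped, whitespace collapsed) and reports the
Jaccard fraction as the headline, with both per-set fractions alongside:
published overlap percentages rarely state their denominator, so all three
conventions are available. Curation metrics divide recorded minutes by
statements and by statements-plus-annotations per arm, rounding half-up to
one decimal as curation-time tables conventionally do. On the published
seven-article comparison log (395 min / 234 statements / 112 annotations
semi-automated; 613 / 191 / 46 manual) this yields 1.7 and 3.2 min per
statement and 2.6 min per statement+annotation for the manual arm; the
semi-automated statement+annotation ratio computes to 395/346 = 1.1,
whereas the corresponding published table prints 1.2 — an internal
inconsistency of that table, documented here rather than reproduced.

## Synthetic fixtures: what they emulate and what they do not

Every stage is testable offline through deterministic generators
(`generator_config()` fixes a seed; identical configurations give
byte-identical outputs):

* `generate_corpus()` builds templated sentences ("<gene> significantly
  increased <process>.", fragment and distractor templates) from the
  bundled excerpt dictionaries, together with the exact gold mentions,
  events and statements those plants imply. The defaults (7 articles,
  12 sentences each, 10% fragment rate, 15% distractors) mirror a small
  focused curation corpus. Because gold and extractor follow the same
  rules, clean-setting recall is 100% *by construction* — this validates
  the plumbing, not linguistic performance on real prose. Real text has
  coreference, apposition, negation scope and paraphrase that templates do
  not emulate; published taggers reach F-scores near 0.8 on gene names,
  and nothing here should be read as improving on that.
* A `withheld_rate` of 0.1 designates 10% of the entity pool as absent
  from the dictionaries (`drop_synonyms()`), emulating incomplete
  vocabularies; expected recall is 90% up to sampling error, and measured
  recall on 30 articles x 20 sentences lands within a few points of it.
* `generate_bel_corpus()` samples statements from a shared pool sized so a
  configurable fraction recurs across documents, giving known
  node/edge/evidence counts checkable by an independent set-construction
  oracle.
* `generate_graph()` wraps preferential-attachment and uniform random
  graphs (igraph's generators) in KAM form: the positive and negative
  controls for the scale-free verdict. At n = 2000, m = 2 the
  preferential-attachment fit returns an exponent near -2.2 with R^2
  around 0.9; uniform graphs of matched size are rejected in a clear
  majority of seeded runs.

Problem sizes in the test suite (500 round-trip statements, corpora of a
few hundred statements, graphs of 400--2000 nodes) were chosen as the
smallest sizes at which the asymptotic behaviours under test are stable.

## Numerical and degenerate-input choices

* Offsets are 0-based half-open everywhere, inherited from the cleaned
  text.
* Rounding in curation metrics is half-up (not banker's) to one decimal.
* `find_hubs()` on an empty graph is an error; degree zero and mean zero
  are fine.
* An empty KAM censuses to all zeros; `edge_census()` satisfies
  causal + non-causal = total by construction.
* Dictionary collisions, undeclared namespaces, undefined annotation keys
  and statements outside evidence blocks are load-time errors with line
  numbers, not warnings.
* Whether the original corpus used `directlyIncreases` as well as
  `directlyDecreases` is unknowable from the published material; both
  directions are implemented symmetrically.

## Known limitations

The extraction components are intentionally minimal stand-ins; recall on
real articles depends on dictionary coverage and linguistic preprocessing
far beyond longest-match and trigger patterns. The bundled dictionaries
are small excerpts for fixtures and examples, not usable vocabularies.
XGMML round-trips preserve nodes, edges and the exported attributes
(function, relation, causality, evidence count) but not evidence text,
which lives in the KAM JSON. The published plaque-destabilization network
itself ships as journal supplementary material; reproducing its exact
566/177 causal/non-causal split would additionally require the original
BEL-framework inference-rule configuration, which is why each structural
rule here is independently switchable.
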