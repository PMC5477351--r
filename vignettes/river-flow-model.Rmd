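---
title: "The River Flow Model of diseases: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The River Flow Model of diseases: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverflow)
```

## The model

The River Flow Model (RFM) treats a disease not as a static property but
as a dependent continuant constituted of **causal chains of abnormal
states**: directed graphs whose nodes are clinical disorders and whose
edges assert "this state brings about that state". Three kinds of chains
matter:

* the **core causal chain**, appearing in every patient with the disease —
  its defining essence;
* **derived causal chains**, reached by tracing the general chains
  upstream (possible causes) or downstream (possible symptoms) from the
  core;
* the **general causal chains**, the union of all authored chains across
  all diseases — assembled bottom-up, since no one can enumerate every
  causal relationship in the body a priori.

Causal links are *global*: a disease's chain is the subgraph of the global
link set induced on its state set. A disease that declares super-diseases
(`subDiseaseOf`) stores only its additional states; reading its chain
aggregates the state sets of all transitive supers (`effective_states()`,
`chain_graph()`).

Abnormal states live in a three-layer is-a hierarchy (`subStateOf`):
Level 1 generic and object-independent, Level 2 object-dependent,
Level 3 context-dependent. Each state may carry
`<Object, Sub-Object, Attribute, Value>` descriptors. `check_levels()`
verifies the layer constraints; unknown nodes (placeholders for
unidentified causes or elided chain segments) are exempt from the
ancestry requirements because they carry no descriptors or parents by
construction.

## Chain inclusion and is-a inference

Disease *A* is a super-class of disease *B* when all of *A*'s chains are
included in *B*'s. `chain_included_in()` decides inclusion with a
backtracking search for an **injective** node map from *A*'s states to
*B*'s states such that:

* a node of *A* maps to the *same* state or a `subStateOf`-**descendant**
  in *B*. This direction — the general disease's node covered by an
  equal-or-more-specific node of the specific disease — is the only one
  consistent with the diabetes worked example together with the
  Level-2/3 specialization narrative;
* an unknown node maps only onto an unknown node (but any state is freely
  traversed *inside* an edge path);
* each causal link of *A* is realized in *B* as a direct link
  (`mode = "strict"`) or a nonempty directed path (`mode = "path"`, the
  default — authored subclass chains routinely elide intermediates, as in
  "long-term steroid treatment → … → deficiency of insulin").

Injectivity prevents degenerate witnesses in which two distinct states of
the general chain collapse onto one specific state. Ties in the search are
broken by sorted state id, so witnesses are bit-reproducible. Inclusion is
compared over the aggregated core-plus-derived graphs ("all causal chains
at the class level"); a core-only comparison is available behind the
`which` flag.

`infer_isa_hierarchy()` runs the test over every ordered disease pair.
Chains that include each other are indistinguishable under the matching
mode and are reported as **equivalences**, never as cycles; the `pairs`
component is therefore antisymmetric and transitively closed, and
`reduced_pairs` is its transitive reduction. Because aggregation makes a
declared subclass always contain its super's chain, a *declared*
`subDiseaseOf` assertion can only fail the inferred test when the subclass
authors nothing of its own (the pair lands in `equivalences`); such pairs
are surfaced as declared-vs-inferred discrepancies.

## Core-chain extraction

`core_causal_chain()` implements the definition "the causal chain included
in the chains of all subclass diseases" by **per-element filtering** rather
than maximal-common-subgraph search: a state of the disease's chain is kept
iff every subclass chain covers it with an equal-or-more-specific state,
and a link iff a direct link/path between covering states exists in every
subclass chain; the result is the graph induced on the kept elements. This
is deterministic and polynomial, and matches the element-wise phrasing of
the definition. Connectivity of the result is reported
(`graph_components()`) but not enforced — the printed examples are
connected paths, but no requirement is stated, so we chose not to invent
one. With zero subclasses the intersection is undefined and the function
falls back to the declared core chain. The `subclasses` argument exists
because some ontologies (including generator output) carry standalone
subclass chains without declared supers.

## Interoperable state representation

A state can be written quantitatively (`<blood, pressure, 180 mmHg>`),
qualitatively (`<blood, pressure, high>`) or as a property
(`<hypertension, true>`). The conversion pattern is part of the model; the
**numeric cut-points are not** — they are user-supplied rule-table content.
The fixture table uses conventional clinical thresholds (140 mmHg systolic
hypertension, 126 mg/dL fasting hyperglycemia, 10 mm² arterial
cross-section, 10 colonic polyps), chosen once as realistic values and
documented as fixture parameters. Intervals are half-open `[lower, upper)`;
units must match exactly (no conversion engine); each property pairs
`TRUE` with the abnormal category and `FALSE` with the normal one, so
normal measurements normalize without error and `interoperable()` can
return a definite `FALSE` for `<blood, pressure, 120 mmHg>` vs
`<hypertension, true>`.

External-vocabulary mapping (`match_external()`) uses perfect string
matching after normalization (trim, collapse internal whitespace,
case-fold). Whether the original workflow's matcher was case-sensitive is
not stated; we default to case-insensitive because the published example
maps "chest pain" to an external "Chest pain", which byte-exact matching
would miss — `options(riverflow.case_sensitive = TRUE)` restores strict
matching. Candidates are never auto-accepted (mapping is a manual act);
`mapping_summary()` tabulates accepted mappings per level.

## RDF model and query layer

`to_rdf()` emits the instance-level linked-data model: typed
`Abnormal_State` / `Disease` resources, `rdfs:label`, `subStateOf` /
`subDiseaseOf`, `hasCoreState` / `hasDerivedState` for a disease's **own**
states only (inherited states are recovered at query time by d2-style
aggregation), and both members of each inverse causal pair (`hasCause` /
`hasResult`, probable variants for probable links) so the serialized graph
answers both directions without inference. By default a `hasCause` arc runs
from an effect state to its cause ("this state has cause X"); the
convention is a vocabulary switch because the published text does not pin
it down. Only the prefix `dont:` is conventional; the namespace IRI is
configurable. Descriptors the published model does not define (levels,
O/SO/A/V, unknown flags, external refs, clinical area, AND-branch
annotations) go into a separate extension namespace and are emitted only
for non-default values, keeping serialization lossless while a minimal
disease-plus-state ontology emits exactly its five contracted triples.
Unrecognized predicates encountered on read are preserved in a side
channel and re-emitted verbatim.

Multiple incoming causes default to OR semantics (alternative causes);
AND is an annotation only, serialized through the extension namespace,
because the published RDF model defines no AND marker. Probable links
participate in all graph operations exactly like certain links — the flag
is carried and reported, never used to prune, since probability semantics
are out of scope. Self-loop causal links are rejected at load time;
traversal semantics for them would be ambiguous and none appear in the
source material.

`run_query()` answers the nine standard patterns (a1–a3, d1–d6) over the
in-memory model; the literal SPARQL texts ship under `inst/sparql/` and the
test suite executes them against the Turtle output with a small,
independent SPARQL evaluator (basic graph patterns, property paths,
`FILTER ... IN`), verifying both routes agree. No conformant SPARQL engine
is available in the supported environment, so that evaluator — code-wise
fully independent of `run_query()` — stands in for one. The shipped a3
pattern follows its published description and traverses `hasCause` /
`hasResult` only; probable arcs use distinct predicates and are not part
of that closure (the model-level `general_graph()` traversals, by
contrast, treat probable links like certain ones).

## The synthetic generator's stated world

`generate_ontology()` emulates the authoring process: root diseases with
fresh chains; subclasses derived by copying the parent chain, then
specializing inherited states to planted `subStateOf` children
(`p_refine = 0.3`), inserting intermediates on inherited edges
(`p_insert = 0.2`), and always appending at least one new upstream or
downstream state. Defaults — 30 diseases on a tree of depth ≤ 3, chains of
3–6 states, 10% probable links, 5% unknown nodes — reflect a small
clinician-authored ontology with moderate refinement; they were chosen
once as the stated world and are not tuned to test outcomes.

One generation rule deserves its rationale: because links are global and
chains are induced subgraphs, inserting an intermediate on an edge whose
endpoints survive verbatim would leave the parent's direct link inside the
subclass chain, and strict-mode inclusion could never fail — the
strict-vs-path direction check would be vacuous. Node insertion therefore
*re-expresses the downstream state* as a fresh planted child in the
subclass context (clinically: refining the causal resolution of a step
re-contextualizes its result), which removes the direct link from the
subclass's induced graph. Path-mode recovery of the planted hierarchy then
stays perfect while strict-mode recall drops, as the acceptance suite
verifies.

Subclasses carry standalone chain copies and declare no `subDiseaseOf`
(flag `declare_supers` to change this): with declared supers, aggregation
would make the planted inclusions true by construction and the recovery
test meaningless.

What a green recovery test establishes: the matcher recovers exactly the
planted hierarchy under the generator's authoring assumptions (fresh
states per family, refinement along planted is-a edges, elisions as
inserted nodes). What it does not establish: performance on real
clinician-authored ontologies, whose chains share states across families,
contain hub states with many diseases, and whose granularity varies —
none of which the generator models. Chain-length and branching
distributions are not calibrated to clinical data; the generator targets
algorithmic test structure only.

## Numerical and degenerate-input choices

* Traversals use visited sets and terminate on cyclic inputs; closures
  always include the seed.
* The empty graph is vacuously included in any graph; a disease with no
  states yields an empty chain.
* Duplicate causal links collapse; a link authored both certain and
  probable deduplicates to certain, deterministically.
* Serialization sorts triples by subject, predicate, object — output is
  byte-stable; ordered core/derived sets preserve authoring order in TSV
  but order carries no semantics (model equality is set-based).
* Identifiers are case-sensitive opaque strings; a state may appear in one
  disease's core set and another's derived set (the model permits it, and
  nothing in the source material forbids it).

## Known limitations

* The Turtle reader supports the subset the writer emits plus common
  conveniences (`;`/`,` continuations, comments, `a`, datatype/language
  tags which are dropped); it is not a full Turtle parser.
* The query layer answers the nine shipped patterns, not arbitrary SPARQL,
  and no HTTP endpoint is provided.
* OWL class-restriction encoding, probability estimation for probable
  links, temporal indexing of states, and progression/identity tracking
  are explicitly out of scope.
* `infer_isa_hierarchy()` is quadratic in the number of diseases with an
  exponential-worst-case matcher per pair; candidate pruning by
  subsumption keeps realistic inputs fast (hundreds of diseases), but
  adversarial graphs with many mutually substitutable states can be slow.
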