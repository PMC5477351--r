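# riverflow

Diseases as causal chains of abnormal states: an R implementation of the
**River Flow Model (RFM)** of disease.

## The problem

Most disease ontologies describe static properties of diseases. Clinicians,
however, think of a disease as a *process unfolding in the body*: an
etiological trigger causes an abnormal state, which causes the next one,
branching and extending like a river. The RFM formalizes that intuition: a
**disease** is constituted of one or more **causal chains** of abnormal
states (clinical disorders), represented as a directed graph with states as
nodes and causal links as edges.

Two definitions give the model its reasoning power:

* **is-a between diseases.** Disease *A* is a super-class of disease *B*
  iff all causal chains of *A* are included in those of *B*, where node
  inclusion allows a node of *A* to be matched by the *same or a more
  specific* state (via the state `subStateOf` hierarchy), and each causal
  link of *A* must be realized as a direct link or a directed path in *B*.
* **Core causal chain.** The part of a disease's chain included in the
  chains of *all* its subclass diseases — the disease's stable, defining
  essence (e.g. for diabetes: *deficiency of insulin → elevated level of
  glucose in the blood*).

Abnormal states themselves live in a three-layer hierarchy (Level 1
generic, e.g. "small in area"; Level 2 object-dependent, e.g. "arterial
stenosis"; Level 3 disease-context-dependent) and carry the
`<Object, Sub-Object, Attribute, Value>` descriptor scheme, which makes a
property (`<hypertension, true>`), a qualitative statement
(`<blood, pressure, high>`) and a quantitative measurement
(`<blood, pressure, 180 mmHg>`) interoperable representations of one
state.

The package is aimed at biomedical knowledge engineers: it provides the
data model, the chain-inclusion matcher and is-a inference, core-chain
extraction, chain traversal, the three-form interoperability layer,
exact-string-match mapping to external vocabularies (HPO/PATO/MeSH/SNOMED
style), lossless Turtle/RDF serialization with a nine-pattern query layer,
packaged worked-example fixtures, a synthetic-ontology generator with
planted ground truth, and a CLI.

## Worked example

```r
library(riverflow)

o <- fixture_diabetes()          # the printed diabetes family
infer_isa_hierarchy(o)
#> <isa_result> 3 pair(s), 3 in reduction, 0 equivalence(s), 0 discrepancy(ies)
#>   diabetes_caused_blindness subDiseaseOf diabetes
#>   steroid_diabetes subDiseaseOf diabetes
#>   type_I_diabetes subDiseaseOf diabetes
```

The three subtypes are recognized as subclasses of diabetes purely from
their chains: each of them contains the diabetes chain (steroid diabetes
through an intermediate unknown node, handled by path-mode edge matching).
No pair is reversed — the 4-state Type-I chain cannot be injected into the
2-state diabetes chain.

```r
core_causal_chain("diabetes", o)
#> <causal_graph> 2 state(s), 1 link(s)
#>   deficiency_of_insulin -> elevated_glucose_in_blood
```

The extracted core chain is exactly the part shared by every subclass.

```r
run_query("core_states", list(disease = "type_I_diabetes"), o)
#> [1] "deficiency_of_insulin"
#> [2] "destruction_of_pancreatic_beta_cells"
#> [3] "elevated_glucose_in_blood"
#> [4] "lack_of_insulin_in_blood"
```

Query `core_states` (pattern d3) aggregates the disease's own core states
with those inherited from its super-diseases, mirroring the published
SPARQL pattern over the Turtle serialization (`to_rdf()` /
`write_turtle()`; the nine `.rq` pattern texts ship under `inst/sparql/`).

```r
rules <- fixture_interop_rules()
to_property(quantize(quantitative_form("blood", "pressure", 180, "mmHg"),
                     rules), rules)
#> <hypertension, true>
```

A clinical measurement normalizes through the qualitative form
(`<blood, pressure, high>`, cut-point 140 mmHg from the user-supplied rule
table) to the property form used in disease definitions.

## Command line

```sh
Rscript -e 'riverflow::cli_dispatch(commandArgs(TRUE))' \
    query core_states --fixture diabetes --disease type_I_diabetes
```

(or use the launcher installed at `inst/cli/riverflow`). Subcommands:
`validate`, `convert`, `query`, `infer-isa`, `core-chain`, `trace`,
`diseases-of`, `interop`, `map-terms`, `summarize-mapping`, `generate`,
`fixtures`. Exit codes: 0 success, 1 validation findings, 2 usage error.

## Vignette

`vignettes/river-flow-model.Rmd` documents the model, the matching
semantics and their design choices, the synthetic generator's stated
world, and known limitations.
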