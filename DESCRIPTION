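Package: riverflow
Title: River Flow Model of Diseases as Causal Chains of Abnormal States
Version: 0.1.0
Authors@R:
    person("Open", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the River Flow Model (RFM) of diseases, in which a
    disease is constituted of causal chains of abnormal states. Provides
    domain types for abnormal states (with the three-layer generic /
    object-dependent / context-dependent hierarchy and the O/SO/A/V
    descriptor scheme), global causal links and disease definitions;
    subsumption-aware causal-chain inclusion matching; inference of the
    disease is-a hierarchy from chain inclusion; core-causal-chain
    extraction; chain aggregation over super-diseases and upstream /
    downstream traversal; a property-attribute interoperable representation
    of abnormal states (quantitative, qualitative and property forms with
    rule-table conversion); exact-string-match mapping of states to external
    vocabularies; lossless serialization of an ontology to a Turtle/RDF
    linked-data model with a query layer answering nine standard query
    patterns; packaged worked-example fixtures and a synthetic-ontology
    generator with planted ground truth; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
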