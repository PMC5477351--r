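RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDFS_LABEL <- "http://www.w3.org/2000/01/rdf-schema#label"

#' Vocabulary for the causal-chain linked-data model
#'
#' The published model types every abnormal state as `Abnormal_State` and
#' every disease as `Disease`; causal relations are the inverse pair
#' `hasCause`/`hasResult` (with `hasProbableCause`/`hasProbableResult` for
#' probable links), definitions use `hasCoreState`/`hasDerivedState`, and
#' the two hierarchies use `subDiseaseOf`/`subStateOf` (instance-level
#' properties rather than `rdfs:subClassOf`, because states and diseases
#' are published as RDF resources). Only the prefix is fixed by convention
#' ("dont:"); the namespace IRI is configurable.
#'
#' Descriptors that the published model does not define (levels, O/SO/A/V,
#' unknown flags, external refs, clinical area, AND-branch annotations)
#' are carried in a separate extension namespace so that serialization is
#' lossless.
#'
#' @param namespace Namespace IRI for the main vocabulary and for entity
#'   resources.
#' @param prefix Prefix rendered in Turtle output.
#' @param ext_namespace Namespace IRI for extension predicates.
#' @param cause_direction `"effect_to_cause"` (default: a `hasCause` arc
#'   runs from an effect state to its cause, i.e. "this state has cause X")
#'   or `"cause_to_effect"`. The inverse `hasResult` arc is always
#'   materialized the opposite way.
#' @return A `rfm_vocabulary` list with `$ns`, `$ext`, `$prefix`,
#'   `$cause_direction` and the term IRIs under `$terms`.
#' @export
rfm_vocabulary <- function(namespace = "http://purl.example.org/diseasechain/",
                           prefix = "dont",
                           ext_namespace = paste0(namespace, "ext/"),
                           cause_direction = c("effect_to_cause",
                                               "cause_to_effect")) {
  cause_direction <- match.arg(cause_direction)
  term <- function(x) paste0(namespace, x)
  ext <- function(x) paste0(ext_namespace, x)
  structure(list(
    ns = namespace, ext = ext_namespace, prefix = prefix,
    cause_direction = cause_direction,
    terms = list(
      Disease = term("Disease"),
      Abnormal_State = term("Abnormal_State"),
      hasCause = term("hasCause"),
      hasResult = term("hasResult"),
      hasProbableCause = term("hasProbableCause"),
      hasProbableResult = term("hasProbableResult"),
      hasCoreState = term("hasCoreState"),
      hasDerivedState = term("hasDerivedState"),
      subDiseaseOf = term("subDiseaseOf"),
      subStateOf = term("subStateOf")
    ),
    ext_terms = list(
      level = ext("level"),
      object = ext("object"),
      subObject = ext("subObject"),
      attribute = ext("attribute"),
      value = ext("value"),
      isUnknown = ext("isUnknown"),
      externalRef = ext("externalRef"),
      area = ext("area"),
      andBranch = ext("andBranch")
    )
  ), class = "rfm_vocabulary")
}

entity_iri <- function(id, vocab) paste0(vocab$ns, id)

iri_to_id <- function(iri, vocab) {
  ifelse(startsWith(iri, vocab$ns), substring(iri, nchar(vocab$ns) + 1L), iri)
}
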