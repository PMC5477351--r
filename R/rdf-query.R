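# ---- query layer: the nine published query patterns ---------------------

QUERY_NAMES <- c(all_states = "a1", causes_of = "a2", general_chain = "a3",
                 all_diseases = "d1", super_diseases = "d2",
                 core_states = "d3", derived_states = "d4",
                 definition_states = "d5", definition_links = "d6")

#' SPARQL text of one of the nine query patterns
#'
#' Returns the query exactly as shipped under `inst/sparql/` (placeholders
#' `<abn_id>` / `<dis_id>` substituted with the resource IRI when an id is
#' given), adjusted to the vocabulary's namespace and cause-direction
#' convention.
#'
#' @param name Query name, see [run_query()].
#' @param id State or disease id to substitute, or `NULL` to keep the
#'   placeholder.
#' @param vocab A [rfm_vocabulary()].
#' @return Single SPARQL string.
#' @export
sparql_pattern <- function(name, id = NULL, vocab = rfm_vocabulary()) {
  name <- match.arg(name, names(QUERY_NAMES))
  p <- vocab$prefix
  prologue <- sprintf(
    "PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>\nPREFIX %s: <%s>\n",
    p, vocab$ns)
  fwd <- vocab$cause_direction == "effect_to_cause"
  causes_pat <- if (fwd) sprintf("<abn_id> %s:hasCause ?cause", p)
                else sprintf("?cause %s:hasCause <abn_id>", p)
  body <- switch(
    name,
    all_states = sprintf("SELECT ?state WHERE { ?state rdf:type %s:Abnormal_State . }", p),
    causes_of = sprintf("SELECT ?cause WHERE { %s . }", causes_pat),
    general_chain = sprintf(
      "SELECT ?state WHERE { <abn_id> (%s:hasCause|%s:hasResult)* ?state . }",
      p, p),
    all_diseases = sprintf("SELECT ?disease WHERE { ?disease rdf:type %s:Disease . }", p),
    super_diseases = sprintf(
      "SELECT ?super WHERE { <dis_id> %s:subDiseaseOf+ ?super . }", p),
    core_states = sprintf(
      "SELECT ?state WHERE { <dis_id> %s:subDiseaseOf* ?d . ?d %s:hasCoreState ?state . }",
      p, p),
    derived_states = sprintf(
      "SELECT ?state WHERE { <dis_id> %s:subDiseaseOf* ?d . ?d %s:hasDerivedState ?state . }",
      p, p),
    definition_states = sprintf(
      "SELECT ?state WHERE { <dis_id> %s:subDiseaseOf* ?d . ?d (%s:hasCoreState|%s:hasDerivedState) ?state . }",
      p, p, p),
    definition_links = sprintf(paste0(
      "SELECT ?s ?p ?o WHERE { <dis_id> %s:subDiseaseOf* ?d1 . ",
      "?d1 (%s:hasCoreState|%s:hasDerivedState) ?s . ",
      "<dis_id> %s:subDiseaseOf* ?d2 . ",
      "?d2 (%s:hasCoreState|%s:hasDerivedState) ?o . ?s ?p ?o . ",
      "FILTER (?p IN (%s:hasCause, %s:hasResult, %s:hasProbableCause, %s:hasProbableResult)) }"),
      p, p, p, p, p, p, p, p, p, p))
  text <- paste0(prologue, body, "\n")
  if (!is.null(id)) {
    iri <- sprintf("<%s>", entity_iri(id, vocab))
    text <- gsub("<abn_id>", iri, text, fixed = TRUE)
    text <- gsub("<dis_id>", iri, text, fixed = TRUE)
  }
  text
}

#' Run one of the nine query patterns against an ontology
#'
#' Answers the standard query set of the linked-data model directly over
#' the in-memory ontology; for every name the result set equals executing
#' the corresponding SPARQL text (see [sparql_pattern()]) over the Turtle
#' serialization with a conformant engine.
#'
#' * `all_states` (a1), `all_diseases` (d1): every resource of the type.
#' * `causes_of` (a2): all `hasCause` targets of a state.
#' * `general_chain` (a3): the reflexive-transitive closure over
#'   `hasCause`/`hasResult` from the seed state, i.e. the general chain
#'   through it. (Probable arcs use distinct predicates and are not part
#'   of this pattern.)
#' * `super_diseases` (d2): transitive `subDiseaseOf` ancestors.
#' * `core_states` (d3) / `derived_states` (d4): own-plus-inherited sets,
#'   aggregated over super-diseases.
#' * `definition_states` (d5): d3 union d4.
#' * `definition_links` (d6): every causal arc, certain or probable, whose
#'   both end states lie in the d5 set; returned as arc rows
#'   (subject, predicate, object ids).
#'
#' @param name Query name (one of the nine above).
#' @param args Named list; `state` for a2/a3, `disease` for d2-d6.
#' @param ontology A `disease_ontology`.
#' @param vocab Vocabulary, used for the arc direction and predicate names
#'   of `definition_links`.
#' @return Sorted character vector of ids, or for `definition_links` a
#'   data.frame with columns `subject`, `predicate`, `object`.
#' @export
run_query <- function(name, args = list(), ontology,
                      vocab = rfm_vocabulary()) {
  name <- match.arg(name, names(QUERY_NAMES))
  need <- function(key) {
    if (is.null(args[[key]]))
      rf_stop(sprintf("query '%s' needs argument '%s'", name, key),
              "riverflow_argument_error")
    args[[key]]
  }
  certain <- ontology$links[!ontology$links$probable, , drop = FALSE]
  switch(
    name,
    all_states = sort(names(ontology$states)),
    all_diseases = sort(names(ontology$diseases)),
    causes_of = {
      s <- need("state"); require_state(s, ontology)
      sort(unique(certain$cause[certain$effect == s]))
    },
    general_chain = {
      s <- need("state"); require_state(s, ontology)
      und <- list()
      for (i in seq_len(nrow(certain))) {
        a <- certain$cause[i]; b <- certain$effect[i]
        und[[a]] <- c(und[[a]], b); und[[b]] <- c(und[[b]], a)
      }
      sort(reach(s, und))
    },
    super_diseases = {
      d <- need("disease"); require_disease(d, ontology)
      sort(setdiff(reach(d, disease_super_adj(ontology)), d))
    },
    core_states = effective_states(need("disease"), "core", ontology),
    derived_states = effective_states(need("disease"), "derived", ontology),
    definition_states = effective_states(need("disease"), "all", ontology),
    definition_links = {
      d <- need("disease")
      states <- effective_states(d, "all", ontology)
      lk <- ontology$links
      lk <- lk[lk$cause %in% states & lk$effect %in% states, , drop = FALSE]
      fwd <- vocab$cause_direction == "effect_to_cause"
      pc <- ifelse(lk$probable, "hasProbableCause", "hasCause")
      pr <- ifelse(lk$probable, "hasProbableResult", "hasResult")
      out <- if (fwd)
        data.frame(subject = c(lk$effect, lk$cause),
                   predicate = c(pc, pr),
                   object = c(lk$cause, lk$effect),
                   stringsAsFactors = FALSE)
      else
        data.frame(subject = c(lk$cause, lk$effect),
                   predicate = c(pc, pr),
                   object = c(lk$effect, lk$cause),
                   stringsAsFactors = FALSE)
      out <- out[order(out$subject, out$predicate, out$object), ,
                 drop = FALSE]
      rownames(out) <- NULL
      out
    })
}
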