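# ---- ontology -> RDF triples -> Turtle ----------------------------------

triples_df <- function(subject = character(), predicate = character(),
                       object = character(), object_type = character()) {
  data.frame(subject = subject, predicate = predicate, object = object,
             object_type = object_type, stringsAsFactors = FALSE)
}

sort_triples <- function(tr) {
  tr <- tr[!duplicated(tr), , drop = FALSE]
  tr <- tr[order(tr$subject, tr$predicate, tr$object_type, tr$object), ,
           drop = FALSE]
  rownames(tr) <- NULL
  tr
}

#' Convert a disease ontology to RDF triples
#'
#' Emits, per state: a type arc, a label arc (when labelled), `subStateOf`
#' arcs, and extension arcs for non-default descriptors (level other than
#' 1, O/SO/A/V values, the unknown flag, external refs). Per disease: a
#' type arc, label, `subDiseaseOf` arcs and `hasCoreState` /
#' `hasDerivedState` arcs to its OWN (non-inherited) state sets - inherited
#' states are recovered at query time by aggregating over super-diseases.
#' Per causal link both members of the inverse pair are materialized
#' (`hasCause` and `hasResult`, or the probable variants), under the
#' direction convention of `vocab`. Side-channel triples preserved by
#' [from_rdf()] are re-emitted verbatim.
#'
#' @param ontology A valid `disease_ontology`; an invalid one is refused
#'   with the validation report attached to the error.
#' @param vocab A [rfm_vocabulary()].
#' @return A sorted triple data.frame (columns `subject`, `predicate`,
#'   `object`, `object_type` with type `"iri"` or `"literal"`).
#' @export
to_rdf <- function(ontology, vocab = rfm_vocabulary()) {
  report <- validate_ontology(ontology)
  if (nrow(report))
    rf_stop(sprintf("refusing to serialize an invalid ontology (%d finding(s)); see the 'report' field",
                    nrow(report)), "riverflow_validation_error",
            report = report)
  v <- vocab$terms; e <- vocab$ext_terms
  s_ <- character(); p_ <- character(); o_ <- character(); t_ <- character()
  emit <- function(s, p, o, t) {
    s_ <<- c(s_, s); p_ <<- c(p_, p); o_ <<- c(o_, o); t_ <<- c(t_, t)
  }
  for (st in ontology$states) {
    iri <- entity_iri(st$id, vocab)
    emit(iri, RDF_TYPE, v$Abnormal_State, "iri")
    if (!is.na(st$label)) emit(iri, RDFS_LABEL, st$label, "literal")
    for (p in st$parents) emit(iri, v$subStateOf, entity_iri(p, vocab), "iri")
    if (st$level != 1L) emit(iri, e$level, as.character(st$level), "literal")
    if (!is.na(st$object)) emit(iri, e$object, st$object, "literal")
    if (!is.na(st$sub_object)) emit(iri, e$subObject, st$sub_object, "literal")
    if (!is.na(st$attribute)) emit(iri, e$attribute, st$attribute, "literal")
    if (!is.na(st$value)) emit(iri, e$value, st$value, "literal")
    if (st$is_unknown) emit(iri, e$isUnknown, "true", "literal")
    if (length(st$external_refs))
      for (r in names(st$external_refs))
        for (x in st$external_refs[[r]])
          emit(iri, e$externalRef, paste0(r, "=", x), "literal")
  }
  for (d in ontology$diseases) {
    iri <- entity_iri(d$id, vocab)
    emit(iri, RDF_TYPE, v$Disease, "iri")
    if (!is.na(d$label)) emit(iri, RDFS_LABEL, d$label, "literal")
    for (s in d$supers) emit(iri, v$subDiseaseOf, entity_iri(s, vocab), "iri")
    for (s in d$core_states)
      emit(iri, v$hasCoreState, entity_iri(s, vocab), "iri")
    for (s in d$derived_states)
      emit(iri, v$hasDerivedState, entity_iri(s, vocab), "iri")
    if (!is.na(d$area)) emit(iri, e$area, d$area, "literal")
  }
  for (i in seq_len(nrow(ontology$links))) {
    cause <- entity_iri(ontology$links$cause[i], vocab)
    effect <- entity_iri(ontology$links$effect[i], vocab)
    prob <- ontology$links$probable[i]
    pc <- if (prob) v$hasProbableCause else v$hasCause
    pr <- if (prob) v$hasProbableResult else v$hasResult
    if (vocab$cause_direction == "effect_to_cause") {
      emit(effect, pc, cause, "iri")
      emit(cause, pr, effect, "iri")
    } else {
      emit(cause, pc, effect, "iri")
      emit(effect, pr, cause, "iri")
    }
  }
  branch <- attr(ontology, "branch_mode")
  if (!is.null(branch))
    for (n in names(branch)[branch == "AND"])
      emit(entity_iri(n, vocab), e$andBranch, "true", "literal")
  extra <- attr(ontology, "extra_triples")
  tr <- triples_df(s_, p_, o_, t_)
  if (!is.null(extra) && nrow(extra)) tr <- rbind(tr, extra)
  sort_triples(tr)
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\r", "\\r", x, fixed = TRUE)
}

compact_iri <- function(iri, prefixes) {
  for (p in names(prefixes)) {
    ns <- prefixes[[p]]
    hit <- startsWith(iri, ns)
    local <- substring(iri, nchar(ns) + 1L)
    ok <- hit & grepl("^[A-Za-z0-9_.-]*$", local) & !grepl("^\\.|\\.$", local)
    if (any(ok)) iri[ok] <- paste0(p, ":", local[ok])
  }
  need <- !grepl("^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*$", iri) |
    grepl("^https?:", iri)
  iri[need] <- paste0("<", iri[need], ">")
  iri
}

#' Serialize triples as Turtle
#'
#' One statement per line, subjects/predicates/objects already sorted by
#' [to_rdf()], so output is byte-stable for a fixed ontology.
#'
#' @param triples Triple data.frame from [to_rdf()].
#' @param path Output file, or `NULL` to return the text.
#' @param vocab The [rfm_vocabulary()] used, for prefix declarations.
#' @return `path` invisibly, or a single Turtle string when `path` is
#'   `NULL`.
#' @export
write_turtle <- function(triples, path = NULL, vocab = rfm_vocabulary()) {
  prefixes <- c(
    stats::setNames(list(vocab$ns, vocab$ext), c(vocab$prefix, "ext")),
    list(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
         rdfs = "http://www.w3.org/2000/01/rdf-schema#"))
  header <- sprintf("@prefix %s: <%s> .", names(prefixes),
                    unlist(prefixes))
  tr <- sort_triples(triples)
  obj <- ifelse(tr$object_type == "literal",
                paste0('"', escape_literal(tr$object), '"'),
                compact_iri(tr$object, prefixes))
  lines <- c(header, "",
             sprintf("%s %s %s .", compact_iri(tr$subject, prefixes),
                     compact_iri(tr$predicate, prefixes), obj))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(text, con, eos = NULL)
  invisible(path)
}
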