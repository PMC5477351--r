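# ---- Turtle subset reader and RDF -> ontology ---------------------------

# Tokenize one Turtle document. Supported subset: @prefix declarations,
# triples with `;` (predicate) and `,` (object) continuation, <IRI> terms,
# prefixed names, and double-quoted literals with \\ \" \n \r escapes and
# optional datatype/language tags (dropped). Comments (# to end of line,
# outside literals) are dropped. Statement punctuation may be attached to
# the preceding token or stand alone.
turtle_tokens <- function(text) {
  rx <- paste0('<[^>]*>',                                   # IRI
               '|"(?:\\\\.|[^"\\\\])*"(?:\\^\\^\\S+|@[A-Za-z0-9-]+)?', # literal
               '|[^ \t\r\n]+')                              # bare token
  out <- character()
  for (line in strsplit(text, "\n", fixed = TRUE)[[1]]) {
    m <- regmatches(line, gregexpr(rx, line, perl = TRUE))[[1]]
    if (!length(m)) next
    quoted <- startsWith(m, '"') | startsWith(m, "<")
    cm <- which(startsWith(m, "#") & !quoted)
    if (length(cm)) {
      if (cm[1] == 1L) next
      m <- m[seq_len(cm[1] - 1L)]
      quoted <- quoted[seq_len(cm[1] - 1L)]
    }
    # drop datatype / language tags from literals
    lit <- startsWith(m, '"')
    m[lit] <- sub('(^"(?:\\\\.|[^"\\\\])*")(?:\\^\\^\\S+|@[A-Za-z0-9-]+)?$',
                  "\\1", m[lit], perl = TRUE)
    # detach trailing statement punctuation from bare tokens
    toks <- character()
    for (k in seq_along(m)) {
      t <- m[k]
      if (quoted[k]) { toks <- c(toks, t); next }
      tail_punct <- character()
      while (nchar(t) > 1L && substr(t, nchar(t), nchar(t)) %in% c(".", ";", ",")) {
        tail_punct <- c(substr(t, nchar(t), nchar(t)), tail_punct)
        t <- substr(t, 1, nchar(t) - 1L)
      }
      toks <- c(toks, t, tail_punct)
    }
    out <- c(out, toks)
  }
  out
}

unescape_literal <- function(x) {
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub('\\"', '"', x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

resolve_term <- function(tok, prefixes) {
  if (startsWith(tok, "<"))
    return(list(value = substr(tok, 2, nchar(tok) - 1L), type = "iri"))
  if (startsWith(tok, '"'))
    return(list(value = unescape_literal(substr(tok, 2, nchar(tok) - 1L)),
                type = "literal"))
  if (tok == "a") return(list(value = RDF_TYPE, type = "iri"))
  colon <- regexpr(":", tok, fixed = TRUE)
  if (colon > 0) {
    p <- substr(tok, 1, colon - 1L)
    if (p %in% names(prefixes))
      return(list(value = paste0(prefixes[[p]],
                                 substr(tok, colon + 1L, nchar(tok))),
                  type = "iri"))
  }
  rf_stop(sprintf("cannot resolve term '%s'", tok), "riverflow_format_error")
}

#' Parse a Turtle document
#'
#' Accepts the subset emitted by [write_turtle()] plus `;`/`,`
#' continuations, comments and the `a` type shorthand.
#'
#' @param x Path to a Turtle file, or a length-1 string of Turtle text.
#' @return A triple data.frame as produced by [to_rdf()].
#' @export
read_turtle <- function(x) {
  text <- if (length(x) == 1L && !grepl("[\n@]", x) && file.exists(x))
    paste(readLines(x, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  else paste(x, collapse = "\n")
  toks <- turtle_tokens(text)
  prefixes <- list()
  s_ <- character(); p_ <- character(); o_ <- character(); t_ <- character()
  i <- 1L; n <- length(toks)
  while (i <= n) {
    if (toks[i] %in% c("@prefix", "PREFIX")) {
      p <- sub(":$", "", toks[i + 1L])
      iri <- toks[i + 2L]
      prefixes[[p]] <- substr(iri, 2, nchar(iri) - 1L)
      i <- i + 3L
      if (i <= n && toks[i] == ".") i <- i + 1L
      next
    }
    subj <- resolve_term(toks[i], prefixes)$value
    i <- i + 1L
    repeat {
      pred <- resolve_term(toks[i], prefixes)$value
      i <- i + 1L
      repeat {
        obj <- resolve_term(toks[i], prefixes)
        i <- i + 1L
        s_ <- c(s_, subj); p_ <- c(p_, pred)
        o_ <- c(o_, obj$value); t_ <- c(t_, obj$type)
        if (i > n || toks[i] != ",") break
        i <- i + 1L
      }
      if (i > n || toks[i] != ";") break
      i <- i + 1L
      if (i <= n && toks[i] == ".") break  # trailing ';' before '.'
    }
    if (i <= n && toks[i] == ".") i <- i + 1L
    else if (i <= n)
      rf_stop(sprintf("expected '.' near token %d ('%s')", i, toks[i]),
              "riverflow_format_error")
  }
  sort_triples(triples_df(s_, p_, o_, t_))
}

#' Reconstruct a disease ontology from RDF triples
#'
#' Inverse of [to_rdf()]: typed `Abnormal_State` resources become states,
#' typed `Disease` resources diseases, and causal arcs become global links
#' (a link is reconstructed when either member of its inverse pair is
#' present; the mirror is implied). Triples using predicates outside the
#' vocabulary are preserved on the result as `attr(, "extra_triples")` and
#' re-emitted verbatim by [to_rdf()]. Arc triples whose endpoints are not
#' typed resources are reported in `attr(, "findings")` as
#' dangling-reference findings.
#'
#' @param triples Triple data.frame (e.g. from [read_turtle()]).
#' @param vocab A [rfm_vocabulary()].
#' @return A `disease_ontology`.
#' @export
from_rdf <- function(triples, vocab = rfm_vocabulary()) {
  v <- vocab$terms; e <- vocab$ext_terms
  tr <- triples
  type_tr <- tr[tr$predicate == RDF_TYPE, , drop = FALSE]
  state_iris <- type_tr$subject[type_tr$object == v$Abnormal_State]
  disease_iris <- type_tr$subject[type_tr$object == v$Disease]
  both <- intersect(state_iris, disease_iris)
  if (length(both))
    rf_stop(sprintf("resource(s) typed both Disease and Abnormal_State: %s",
                    paste(iri_to_id(both, vocab), collapse = ", ")),
            "riverflow_format_error")

  by_subj <- split(tr[c("predicate", "object")], tr$subject)
  of <- function(iri, pred) {
    d <- by_subj[[iri]]
    if (is.null(d)) character() else d$object[d$predicate == pred]
  }
  one_of <- function(iri, pred) {
    x <- of(iri, pred)
    if (length(x)) x[1] else NA_character_
  }

  states <- lapply(sort(state_iris), function(iri) {
    refs_raw <- sort(of(iri, e$externalRef))
    refs <- parse_refs(if (length(refs_raw)) join_multi(refs_raw) else "")
    lvl <- one_of(iri, e$level)
    abnormal_state(
      id = iri_to_id(iri, vocab),
      label = one_of(iri, RDFS_LABEL),
      object = one_of(iri, e$object),
      sub_object = one_of(iri, e$subObject),
      attribute = one_of(iri, e$attribute),
      value = one_of(iri, e$value),
      level = if (is.na(lvl)) 1L else as.integer(lvl),
      parents = sort(iri_to_id(of(iri, v$subStateOf), vocab)),
      is_unknown = identical(one_of(iri, e$isUnknown), "true"),
      external_refs = refs)
  })
  diseases <- lapply(sort(disease_iris), function(iri) {
    disease(
      id = iri_to_id(iri, vocab),
      label = one_of(iri, RDFS_LABEL),
      core_states = sort(iri_to_id(of(iri, v$hasCoreState), vocab)),
      derived_states = sort(iri_to_id(of(iri, v$hasDerivedState), vocab)),
      supers = sort(iri_to_id(of(iri, v$subDiseaseOf), vocab)),
      area = one_of(iri, e$area))
  })

  # causal links: accept either member of each inverse pair
  fwd <- vocab$cause_direction == "effect_to_cause"
  collect <- function(pred, subj_is_effect, probable) {
    sel <- tr$predicate == pred
    if (!any(sel)) return(causal_links())
    s <- iri_to_id(tr$subject[sel], vocab)
    o <- iri_to_id(tr$object[sel], vocab)
    if (subj_is_effect) causal_links(o, s, probable)
    else causal_links(s, o, probable)
  }
  links <- rbind(
    collect(v$hasCause, subj_is_effect = fwd, probable = FALSE),
    collect(v$hasResult, subj_is_effect = !fwd, probable = FALSE),
    collect(v$hasProbableCause, subj_is_effect = fwd, probable = TRUE),
    collect(v$hasProbableResult, subj_is_effect = !fwd, probable = TRUE))
  links <- normalize_links(links)

  known_preds <- c(RDF_TYPE, RDFS_LABEL, unlist(v), unlist(e))
  extra <- tr[!tr$predicate %in% known_preds, , drop = FALSE]

  # dangling arcs: vocabulary arcs touching untyped resources
  typed <- c(state_iris, disease_iris)
  fl_type <- character(); fl_ent <- character(); fl_det <- character()
  arc_preds <- unlist(v[c("hasCause", "hasResult", "hasProbableCause",
                          "hasProbableResult", "hasCoreState",
                          "hasDerivedState", "subDiseaseOf", "subStateOf")])
  arcs <- tr[tr$predicate %in% arc_preds, , drop = FALSE]
  for (i in seq_len(nrow(arcs))) {
    for (side in c("subject", "object")) {
      iri <- arcs[[side]][i]
      if (!iri %in% typed) {
        fl_type <- c(fl_type, "dangling_reference")
        fl_ent <- c(fl_ent, iri_to_id(iri, vocab))
        fl_det <- c(fl_det, sprintf("untyped %s of %s arc", side,
                                    iri_to_id(arcs$predicate[i], vocab)))
      }
    }
  }

  onto <- disease_ontology(states, diseases, links)
  branch_subj <- tr$subject[tr$predicate == e$andBranch & tr$object == "true"]
  if (length(branch_subj))
    attr(onto, "branch_mode") <- stats::setNames(
      rep("AND", length(branch_subj)),
      iri_to_id(sort(branch_subj), vocab))
  if (nrow(extra)) attr(onto, "extra_triples") <- sort_triples(extra)
  attr(onto, "findings") <- validation_report(fl_type, fl_ent, fl_det)
  onto
}
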