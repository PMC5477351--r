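#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

rf_stop <- function(msg, class = "riverflow_error", ...) {
  stop(structure(class = c(class, "riverflow_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

chr1_or_na <- function(x, what) {
  if (is.null(x) || length(x) == 0L || all(is.na(x))) return(NA_character_)
  if (!is.character(x) || length(x) != 1L)
    rf_stop(sprintf("'%s' must be a single string or NA", what))
  x
}

#' Create an abnormal state
#'
#' An abnormal state (clinical disorder) is a node of disease causal chains.
#' It carries the O/SO/A/V descriptor scheme (Object, Sub-Object, Attribute,
#' Value), a level in the three-layer model, is-a parents (`subStateOf`) and
#' optional mappings to external vocabularies.
#'
#' Levels follow the three-layer model: Level 1 states are generic and
#' object-independent (e.g. "small in area") and must not carry an Object;
#' Level 2 states depend on a structural entity (e.g. "arterial stenosis");
#' Level 3 states are disease-context-dependent. Unknown nodes are
#' placeholders for unidentified causes or elided chain segments and carry
#' no descriptors.
#'
#' @param id Opaque, IRI-safe identifier (case-sensitive).
#' @param label Human-readable name; defaults to the id.
#' @param object,sub_object,attribute,value O/SO/A/V descriptors, each a
#'   single string or `NA` when absent.
#' @param level Integer 1, 2 or 3 (default 1, the generic layer).
#' @param parents Character vector of parent state ids (`subStateOf`).
#' @param is_unknown Logical; `TRUE` marks an unknown node.
#' @param external_refs Named list, resource name -> character vector of
#'   external ids (e.g. `list(HPO = "HP:0100749")`).
#' @return An object of class `abnormal_state`.
#' @examples
#' abnormal_state("small_in_area", "small in area", level = 1)
#' @export
abnormal_state <- function(id, label = id, object = NA, sub_object = NA,
                           attribute = NA, value = NA, level = 1L,
                           parents = character(), is_unknown = FALSE,
                           external_refs = list()) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    rf_stop("state id must be a non-empty string", "riverflow_id_error")
  level <- as.integer(level)
  if (length(level) != 1L || is.na(level) || !level %in% 1:3)
    rf_stop(sprintf("state '%s': level must be 1, 2 or 3", id))
  if (is.null(parents)) parents <- character()
  structure(list(
    id = id,
    label = chr1_or_na(label, "label"),
    object = chr1_or_na(object, "object"),
    sub_object = chr1_or_na(sub_object, "sub_object"),
    attribute = chr1_or_na(attribute, "attribute"),
    value = chr1_or_na(value, "value"),
    level = level,
    parents = as.character(parents),
    is_unknown = isTRUE(is_unknown),
    external_refs = external_refs
  ), class = "abnormal_state")
}

#' Create a disease definition
#'
#' A disease, under the River Flow Model, is constituted of one or more
#' causal chains of abnormal states. A definition names the states of its
#' core causal chain (appearing in every patient) and of its derived chains
#' (possible causes upstream, possible symptoms downstream), plus declared
#' `subDiseaseOf` links. The disease's chain graph is the subgraph of the
#' global causal-link set induced on these states (aggregated over
#' super-diseases).
#'
#' @param id Opaque identifier.
#' @param label Display name.
#' @param core_states,derived_states Character vectors of state ids; order
#'   is preserved for deterministic serialization but carries no semantics.
#'   The two sets must be disjoint.
#' @param supers Character vector of super-disease ids (`subDiseaseOf`).
#' @param area Clinical division tag or `NA`.
#' @return An object of class `disease`.
#' @export
disease <- function(id, label = id, core_states = character(),
                    derived_states = character(), supers = character(),
                    area = NA) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    rf_stop("disease id must be a non-empty string", "riverflow_id_error")
  structure(list(
    id = id,
    label = chr1_or_na(label, "label"),
    core_states = as.character(core_states %||% character()),
    derived_states = as.character(derived_states %||% character()),
    supers = as.character(supers %||% character()),
    area = chr1_or_na(area, "area")
  ), class = "disease")
}

#' Build a table of causal links
#'
#' Causal links are global (not scoped to a disease): a link cause -> effect
#' asserts that the cause state can bring about the effect state anywhere in
#' the body. `probable` marks links published with the probable-cause
#' properties; probable links participate in every graph operation exactly
#' like certain links (probability semantics are out of scope), the flag is
#' only carried through and reported.
#'
#' @param cause,effect Character vectors of state ids (recycled to equal
#'   length).
#' @param probable Logical vector.
#' @return A data.frame with columns `cause`, `effect`, `probable`.
#' @export
causal_links <- function(cause = character(), effect = character(),
                         probable = FALSE) {
  n <- max(length(cause), length(effect))
  if (n == 0L)
    return(data.frame(cause = character(), effect = character(),
                      probable = logical(), stringsAsFactors = FALSE))
  data.frame(cause = rep_len(as.character(cause), n),
             effect = rep_len(as.character(effect), n),
             probable = rep_len(as.logical(probable), n),
             stringsAsFactors = FALSE)
}

empty_links <- function() causal_links()

# canonical ordering + dedup of a link table
normalize_links <- function(links) {
  links <- links[!duplicated(links[c("cause", "effect")]), , drop = FALSE]
  links <- links[order(links$cause, links$effect), , drop = FALSE]
  rownames(links) <- NULL
  links
}

#' Assemble a disease ontology
#'
#' The container for a full dataset: an index of abnormal states, an index
#' of disease definitions, and the global set of causal links. Referential
#' integrity and acyclicity of the two hierarchies are checked by
#' [validate_ontology()]; construction only indexes.
#'
#' @param states List of [abnormal_state()] objects.
#' @param diseases List of [disease()] objects.
#' @param links Link table from [causal_links()].
#' @return An object of class `disease_ontology` with named indexes
#'   `$states`, `$diseases` and the table `$links`.
#' @export
disease_ontology <- function(states = list(), diseases = list(),
                             links = causal_links()) {
  sid <- vapply(states, function(s) s$id, character(1))
  did <- vapply(diseases, function(d) d$id, character(1))
  if (anyDuplicated(sid))
    rf_stop(sprintf("duplicate state id(s): %s",
                    paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  if (anyDuplicated(did))
    rf_stop(sprintf("duplicate disease id(s): %s",
                    paste(unique(did[duplicated(did)]), collapse = ", ")))
  names(states) <- sid
  names(diseases) <- did
  if (any(links$cause == links$effect)) {
    bad <- links$cause[links$cause == links$effect]
    rf_stop(sprintf("self-loop causal link(s) rejected: %s",
                    paste(unique(bad), collapse = ", ")))
  }
  structure(list(states = states, diseases = diseases,
                 links = normalize_links(links)),
            class = "disease_ontology")
}

#' @export
print.disease_ontology <- function(x, ...) {
  cat(sprintf("<disease_ontology> %d states, %d diseases, %d causal links\n",
              length(x$states), length(x$diseases), nrow(x$links)))
  invisible(x)
}

#' @export
print.abnormal_state <- function(x, ...) {
  desc <- c(O = x$object, SO = x$sub_object, A = x$attribute, V = x$value)
  desc <- desc[!is.na(desc)]
  cat(sprintf("<abnormal_state> %s (L%d)%s%s\n", x$id, x$level,
              if (x$is_unknown) " [unknown]" else "",
              if (length(desc))
                paste0(" <", paste(sprintf("%s=%s", names(desc), desc),
                                   collapse = ", "), ">")
              else ""))
  invisible(x)
}

#' @export
print.disease <- function(x, ...) {
  cat(sprintf("<disease> %s: %d core, %d derived state(s)%s\n", x$id,
              length(x$core_states), length(x$derived_states),
              if (length(x$supers))
                paste0("; subDiseaseOf ", paste(x$supers, collapse = ", "))
              else ""))
  invisible(x)
}

#' Construct a causal graph
#'
#' A directed graph over a set of abnormal-state ids: the unit compared by
#' chain-inclusion matching. Nodes with several incoming causes default to
#' OR semantics (alternative causes); AND may be recorded per effect node as
#' an annotation only.
#'
#' @param states Character vector of state ids.
#' @param links Link table; every endpoint must be in `states`.
#' @param branch_mode Named character vector, effect-state id -> "AND" or
#'   "OR". Absent nodes default to OR.
#' @return An object of class `causal_graph`.
#' @export
causal_graph <- function(states = character(), links = causal_links(),
                         branch_mode = character()) {
  states <- sort(unique(as.character(states)))
  bad <- setdiff(unique(c(links$cause, links$effect)), states)
  if (length(bad))
    rf_stop(sprintf("link endpoint(s) outside the state set: %s",
                    paste(bad, collapse = ", ")))
  if (length(branch_mode)) {
    stopifnot(all(branch_mode %in% c("AND", "OR")),
              !is.null(names(branch_mode)))
  }
  structure(list(states = states, links = normalize_links(links),
                 branch_mode = branch_mode),
            class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("<causal_graph> %d state(s), %d link(s)\n",
              length(x$states), nrow(x$links)))
  if (nrow(x$links))
    cat(paste0("  ", x$links$cause, " -> ", x$links$effect,
               ifelse(x$links$probable, " (probable)", ""), "\n"), sep = "")
  invisible(x)
}

# adjacency list: effect ids keyed by cause id (or reverse)
adjacency <- function(links, reverse = FALSE) {
  from <- if (reverse) links$effect else links$cause
  to <- if (reverse) links$cause else links$effect
  split(to, factor(from, levels = unique(from)))
}

# set of ids reachable from seeds following `adj`; visited-set contract
# guarantees termination on cycles. Seeds included (reflexive closure).
reach <- function(seeds, adj, max_depth = Inf) {
  seen <- unique(seeds)
  frontier <- seen
  depth <- 0
  while (length(frontier) && depth < max_depth) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    if (!length(nxt)) break
    seen <- c(seen, nxt)
    frontier <- nxt
    depth <- depth + 1
  }
  seen
}

#' Model equality of two ontologies
#'
#' Field-wise comparison in which id-keyed collections and multi-valued
#' fields (parents, supers, external refs, link sets) compare as sets;
#' the stored order of core/derived states is ignored because it carries
#' no semantics.
#'
#' @param a,b `disease_ontology` objects.
#' @return `TRUE` or `FALSE`.
#' @export
ontology_equal <- function(a, b) {
  setequalc <- function(x, y) setequal(as.character(x), as.character(y))
  if (!setequalc(names(a$states), names(b$states))) return(FALSE)
  if (!setequalc(names(a$diseases), names(b$diseases))) return(FALSE)
  for (id in names(a$states)) {
    s <- a$states[[id]]; t <- b$states[[id]]
    if (!identical(s$label, t$label)) return(FALSE)
    for (f in c("object", "sub_object", "attribute", "value"))
      if (!identical(s[[f]], t[[f]])) return(FALSE)
    if (s$level != t$level || s$is_unknown != t$is_unknown) return(FALSE)
    if (!setequalc(s$parents, t$parents)) return(FALSE)
    er_s <- s$external_refs; er_t <- t$external_refs
    if (!setequalc(names(er_s) %||% character(),
                   names(er_t) %||% character())) return(FALSE)
    for (r in names(er_s) %||% character())
      if (!setequalc(er_s[[r]], er_t[[r]])) return(FALSE)
  }
  for (id in names(a$diseases)) {
    d <- a$diseases[[id]]; e <- b$diseases[[id]]
    if (!identical(d$label, e$label)) return(FALSE)
    if (!identical(d$area, e$area)) return(FALSE)
    if (!setequalc(d$core_states, e$core_states)) return(FALSE)
    if (!setequalc(d$derived_states, e$derived_states)) return(FALSE)
    if (!setequalc(d$supers, e$supers)) return(FALSE)
  }
  la <- normalize_links(a$links); lb <- normalize_links(b$links)
  isTRUE(all.equal(la, lb, check.attributes = FALSE))
}
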