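# ---- chain assembly and traversal ---------------------------------------

#' Aggregated state set of a disease
#'
#' A disease with declared super-diseases is defined against its supers'
#' chains as well as its own: when reading a definition the chains of every
#' transitive super-disease must be aggregated with the disease's own
#' states. `effective_states` returns that union for the requested set.
#'
#' @param disease Disease id.
#' @param which `"core"`, `"derived"` or `"all"` (core and derived,
#'   aggregated).
#' @param ontology A `disease_ontology`.
#' @return Sorted character vector of state ids.
#' @export
effective_states <- function(disease, which = c("all", "core", "derived"),
                             ontology) {
  which <- match.arg(which)
  require_disease(disease, ontology)
  lineage <- reach(disease, disease_super_adj(ontology))
  out <- character()
  for (d in lineage) {
    def <- ontology$diseases[[d]]
    if (is.null(def)) next  # dangling super: surfaced by validate_ontology
    if (which %in% c("core", "all")) out <- c(out, def$core_states)
    if (which %in% c("derived", "all")) out <- c(out, def$derived_states)
  }
  sort(unique(out))
}

induced_graph <- function(states, ontology) {
  links <- ontology$links
  keep <- links$cause %in% states & links$effect %in% states
  causal_graph(states, links[keep, , drop = FALSE])
}

#' Causal-chain graph of a disease
#'
#' The induced subgraph of the global causal-link set on the disease's
#' aggregated state set: a link belongs to a disease's chain exactly when
#' both of its end states are connected to the disease (directly or through
#' a super-disease).
#'
#' @inheritParams effective_states
#' @return A `causal_graph`.
#' @export
chain_graph <- function(disease, which = c("all", "core", "derived"),
                        ontology) {
  which <- match.arg(which)
  induced_graph(effective_states(disease, which, ontology), ontology)
}

#' The general causal graph
#'
#' All possible causal chains of abnormal states in the body: every state in
#' the ontology together with the full global link set, assembled bottom-up
#' from the authored disease definitions plus free links.
#'
#' @param ontology A `disease_ontology`.
#' @return A `causal_graph` over every state.
#' @export
general_graph <- function(ontology) {
  causal_graph(names(ontology$states), ontology$links)
}

closure_impl <- function(state, graph, reverse, max_depth) {
  if (!state %in% graph$states)
    rf_stop(sprintf("state '%s' is not in the graph", state),
            "riverflow_id_error")
  adj <- adjacency(graph$links, reverse = reverse)
  keep <- reach(state, adj, max_depth = max_depth)
  links <- graph$links
  sub <- links[links$cause %in% keep & links$effect %in% keep, , drop = FALSE]
  causal_graph(keep, sub, graph$branch_mode[names(graph$branch_mode) %in% keep])
}

#' Upstream / downstream closure from a state
#'
#' Traces a causal graph from a seed state towards causes (`upstream_closure`)
#' or towards effects (`downstream_closure`), the operation behind derived
#' causal chains: upstream chains imply possible causes of a disease,
#' downstream chains possible symptoms. A visited set guarantees termination
#' on cyclic graphs; the seed is always part of the result.
#'
#' @param state Seed state id; must be a node of `graph`.
#' @param graph A `causal_graph` (typically [general_graph()] output).
#' @param max_depth Maximum number of link-following steps, default
#'   unbounded.
#' @return The induced `causal_graph` on the reachable states.
#' @export
upstream_closure <- function(state, graph, max_depth = Inf) {
  closure_impl(state, graph, reverse = TRUE, max_depth = max_depth)
}

#' @rdname upstream_closure
#' @export
downstream_closure <- function(state, graph, max_depth = Inf) {
  closure_impl(state, graph, reverse = FALSE, max_depth = max_depth)
}

#' List diseases whose chains contain a state
#'
#' @param state State id.
#' @param ontology A `disease_ontology`.
#' @param include_state_descendants When `TRUE`, a disease also counts if
#'   its chain contains any `subStateOf`-descendant of `state`.
#' @return Sorted character vector of disease ids.
#' @export
diseases_containing <- function(state, ontology,
                                include_state_descendants = FALSE) {
  require_state(state, ontology)
  targets <- if (include_state_descendants)
    state_descendants(state, ontology) else state
  hits <- character()
  for (d in names(ontology$diseases)) {
    if (any(targets %in% effective_states(d, "all", ontology)))
      hits <- c(hits, d)
  }
  sort(hits)
}

#' Export a causal graph as edge-list TSV text
#'
#' @param graph A `causal_graph`.
#' @return Character vector of TSV lines (header, then one link per line;
#'   isolated states follow with an empty effect column).
#' @export
graph_as_tsv <- function(graph) {
  lines <- "cause\teffect\tprobable"
  if (nrow(graph$links))
    lines <- c(lines, sprintf("%s\t%s\t%s", graph$links$cause,
                              graph$links$effect,
                              tolower(graph$links$probable)))
  isolated <- setdiff(graph$states,
                      unique(c(graph$links$cause, graph$links$effect)))
  if (length(isolated))
    lines <- c(lines, sprintf("%s\t\t", sort(isolated)))
  lines
}

#' Export a causal graph in Graphviz DOT format
#'
#' Probable links are drawn dashed; unknown nodes (when `ontology` is
#' given) are drawn as boxes labelled "unknown".
#'
#' @param graph A `causal_graph`.
#' @param ontology Optional `disease_ontology` supplying labels.
#' @return Character vector of DOT lines.
#' @export
graph_as_dot <- function(graph, ontology = NULL) {
  esc <- function(x) gsub('"', '\\\\"', x)
  node_line <- function(id) {
    lab <- id; shape <- NULL
    if (!is.null(ontology) && id %in% names(ontology$states)) {
      s <- ontology$states[[id]]
      if (!is.na(s$label)) lab <- s$label
      if (s$is_unknown) { lab <- "unknown"; shape <- "box" }
    }
    sprintf('  "%s" [label="%s"%s];', esc(id), esc(lab),
            if (is.null(shape)) "" else sprintf(' shape=%s', shape))
  }
  lines <- c("digraph causal_chain {", "  rankdir=LR;",
             unname(vapply(graph$states, node_line, "")))
  if (nrow(graph$links))
    lines <- c(lines, sprintf('  "%s" -> "%s"%s;', esc(graph$links$cause),
                              esc(graph$links$effect),
                              ifelse(graph$links$probable,
                                     " [style=dashed]", "")))
  c(lines, "}")
}
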