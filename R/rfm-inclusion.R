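# ---- subsumption-aware chain inclusion (Definition-2 matching) ----------

link_keys <- function(links) paste(links$cause, links$effect, sep = "\r")

# reachability-with-at-least-one-step sets for every node of a graph
reach_plus <- function(graph) {
  adj <- adjacency(graph$links)
  out <- list()
  for (n in graph$states) {
    succ <- adj[[n]]
    out[[n]] <- if (length(succ)) reach(succ, adj) else character()
  }
  out
}

# shortest directed path from `from` to `to` (>=1 edge, from != to) as a
# link table; NULL when unreachable
bfs_path <- function(from, to, graph) {
  stopifnot(from != to)
  adj <- adjacency(graph$links)
  parent <- list()
  visited <- from
  frontier <- from
  while (length(frontier) && is.null(parent[[to]])) {
    nxt <- character()
    for (n in sort(frontier)) {
      for (m in sort(adj[[n]] %||% character())) {
        if (m %in% visited) next
        visited <- c(visited, m)
        parent[[m]] <- n
        nxt <- c(nxt, m)
      }
    }
    frontier <- nxt
  }
  if (is.null(parent[[to]])) return(NULL)
  nodes <- to
  while (nodes[1] != from) nodes <- c(parent[[nodes[1]]], nodes)
  keys <- link_keys(graph$links)
  idx <- match(paste(nodes[-length(nodes)], nodes[-1], sep = "\r"), keys)
  graph$links[idx, , drop = FALSE]
}

# per-state reflexive ancestor sets, computed once per ontology and
# passed through the matcher's hot path
ancestors_index <- function(ontology) {
  adj <- state_parent_adj(ontology)
  idx <- lapply(names(ontology$states), function(id) reach(id, adj))
  names(idx) <- names(ontology$states)
  idx
}

# candidate targets in B for node `a` of A: unknown nodes cover only
# unknown nodes; otherwise any equal-or-more-specific state of B
inclusion_candidates <- function(a, B, ontology, index = NULL) {
  sa <- require_state(a, ontology)
  if (is.null(index)) index <- ancestors_index(ontology)
  cand <- character()
  for (b in B$states) {
    sb <- require_state(b, ontology)
    ok <- if (sa$is_unknown) sb$is_unknown
          else !sb$is_unknown && a %in% index[[b]]
    if (ok) cand <- c(cand, b)
  }
  sort(cand)
}

#' Subsumption-aware inclusion of one causal graph in another
#'
#' Decides whether graph `A` is included in graph `B` in the sense used to
#' infer disease is-a relations: an injective map must send every state of
#' `A` to a state of `B` that is the same state or a `subStateOf`-descendant
#' (node inclusion "considering an is-a relation between the nodes, as well
#' as the sameness of nodes"), and every causal link of `A` to a direct link
#' (`mode = "strict"`) or a nonempty directed path (`mode = "path"`, the
#' default) between the mapped endpoints in `B`. Path mode exists because
#' authored subclass chains routinely elide intermediates. Unknown nodes
#' map only onto unknown nodes but are freely traversed inside edge paths.
#'
#' The search backtracks over candidate assignments in sorted-id order, so
#' the returned witness is reproducible bit-for-bit.
#'
#' @param A,B `causal_graph` objects whose states are known to `ontology`.
#' @param ontology A `disease_ontology` supplying the state hierarchy.
#' @param mode `"path"` or `"strict"`.
#' @param .index Precomputed [ancestors_index] (internal; callers testing
#'   many pairs against one ontology share it to avoid recomputation).
#' @return An `inclusion_witness` (list with injective `node_map`,
#'   `edge_map` from each A-link to its B-path, and `mode`), or `NULL`
#'   when no witness exists. The empty graph is vacuously included in any
#'   graph.
#' @export
chain_included_in <- function(A, B, ontology, mode = c("path", "strict"),
                              .index = NULL) {
  mode <- match.arg(mode)
  if (is.null(.index)) .index <- ancestors_index(ontology)
  nodes <- A$states  # already sorted
  cand <- lapply(nodes, inclusion_candidates, B = B, ontology = ontology,
                 index = .index)
  names(cand) <- nodes
  if (any(vapply(cand, length, 1L) == 0L) && length(nodes)) return(NULL)

  direct <- link_keys(B$links)
  rplus <- if (mode == "path") reach_plus(B) else NULL
  connected <- function(x, y) {
    if (mode == "strict") paste(x, y, sep = "\r") %in% direct
    else y %in% rplus[[x]]
  }
  # edges of A grouped for incremental checking
  a_links <- A$links
  assign <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  used <- character()

  consistent <- function(a, b) {
    # every A-edge between `a` and an assigned node must be realized in B
    for (i in seq_len(nrow(a_links))) {
      ca <- a_links$cause[i]; ef <- a_links$effect[i]
      if (ca == a && !is.na(assign[ef])) {
        if (!connected(b, assign[ef])) return(FALSE)
      } else if (ef == a && !is.na(assign[ca])) {
        if (!connected(assign[ca], b)) return(FALSE)
      } else if (ca == a && ef == a) {
        return(FALSE)  # self loops are rejected upstream anyway
      }
    }
    TRUE
  }

  solve <- function(k) {
    if (k > length(nodes)) return(TRUE)
    a <- nodes[k]
    for (b in cand[[a]]) {
      if (b %in% used) next
      if (!consistent(a, b)) next
      assign[a] <<- b
      used <<- c(used, b)
      if (solve(k + 1)) return(TRUE)
      assign[a] <<- NA_character_
      used <<- setdiff(used, b)
    }
    FALSE
  }

  if (!solve(1L) && length(nodes)) return(NULL)

  edge_map <- list()
  if (nrow(a_links)) {
    for (i in seq_len(nrow(a_links))) {
      ca <- assign[a_links$cause[i]]; ef <- assign[a_links$effect[i]]
      path <- if (mode == "strict") {
        B$links[match(paste(ca, ef, sep = "\r"), direct), , drop = FALSE]
      } else {
        bfs_path(ca, ef, B)
      }
      edge_map[[paste(a_links$cause[i], a_links$effect[i], sep = " -> ")]] <-
        path
    }
  }
  structure(list(node_map = assign[!is.na(assign)], edge_map = edge_map,
                 mode = mode),
            class = "inclusion_witness")
}

#' @export
print.inclusion_witness <- function(x, ...) {
  cat(sprintf("<inclusion_witness> mode=%s, %d node(s), %d edge path(s)\n",
              x$mode, length(x$node_map), length(x$edge_map)))
  if (length(x$node_map))
    cat(sprintf("  %s => %s\n", names(x$node_map), x$node_map), sep = "")
  invisible(x)
}

#' Is disease A a super-class of disease B?
#'
#' Implements the is-a criterion over causal chains: A is a super-class of
#' B when all of A's causal chains (its aggregated core-and-derived chain
#' graph) are included in B's, with node inclusion judged under state
#' subsumption. Set `which = "core"` to compare core chains only.
#'
#' @param A,B Distinct disease ids.
#' @param ontology A `disease_ontology`.
#' @param mode Edge-matching mode, see [chain_included_in()].
#' @param which Chain selection passed to [chain_graph()], default `"all"`.
#' @return `TRUE` or `FALSE`.
#' @export
disease_is_super_of <- function(A, B, ontology, mode = c("path", "strict"),
                                which = "all") {
  mode <- match.arg(mode)
  if (identical(A, B))
    rf_stop("A and B must be distinct diseases", "riverflow_argument_error")
  ga <- chain_graph(A, which, ontology)
  gb <- chain_graph(B, which, ontology)
  !is.null(chain_included_in(ga, gb, ontology, mode))
}
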