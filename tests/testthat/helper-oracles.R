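# Independent oracles and random-case generators shared across tests.

`%||%` <- function(x, y) if (is.null(x)) y else x

pair_key <- function(df) paste(df$sub, df$super)

# Exhaustive inclusion oracle: enumerates every injective assignment of
# A-nodes to subsumption-compatible B-nodes and checks all edges at the
# leaves. Independent of the package's pruned backtracking search.
oracle_included <- function(A, B, ontology, mode = "path") {
  nodes <- A$states
  if (!length(nodes)) return(TRUE)
  cand <- lapply(nodes, function(a) {
    sa <- ontology$states[[a]]
    Filter(function(b) {
      sb <- ontology$states[[b]]
      if (sa$is_unknown) sb$is_unknown
      else !sb$is_unknown && state_subsumes(a, b, ontology)
    }, B$states)
  })
  adjB <- split(B$links$effect,
                factor(B$links$cause, levels = unique(B$links$cause)))
  reachable <- function(x, y) {
    frontier <- unique(unlist(adjB[x], use.names = FALSE))
    seen <- character()
    while (length(frontier)) {
      if (y %in% frontier) return(TRUE)
      seen <- c(seen, frontier)
      frontier <- setdiff(unique(unlist(adjB[frontier], use.names = FALSE)),
                          seen)
    }
    FALSE
  }
  direct <- paste(B$links$cause, B$links$effect)
  edges_ok <- function(map) {
    for (i in seq_len(nrow(A$links))) {
      x <- map[[A$links$cause[i]]]
      y <- map[[A$links$effect[i]]]
      ok <- if (mode == "strict") paste(x, y) %in% direct else reachable(x, y)
      if (!ok) return(FALSE)
    }
    TRUE
  }
  rec <- function(k, map, used) {
    if (k > length(nodes)) return(edges_ok(map))
    for (b in cand[[k]]) {
      if (b %in% used) next
      map[[nodes[k]]] <- b
      if (rec(k + 1L, map, c(used, b))) return(TRUE)
    }
    FALSE
  }
  rec(1L, list(), character())
}

# Small ontology with a random subStateOf forest and some unknown nodes;
# all states Level 1 (descriptor invariants vacuous), hierarchy acyclic by
# construction (parents only among earlier states).
random_hierarchy_ontology <- function(n_states, p_unknown = 0.15,
                                      p_parent = 0.7) {
  ids <- sprintf("t%02d", seq_len(n_states))
  states <- vector("list", n_states)
  known_sofar <- character()
  for (i in seq_len(n_states)) {
    unk <- stats::runif(1) < p_unknown
    parents <- if (!unk && length(known_sofar) &&
                   stats::runif(1) < p_parent)
      known_sofar[sample.int(length(known_sofar), 1)] else character()
    states[[i]] <- abnormal_state(ids[i], gsub("t", "term ", ids[i]),
                                  level = 1, parents = parents,
                                  is_unknown = unk)
    if (!unk) known_sofar <- c(known_sofar, ids[i])
  }
  disease_ontology(states)
}

# random causal graph over a sample of the ontology's states
random_graph <- function(ontology, n_nodes, p_edge = 0.3) {
  pool <- names(ontology$states)
  n_nodes <- min(n_nodes, length(pool))
  sts <- if (n_nodes) pool[sample.int(length(pool), n_nodes)] else character()
  cause <- character(); effect <- character()
  if (n_nodes >= 2)
    for (a in sts) for (b in sts)
      if (a != b && stats::runif(1) < p_edge) {
        cause <- c(cause, a); effect <- c(effect, b)
      }
  causal_graph(sts, causal_links(cause, effect))
}

# structural validity of a witness returned by chain_included_in
expect_valid_witness <- function(w, A, B, ontology, mode) {
  expect_s3_class(w, "inclusion_witness")
  expect_setequal(names(w$node_map), A$states)
  expect_false(anyDuplicated(w$node_map) > 0)  # injective
  for (a in names(w$node_map)) {
    b <- w$node_map[[a]]
    expect_true(b %in% B$states)
    if (ontology$states[[a]]$is_unknown) {
      expect_true(ontology$states[[b]]$is_unknown)
    } else {
      expect_true(state_subsumes(a, b, ontology))
    }
  }
  bk <- paste(B$links$cause, B$links$effect)
  for (i in seq_len(nrow(A$links))) {
    key <- paste(A$links$cause[i], "->", A$links$effect[i])
    path <- w$edge_map[[key]]
    expect_true(!is.null(path) && nrow(path) >= 1L)
    expect_identical(path$cause[1], unname(w$node_map[A$links$cause[i]]))
    expect_identical(path$effect[nrow(path)],
                     unname(w$node_map[A$links$effect[i]]))
    if (nrow(path) > 1L)
      expect_identical(path$cause[-1], path$effect[-nrow(path)])
    if (mode == "strict") expect_identical(nrow(path), 1L)
    expect_true(all(paste(path$cause, path$effect) %in% bk))
  }
}
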