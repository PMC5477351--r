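# ---- disease is-a inference and core-causal-chain extraction ------------

pairs_df <- function(sub = character(), super = character()) {
  df <- data.frame(sub = as.character(sub), super = as.character(super),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df), , drop = FALSE]
  df <- df[order(df$sub, df$super), , drop = FALSE]
  rownames(df) <- NULL
  df
}

transitive_closure_pairs <- function(pairs) {
  adj <- split(pairs$super, factor(pairs$sub, levels = unique(pairs$sub)))
  subs <- unique(pairs$sub)
  out_sub <- character(); out_super <- character()
  for (s in subs) {
    ups <- setdiff(reach(s, adj), s)
    out_sub <- c(out_sub, rep(s, length(ups)))
    out_super <- c(out_super, ups)
  }
  pairs_df(out_sub, out_super)
}

transitive_reduction_pairs <- function(pairs) {
  # assumes `pairs` transitively closed and acyclic
  keep <- rep(TRUE, nrow(pairs))
  key <- paste(pairs$sub, pairs$super, sep = "\r")
  for (i in seq_len(nrow(pairs))) {
    u <- pairs$sub[i]; v <- pairs$super[i]
    mids <- pairs$super[pairs$sub == u & pairs$super != v]
    if (any(paste(mids, v, sep = "\r") %in% key)) keep[i] <- FALSE
  }
  pairs_df(pairs$sub[keep], pairs$super[keep])
}

#' Infer the disease is-a hierarchy from chain inclusion
#'
#' Tests every ordered pair of diseases with [disease_is_super_of()] and
#' assembles the resulting sub/super pairs. Pairs of diseases whose chains
#' include each other (indistinguishable under the matching mode) are
#' reported as `equivalences`, never as cycles in `pairs`. Declared
#' `subDiseaseOf` assertions that the chain test does not confirm are
#' reported as `discrepancies`.
#'
#' @param ontology A validated `disease_ontology`.
#' @param mode Edge-matching mode, see [chain_included_in()].
#' @param which Chain selection (default `"all"`).
#' @return An `isa_result`: list with `pairs` (transitively closed
#'   data.frame of sub/super), `reduced_pairs` (its transitive reduction),
#'   `equivalences` (unordered id pairs) and `discrepancies`.
#' @export
infer_isa_hierarchy <- function(ontology, mode = c("path", "strict"),
                                which = "all") {
  mode <- match.arg(mode)
  ids <- sort(names(ontology$diseases))
  graphs <- lapply(ids, chain_graph, which = which, ontology = ontology)
  names(graphs) <- ids
  idx <- ancestors_index(ontology)
  sub <- character(); super <- character()
  for (a in ids) for (b in ids) {
    if (a == b) next
    if (!is.null(chain_included_in(graphs[[a]], graphs[[b]], ontology, mode,
                                   .index = idx))) {
      sub <- c(sub, b); super <- c(super, a)
    }
  }
  raw <- pairs_df(sub, super)
  key <- paste(raw$sub, raw$super, sep = "\r")
  rev_key <- paste(raw$super, raw$sub, sep = "\r")
  mutual <- key %in% rev_key
  eq <- raw[mutual & raw$sub < raw$super, , drop = FALSE]
  equivalences <- data.frame(a = eq$sub, b = eq$super,
                             stringsAsFactors = FALSE)
  strict <- raw[!mutual, , drop = FALSE]
  pairs <- transitive_closure_pairs(strict)
  # the inclusion relation is itself transitive, so closure only ever
  # confirms what the pairwise tests already found
  pairs <- pairs_df(c(pairs$sub, strict$sub), c(pairs$super, strict$super))

  dsub <- character(); dsuper <- character()
  for (d in ontology$diseases) for (s in d$supers) {
    if (!s %in% ids) next
    if (!paste(d$id, s, sep = "\r") %in% paste(pairs$sub, pairs$super, sep = "\r")) {
      dsub <- c(dsub, d$id); dsuper <- c(dsuper, s)
    }
  }
  structure(list(pairs = pairs,
                 reduced_pairs = transitive_reduction_pairs(pairs),
                 equivalences = equivalences,
                 discrepancies = pairs_df(dsub, dsuper),
                 mode = mode),
            class = "isa_result")
}

#' @export
print.isa_result <- function(x, ...) {
  cat(sprintf("<isa_result> %d pair(s), %d in reduction, %d equivalence(s), %d discrepancy(ies)\n",
              nrow(x$pairs), nrow(x$reduced_pairs), nrow(x$equivalences),
              nrow(x$discrepancies)))
  if (nrow(x$reduced_pairs))
    cat(sprintf("  %s subDiseaseOf %s\n", x$reduced_pairs$sub,
                x$reduced_pairs$super), sep = "")
  invisible(x)
}

declared_subclasses <- function(disease, ontology) {
  sort(names(Filter(function(d) disease %in% d$supers, ontology$diseases)))
}

# is element-state `s` covered by some state of graph B?
state_covered_in <- function(s, B, ontology, index = NULL) {
  length(inclusion_candidates(s, B, ontology, index)) > 0L
}

link_covered_in <- function(cause, effect, B, ontology, mode, rplusB,
                            index = NULL) {
  tc <- inclusion_candidates(cause, B, ontology, index)
  te <- inclusion_candidates(effect, B, ontology, index)
  if (!length(tc) || !length(te)) return(FALSE)
  direct <- link_keys(B$links)
  for (x in tc) for (y in te) {
    if (x == y) next
    ok <- if (mode == "strict") paste(x, y, sep = "\r") %in% direct
          else y %in% rplusB[[x]]
    if (ok) return(TRUE)
  }
  FALSE
}

#' Extract the core causal chain of a disease
#'
#' The core causal chain is the part of a disease's chain included in the
#' chains of all its subclass diseases: the stable definition appearing in
#' every patient. With declared subclasses, each state of the disease's
#' aggregated chain is kept iff every subclass chain contains an
#' equal-or-more-specific state covering it, and each link iff a direct
#' link (`mode = "strict"`) or directed path (`mode = "path"`) between
#' covering states exists in every subclass chain; the result is the graph
#' induced on the kept elements. A disease with no declared subclasses
#' falls back to its declared core chain (the intersection over zero
#' subclasses being undefined).
#'
#' Connectivity of the result is not enforced; use [graph_components()]
#' to inspect it.
#'
#' @param disease Disease id.
#' @param ontology A `disease_ontology`.
#' @param mode Edge-matching mode.
#' @param subclasses Disease ids to intersect over; defaults to the
#'   declared (direct) `subDiseaseOf` children. Supply explicitly for
#'   ontologies whose subclasses carry standalone chains without declared
#'   supers.
#' @return A `causal_graph`.
#' @export
core_causal_chain <- function(disease, ontology, mode = c("path", "strict"),
                              subclasses = NULL) {
  mode <- match.arg(mode)
  require_disease(disease, ontology)
  subs <- subclasses %||% declared_subclasses(disease, ontology)
  if (!length(subs)) return(chain_graph(disease, "core", ontology))
  G <- chain_graph(disease, "all", ontology)
  sub_graphs <- lapply(subs, chain_graph, which = "all", ontology = ontology)
  rplus <- lapply(sub_graphs, reach_plus)
  idx <- ancestors_index(ontology)
  keep_state <- vapply(G$states, function(s)
    all(vapply(sub_graphs, function(B) state_covered_in(s, B, ontology, idx),
               TRUE)), TRUE)
  kept <- G$states[keep_state]
  lk <- G$links[G$links$cause %in% kept & G$links$effect %in% kept, ,
                drop = FALSE]
  if (nrow(lk)) {
    keep_link <- vapply(seq_len(nrow(lk)), function(i)
      all(vapply(seq_along(sub_graphs), function(j)
        link_covered_in(lk$cause[i], lk$effect[i], sub_graphs[[j]],
                        ontology, mode, rplus[[j]], idx), TRUE)), TRUE)
    lk <- lk[keep_link, , drop = FALSE]
  }
  causal_graph(kept, lk)
}

#' Check a declared core chain against every subclass
#'
#' Verifies the Definition-3 consistency condition: the disease's declared
#' core chain must be included in the aggregated chain of every declared
#' subclass. Returns one row per uncovered element.
#'
#' @param disease Disease id.
#' @param ontology A `disease_ontology`.
#' @param mode Edge-matching mode.
#' @param subclasses Disease ids to check against; defaults to the
#'   declared direct subclasses.
#' @return Data.frame with columns `subclass`, `element`, `kind`
#'   (`"state"`, `"link"` or `"witness"`); zero rows iff consistent.
#' @export
validate_core_against_subclasses <- function(disease, ontology,
                                             mode = c("path", "strict"),
                                             subclasses = NULL) {
  mode <- match.arg(mode)
  require_disease(disease, ontology)
  core <- chain_graph(disease, "core", ontology)
  subs <- subclasses %||% declared_subclasses(disease, ontology)
  out <- data.frame(subclass = character(), element = character(),
                    kind = character(), stringsAsFactors = FALSE)
  for (s in subs) {
    B <- chain_graph(s, "all", ontology)
    if (!is.null(chain_included_in(core, B, ontology, mode))) next
    rp <- if (mode == "path") reach_plus(B) else NULL
    found <- FALSE
    for (st in core$states) {
      if (!state_covered_in(st, B, ontology)) {
        out[nrow(out) + 1L, ] <- c(s, st, "state"); found <- TRUE
      }
    }
    for (i in seq_len(nrow(core$links))) {
      if (!link_covered_in(core$links$cause[i], core$links$effect[i], B,
                           ontology, mode, rp)) {
        out[nrow(out) + 1L, ] <- c(s, paste(core$links$cause[i], "->",
                                            core$links$effect[i]), "link")
        found <- TRUE
      }
    }
    if (!found)  # elements individually covered, but no injective witness
      out[nrow(out) + 1L, ] <- c(s, "*", "witness")
  }
  out
}

#' Weakly connected components of a causal graph
#'
#' @param graph A `causal_graph`.
#' @return Named integer vector: component index per state id.
#' @export
graph_components <- function(graph) {
  und <- list()
  for (i in seq_len(nrow(graph$links))) {
    a <- graph$links$cause[i]; b <- graph$links$effect[i]
    und[[a]] <- c(und[[a]], b); und[[b]] <- c(und[[b]], a)
  }
  comp <- stats::setNames(rep(NA_integer_, length(graph$states)),
                          graph$states)
  k <- 0L
  for (s in graph$states) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    comp[reach(s, und)] <- k
  }
  comp
}
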