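#' Check the three-layer level constraints of a state hierarchy
#'
#' The abnormality hierarchy has three layers: Level 1 generic,
#' object-independent states; Level 2 object-dependent states developed by
#' specializing Level-1 concepts; Level 3 disease-context-dependent states
#' referring to Level-2 states. `check_levels` verifies that each Level-2
#' state has at least one ancestor path reaching a Level-1 state, that each
#' Level-3 state has a Level-2 ancestor, and that no state has a parent of
#' strictly greater level. Unknown nodes are exempt from the ancestry
#' requirements: they are placeholders without declared parents.
#'
#' @param ontology A `disease_ontology`.
#' @return Data.frame with columns `state`, `detail`; zero rows iff all
#'   constraints hold.
#' @export
check_levels <- function(ontology) {
  st <- character(); detail <- character()
  add <- function(s, d) { st <<- c(st, s); detail <<- c(detail, d) }
  level_of <- function(id) ontology$states[[id]]$level
  for (s in ontology$states) {
    for (p in s$parents) {
      if (!p %in% names(ontology$states)) next  # dangling: validate_ontology
      if (level_of(p) > s$level)
        add(s$id, sprintf("parent '%s' has greater level (%d > %d)", p,
                          level_of(p), s$level))
    }
    if (s$is_unknown) next
    anc <- state_ancestors(s$id, ontology)
    anc <- anc[anc %in% names(ontology$states)]
    anc_levels <- vapply(anc, level_of, 1L)
    if (s$level == 2L && !any(anc_levels == 1L))
      add(s$id, "Level-2 state with no Level-1 ancestor")
    if (s$level == 3L && !any(anc_levels == 2L))
      add(s$id, "Level-3 state with no Level-2 ancestor")
  }
  data.frame(state = st, detail = detail, stringsAsFactors = FALSE)
}
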