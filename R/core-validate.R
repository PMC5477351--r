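# nodes of `ids` that lie on a directed cycle of the relation id -> adj[[id]]
nodes_on_cycles <- function(ids, adj) {
  on_cycle <- character()
  for (n in ids) {
    succ <- adj[[n]]
    if (length(succ) && n %in% reach(succ, adj)) on_cycle <- c(on_cycle, n)
  }
  sort(unique(on_cycle))
}

state_parent_adj <- function(ontology) {
  lapply(ontology$states, function(s) s$parents)
}

disease_super_adj <- function(ontology) {
  lapply(ontology$diseases, function(d) d$supers)
}

#' Test subsumption between two abnormal states
#'
#' `state_subsumes(general, specific)` is `TRUE` iff `specific` is the same
#' state as `general` or `general` is reachable from `specific` along
#' `subStateOf` edges: the reflexive-transitive closure of the declared is-a
#' hierarchy. Example chain: arterial stenosis is-a vascular stenosis is-a
#' tube narrowing is-a small in area, so "small in area" subsumes
#' "arterial stenosis".
#'
#' @param general,specific State ids.
#' @param ontology A `disease_ontology`.
#' @return `TRUE` or `FALSE`.
#' @export
state_subsumes <- function(general, specific, ontology) {
  for (id in c(general, specific))
    if (!id %in% names(ontology$states))
      rf_stop(sprintf("unknown state id '%s'", id), "riverflow_id_error")
  if (general == specific) return(TRUE)
  general %in% reach(specific, state_parent_adj(ontology))
}

# ancestors of a state (excluding itself); safe on cycles
state_ancestors <- function(id, ontology) {
  setdiff(reach(id, state_parent_adj(ontology)), id)
}

# all states subsumed by `id` (id plus its subStateOf descendants)
state_descendants <- function(id, ontology, proper = FALSE) {
  kids <- lapply(ontology$states, function(s) s$id)
  child_adj <- list()
  for (s in ontology$states)
    for (p in s$parents)
      child_adj[[p]] <- c(child_adj[[p]], s$id)
  out <- reach(id, child_adj)
  if (proper) setdiff(out, id) else out
}

validation_report <- function(type = character(), entity = character(),
                              detail = character()) {
  structure(data.frame(type = type, entity = entity, detail = detail,
                       stringsAsFactors = FALSE),
            class = c("rf_validation", "data.frame"))
}

#' @export
print.rf_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("validation: no findings\n")
  } else {
    cat(sprintf("validation: %d finding(s)\n", nrow(x)))
    for (i in seq_len(nrow(x)))
      cat(sprintf("  [%s] %s: %s\n", x$type[i], x$entity[i], x$detail[i]))
  }
  invisible(x)
}

#' Validate a disease ontology
#'
#' Checks every structural invariant of the model and returns a report of
#' findings; an empty report means the ontology is valid. Checked: dangling
#' references (state parents, link endpoints, disease state sets, disease
#' supers), cycles in the `subStateOf` and `subDiseaseOf` hierarchies,
#' overlap of a disease's core and derived sets, self-loop causal links,
#' and per-state descriptor invariants (Level-1 states carry no Object;
#' Level-2/3 states carry one unless unknown; unknown nodes carry no
#' descriptors). The function is pure: it never modifies its input, and
#' re-running it yields the identical report.
#'
#' @param ontology A `disease_ontology`.
#' @return An `rf_validation` data.frame with columns `type`, `entity`,
#'   `detail`; zero rows iff all invariants hold.
#' @export
validate_ontology <- function(ontology) {
  types <- character(); entities <- character(); details <- character()
  add <- function(type, entity, detail) {
    types <<- c(types, type); entities <<- c(entities, entity)
    details <<- c(details, detail)
  }
  sids <- names(ontology$states)
  dids <- names(ontology$diseases)

  for (s in ontology$states) {
    miss <- setdiff(s$parents, sids)
    for (m in miss)
      add("dangling_reference", s$id, sprintf("parent state '%s' not found", m))
    if (s$is_unknown) {
      if (!all(is.na(c(s$object, s$sub_object, s$attribute, s$value))))
        add("descriptor_invariant", s$id,
            "unknown node must carry no O/SO/A/V descriptors")
    } else if (s$level == 1L) {
      if (!is.na(s$object))
        add("descriptor_invariant", s$id,
            "Level-1 state must not have a target object")
    } else {
      if (is.na(s$object))
        add("descriptor_invariant", s$id,
            sprintf("Level-%d state must have a target object", s$level))
    }
  }

  for (i in seq_len(nrow(ontology$links))) {
    ca <- ontology$links$cause[i]; ef <- ontology$links$effect[i]
    if (ca == ef)
      add("self_loop", ca, "causal link with identical endpoints")
    for (e in setdiff(c(ca, ef), sids))
      add("dangling_reference", e,
          sprintf("causal link endpoint '%s' not an ontology state", e))
  }

  for (d in ontology$diseases) {
    for (m in setdiff(c(d$core_states, d$derived_states), sids))
      add("dangling_reference", d$id, sprintf("state '%s' not found", m))
    for (m in setdiff(d$supers, dids))
      add("dangling_reference", d$id,
          sprintf("super disease '%s' not found", m))
    ovl <- intersect(d$core_states, d$derived_states)
    if (length(ovl))
      add("core_derived_overlap", d$id,
          sprintf("state(s) in both core and derived sets: %s",
                  paste(ovl, collapse = ", ")))
  }

  cyc <- nodes_on_cycles(sids, state_parent_adj(ontology))
  if (length(cyc))
    add("cycle", paste(cyc, collapse = ","),
        "subStateOf hierarchy contains a cycle")
  cyc <- nodes_on_cycles(dids, disease_super_adj(ontology))
  if (length(cyc))
    add("cycle", paste(cyc, collapse = ","),
        "subDiseaseOf hierarchy contains a cycle")

  validation_report(types, entities, details)
}

ontology_valid <- function(ontology) nrow(validate_ontology(ontology)) == 0L

require_disease <- function(id, ontology) {
  if (!id %in% names(ontology$diseases))
    rf_stop(sprintf("unknown disease id '%s'", id), "riverflow_id_error")
  ontology$diseases[[id]]
}

require_state <- function(id, ontology) {
  if (!id %in% names(ontology$states))
    rf_stop(sprintf("unknown state id '%s'", id), "riverflow_id_error")
  ontology$states[[id]]
}
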