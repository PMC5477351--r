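# ---- exact-string-match mapping to external vocabularies ----------------

#' Normalize a label for matching
#'
#' Trims, collapses internal whitespace and case-folds. Normalized rather
#' than byte-exact comparison is needed to reproduce matches such as
#' "chest pain" vs an external "Chest pain". Set
#' `options(riverflow.case_sensitive = TRUE)` to restore case-sensitive
#' matching.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_label <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  if (isTRUE(getOption("riverflow.case_sensitive", FALSE))) x else tolower(x)
}

#' Read an external vocabulary table
#'
#' @param path Two-column TSV (`id`, `label`) with a header row.
#' @return Data.frame with columns `id`, `label`.
#' @export
read_vocab <- function(path) {
  df <- read_tsv_chr(path)
  data.frame(id = df$id, label = df$label, stringsAsFactors = FALSE)
}

#' Detect mapping candidates by perfect string match
#'
#' For each state, finds every vocabulary entry whose normalized label
#' equals the state's normalized label. Candidates are only candidates:
#' they carry `status = "candidate"` and are never auto-accepted, mirroring
#' a workflow where mapping is performed manually after candidate
#' detection. Use [accept_candidates()] (or set `accepted` yourself)
#' before summarising accepted mappings.
#'
#' @param states List of `abnormal_state` objects (e.g. `ontology$states`).
#' @param vocab Data.frame with columns `id`, `label`, from [read_vocab()].
#' @param resource Name of the vocabulary, recorded per candidate.
#' @return Data.frame with columns `state`, `resource`, `external_id`,
#'   `external_label`, `status`, `accepted`.
#' @export
match_external <- function(states, vocab, resource = "external") {
  out <- data.frame(state = character(), resource = character(),
                    external_id = character(), external_label = character(),
                    status = character(), accepted = logical(),
                    stringsAsFactors = FALSE)
  if (!nrow(vocab)) return(out)
  vnorm <- normalize_label(vocab$label)
  for (s in states) {
    if (is.na(s$label)) next
    hit <- which(vnorm == normalize_label(s$label))
    hit <- hit[order(vocab$id[hit])]
    for (i in hit)
      out[nrow(out) + 1L, ] <- list(s$id, resource, vocab$id[i],
                                    vocab$label[i], "candidate", FALSE)
  }
  out[order(out$state, out$resource, out$external_id), , drop = FALSE]
}

#' @rdname match_external
#' @param candidates Candidate table from [match_external()].
#' @export
accept_candidates <- function(candidates) {
  candidates$accepted <- TRUE
  candidates$status <- "accepted"
  candidates
}

#' Per-level summary of accepted external mappings
#'
#' Builds the standard mapping-summary table: for each level of the
#' three-layer model and each vocabulary, the number of states with at
#' least one accepted mapping, plus a totals row equal to the column sums
#' and a column with the number of ontology states per level.
#'
#' @param candidates Candidate table (possibly concatenated across
#'   vocabularies) with logical column `accepted`.
#' @param ontology A `disease_ontology` supplying state levels.
#' @param resources Vocabulary names to tabulate; defaults to those present
#'   in `candidates`. Supply explicitly to force all-zero columns for
#'   vocabularies that produced no candidates at all.
#' @return Data.frame: one row per level plus `total`; columns `level`,
#'   `n_states`, then one count column per resource.
#' @export
mapping_summary <- function(candidates, ontology,
                            resources = sort(unique(candidates$resource))) {
  levels_of <- vapply(ontology$states, `[[`, 1L, "level")
  out <- data.frame(level = c("1", "2", "3", "total"),
                    n_states = c(sum(levels_of == 1L), sum(levels_of == 2L),
                                 sum(levels_of == 3L), length(levels_of)),
                    stringsAsFactors = FALSE)
  acc <- candidates[candidates$accepted, , drop = FALSE]
  for (r in resources) {
    mapped_states <- unique(acc$state[acc$resource == r])
    mapped_states <- mapped_states[mapped_states %in% names(levels_of)]
    lv <- levels_of[mapped_states]
    out[[r]] <- c(sum(lv == 1L), sum(lv == 2L), sum(lv == 3L), length(lv))
  }
  out
}
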