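# ---- TSV ontology interchange -------------------------------------------
# Three UTF-8 tables with header rows; multi-valued cells pipe-separated;
# external refs encoded as RESOURCE=ID (the id itself may contain ':').
#   states.tsv:   id label level object sub_object attribute value parents
#                 is_unknown external_refs
#   links.tsv:    cause effect probable
#   diseases.tsv: id label area supers core_states derived_states

split_multi <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, "|", fixed = TRUE)[[1]]
}

join_multi <- function(x) paste(x, collapse = "|")

parse_refs <- function(x) {
  parts <- split_multi(x)
  out <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) rf_stop(sprintf("malformed external ref '%s' (want RES=ID)", p))
    res <- substr(p, 1, eq - 1)
    id <- substr(p, eq + 1, nchar(p))
    out[[res]] <- c(out[[res]], id)
  }
  out
}

format_refs <- function(refs) {
  if (!length(refs)) return("")
  refs <- refs[order(names(refs))]
  join_multi(unlist(lapply(names(refs), function(r)
    paste0(r, "=", sort(refs[[r]])))))
}

read_tsv_chr <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL,
                          check.names = FALSE, fileEncoding = "UTF-8")
  df
}

blank_na <- function(x) ifelse(nzchar(x), x, NA_character_)

#' Read a disease ontology from its three-table TSV format
#'
#' @param dir Directory containing `states.tsv`, `links.tsv`,
#'   `diseases.tsv`.
#' @return A `disease_ontology`.
#' @seealso [write_ontology()]
#' @export
read_ontology <- function(dir) {
  st <- read_tsv_chr(file.path(dir, "states.tsv"))
  lk <- read_tsv_chr(file.path(dir, "links.tsv"))
  ds <- read_tsv_chr(file.path(dir, "diseases.tsv"))
  states <- lapply(seq_len(nrow(st)), function(i) {
    abnormal_state(
      id = st$id[i], label = blank_na(st$label[i]),
      object = blank_na(st$object[i]), sub_object = blank_na(st$sub_object[i]),
      attribute = blank_na(st$attribute[i]), value = blank_na(st$value[i]),
      level = as.integer(st$level[i]),
      parents = split_multi(st$parents[i]),
      is_unknown = tolower(st$is_unknown[i]) %in% c("true", "1", "yes"),
      external_refs = parse_refs(st$external_refs[i]))
  })
  diseases <- lapply(seq_len(nrow(ds)), function(i) {
    disease(id = ds$id[i], label = blank_na(ds$label[i]),
            area = blank_na(ds$area[i]),
            supers = split_multi(ds$supers[i]),
            core_states = split_multi(ds$core_states[i]),
            derived_states = split_multi(ds$derived_states[i]))
  })
  links <- causal_links(lk$cause, lk$effect,
                        tolower(lk$probable) %in% c("true", "1", "yes"))
  disease_ontology(states, diseases, links)
}

na_blank <- function(x) ifelse(is.na(x), "", x)

#' Write a disease ontology in the three-table TSV format
#'
#' Rows are sorted by id so output is byte-stable for a fixed ontology.
#'
#' @param ontology A `disease_ontology`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ontology <- function(ontology, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  states <- ontology$states[order(names(ontology$states))]
  st <- data.frame(
    id = vapply(states, `[[`, "", "id"),
    label = na_blank(vapply(states, `[[`, "", "label")),
    level = vapply(states, `[[`, 1L, "level"),
    object = na_blank(vapply(states, `[[`, "", "object")),
    sub_object = na_blank(vapply(states, `[[`, "", "sub_object")),
    attribute = na_blank(vapply(states, `[[`, "", "attribute")),
    value = na_blank(vapply(states, `[[`, "", "value")),
    parents = vapply(states, function(s) join_multi(sort(s$parents)), ""),
    is_unknown = tolower(vapply(states, `[[`, TRUE, "is_unknown")),
    external_refs = vapply(states, function(s) format_refs(s$external_refs), ""),
    stringsAsFactors = FALSE)
  diseases <- ontology$diseases[order(names(ontology$diseases))]
  ds <- data.frame(
    id = vapply(diseases, `[[`, "", "id"),
    label = na_blank(vapply(diseases, `[[`, "", "label")),
    area = na_blank(vapply(diseases, `[[`, "", "area")),
    supers = vapply(diseases, function(d) join_multi(sort(d$supers)), ""),
    core_states = vapply(diseases, function(d) join_multi(d$core_states), ""),
    derived_states = vapply(diseases, function(d) join_multi(d$derived_states), ""),
    stringsAsFactors = FALSE)
  lk <- normalize_links(ontology$links)
  lk$probable <- tolower(lk$probable)
  wr <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  wr(st, "states.tsv"); wr(lk, "links.tsv"); wr(ds, "diseases.tsv")
  invisible(dir)
}
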