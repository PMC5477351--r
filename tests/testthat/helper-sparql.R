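# A minimal, self-contained SPARQL evaluator used as the independent
# second route for the query layer: it parses the literal .rq text shipped
# with the package and executes it over the parsed Turtle triples. It
# supports exactly the constructs those nine patterns use: basic graph
# patterns, property paths (alternation, *, +), variable predicates and
# FILTER (?v IN (...)). It shares no code with run_query().

sparql_split_statements <- function(body) {
  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  depth <- 0L; in_iri <- FALSE; buf <- character(); out <- character()
  for (ch in chars) {
    if (ch == "<") in_iri <- TRUE
    if (ch == ">") in_iri <- FALSE
    if (!in_iri && ch == "(") depth <- depth + 1L
    if (!in_iri && ch == ")") depth <- depth - 1L
    if (ch == "." && depth == 0L && !in_iri) {
      out <- c(out, paste(buf, collapse = "")); buf <- character()
    } else buf <- c(buf, ch)
  }
  last <- trimws(paste(buf, collapse = ""))
  if (nzchar(last)) out <- c(out, last)
  trimws(out[nzchar(trimws(out))])
}

sparql_resolve <- function(tok, prefixes) {
  if (startsWith(tok, "?")) return(list(kind = "var", name = substring(tok, 2)))
  if (startsWith(tok, "<"))
    return(list(kind = "const", value = substr(tok, 2, nchar(tok) - 1L)))
  colon <- regexpr(":", tok, fixed = TRUE)
  stopifnot(colon > 0)
  p <- substr(tok, 1, colon - 1L)
  list(kind = "const",
       value = paste0(prefixes[[p]], substring(tok, colon + 1L)))
}

sparql_parse_path <- function(tok, prefixes) {
  mod <- ""
  if (grepl("[*+]$", tok)) {
    mod <- substr(tok, nchar(tok), nchar(tok))
    tok <- substr(tok, 1, nchar(tok) - 1L)
  }
  tok <- sub("^\\(", "", sub("\\)$", "", tok))
  preds <- vapply(strsplit(tok, "|", fixed = TRUE)[[1]],
                  function(t) sparql_resolve(t, prefixes)$value, "")
  list(preds = unname(preds), mod = mod)
}

# all (from, to) pairs satisfying a property path over the triple set
sparql_path_pairs <- function(path, triples, extra_terms = character()) {
  rel <- triples[triples$predicate %in% path$preds &
                   triples$object_type == "iri", c("subject", "object")]
  if (path$mod == "")
    return(stats::setNames(rel, c("from", "to")))
  adj <- split(rel$object, factor(rel$subject, levels = unique(rel$subject)))
  universe <- unique(c(triples$subject,
                       triples$object[triples$object_type == "iri"],
                       extra_terms))
  from <- character(); to <- character()
  for (u in universe) {
    seen <- character(); frontier <- unique(unlist(adj[u], use.names = FALSE))
    while (length(frontier)) {
      seen <- c(seen, frontier)
      frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                          seen)
    }
    targets <- if (path$mod == "*") unique(c(u, seen)) else seen
    from <- c(from, rep(u, length(targets))); to <- c(to, targets)
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

sparql_eval <- function(query_text, triples) {
  lines <- strsplit(query_text, "\n", fixed = TRUE)[[1]]
  prefixes <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^PREFIX\\s+([A-Za-z0-9_]+):\\s+<([^>]*)>", l))[[1]]
    if (length(m)) prefixes[[m[2]]] <- m[3]
  }
  one <- paste(lines[!grepl("^PREFIX", lines)], collapse = " ")
  sel <- regmatches(one, regexec("SELECT\\s+(.*?)\\s+WHERE", one))[[1]][2]
  vars <- substring(strsplit(trimws(sel), "\\s+")[[1]], 2)
  body <- sub("^[^{]*\\{", "", one)
  body <- sub("\\}[^}]*$", "", body)
  stmts <- sparql_split_statements(body)

  bindings <- data.frame(.all = 1L)
  for (st in stmts) {
    if (grepl("^FILTER", st)) {
      m <- regmatches(st, regexec(
        "^FILTER\\s*\\(\\s*\\?([A-Za-z0-9_]+)\\s+IN\\s+\\(([^)]*)\\)\\s*\\)$",
        st))[[1]]
      stopifnot(length(m) == 3)
      allowed <- vapply(trimws(strsplit(m[3], ",", fixed = TRUE)[[1]]),
                        function(t) sparql_resolve(t, prefixes)$value, "")
      bindings <- bindings[bindings[[m[2]]] %in% allowed, , drop = FALSE]
      next
    }
    toks <- strsplit(st, "\\s+")[[1]]
    stopifnot(length(toks) == 3)
    s_t <- sparql_resolve(toks[1], prefixes)
    o_t <- sparql_resolve(toks[3], prefixes)
    if (startsWith(toks[2], "?")) {
      p_t <- sparql_resolve(toks[2], prefixes)
      pairs <- data.frame(from = triples$subject, to = triples$object,
                          .p = triples$predicate, stringsAsFactors = FALSE)
      pairs <- pairs[triples$object_type == "iri", , drop = FALSE]
    } else {
      path <- sparql_parse_path(toks[2], prefixes)
      extra <- c(if (s_t$kind == "const") s_t$value,
                 if (o_t$kind == "const") o_t$value)
      pairs <- sparql_path_pairs(path, triples, extra)
      p_t <- NULL
    }
    cols <- character()
    if (s_t$kind == "const") {
      pairs <- pairs[pairs$from == s_t$value, , drop = FALSE]
    } else {
      names(pairs)[names(pairs) == "from"] <- s_t$name
      cols <- c(cols, s_t$name)
    }
    if (o_t$kind == "const") {
      pairs <- pairs[pairs$to == o_t$value, , drop = FALSE]
    } else {
      names(pairs)[names(pairs) == "to"] <- o_t$name
      cols <- c(cols, o_t$name)
    }
    if (!is.null(p_t)) {
      names(pairs)[names(pairs) == ".p"] <- p_t$name
      cols <- c(cols, p_t$name)
    }
    pairs <- unique(pairs[, cols, drop = FALSE])
    shared <- intersect(names(bindings), names(pairs))
    bindings <- if (length(shared)) merge(bindings, pairs, by = shared)
                else merge(bindings, pairs, by = NULL)
    if (!nrow(bindings)) break
  }
  if (!nrow(bindings))
    return(stats::setNames(
      as.data.frame(replicate(length(vars), character(),
                              simplify = FALSE)), vars))
  unique(bindings[, vars, drop = FALSE])
}

# run one named pattern through the independent engine, over the Turtle
# serialization, returning plain ids; pass `triples` to reuse one parse
sparql_oracle <- function(name, id = NULL, ontology,
                          vocab = rfm_vocabulary(), triples = NULL) {
  if (is.null(triples))
    triples <- read_turtle(write_turtle(to_rdf(ontology, vocab), NULL, vocab))
  res <- sparql_eval(sparql_pattern(name, id, vocab), triples)
  strip <- function(x) sub(paste0("^", vocab$ns), "", x)
  if (ncol(res) == 1L) sort(unique(strip(res[[1]])))
  else {
    out <- data.frame(subject = strip(res$s), predicate = strip(res$p),
                      object = strip(res$o), stringsAsFactors = FALSE)
    out <- unique(out)
    out <- out[order(out$subject, out$predicate, out$object), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
}
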