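# ---- synthetic ontology generator with planted ground truth -------------

#' Configuration for the synthetic-ontology generator
#'
#' The generator emulates how clinicians author an RFM ontology: a shared
#' state hierarchy, root diseases with authored chains, and subclasses
#' derived from a parent disease by copying its chain and then specializing
#' some states to planted descendants (`p_refine`), expressing some causal
#' steps at finer resolution by inserting intermediates (`p_insert`), and
#' always extending the chain upstream or downstream by at least one new
#' state. Defaults give moderate refinement on a two-to-three-level
#' disease tree; see the package vignette for the rationale.
#'
#' @param n_level1_states Number of generic Level-1 states.
#' @param n_level2_states Size of the shared Level-2 pool.
#' @param n_diseases Total diseases (roots plus derived subclasses).
#' @param hierarchy_depth Maximum depth of the planted disease tree.
#' @param chain_length Length-2 integer range for root chain lengths.
#' @param p_refine Probability a subclass specializes an inherited state.
#' @param p_insert Probability of inserting an intermediate on an
#'   inherited edge (re-expressing its downstream state in the subclass
#'   context, so the step is only reachable as a path there).
#' @param p_probable Probability a link is marked probable.
#' @param p_unknown Probability a newly created chain state is an unknown
#'   node.
#' @param declare_supers Emit `subDiseaseOf` for planted edges (default
#'   `FALSE`: subclasses carry standalone chain copies so that is-a
#'   inference from chain content is a genuine recovery test).
#' @param seed Integer seed; the same seed gives an identical ontology.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_level1_states = 6, n_level2_states = 40,
                             n_diseases = 30, hierarchy_depth = 3,
                             chain_length = c(3, 6), p_refine = 0.3,
                             p_insert = 0.2, p_probable = 0.1,
                             p_unknown = 0.05, declare_supers = FALSE,
                             seed = 1) {
  cfg <- list(n_level1_states = as.integer(n_level1_states),
              n_level2_states = as.integer(n_level2_states),
              n_diseases = as.integer(n_diseases),
              hierarchy_depth = as.integer(hierarchy_depth),
              chain_length = as.integer(chain_length),
              p_refine = p_refine, p_insert = p_insert,
              p_probable = p_probable, p_unknown = p_unknown,
              declare_supers = isTRUE(declare_supers),
              seed = as.integer(seed))
  for (p in c("p_refine", "p_insert", "p_probable", "p_unknown"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      rf_stop(sprintf("%s must lie in [0, 1]", p), "riverflow_config_error")
  for (p in c("n_level1_states", "n_level2_states", "n_diseases",
              "hierarchy_depth"))
    if (cfg[[p]] < 1L)
      rf_stop(sprintf("%s must be positive", p), "riverflow_config_error")
  if (length(cfg$chain_length) != 2L || any(cfg$chain_length < 1L) ||
      cfg$chain_length[1] > cfg$chain_length[2])
    rf_stop("chain_length must be an increasing positive range",
            "riverflow_config_error")
  if (cfg$chain_length[2] > cfg$n_level2_states)
    rf_stop("chain_length exceeds the available Level-2 pool",
            "riverflow_config_error")
  structure(cfg, class = "generator_config")
}

#' Generate a random disease ontology with planted ground truth
#'
#' @param config A [generator_config()].
#' @return A list with `ontology` (a valid `disease_ontology`) and
#'   `ground_truth`: `isa_pairs` (planted direct sub/super pairs),
#'   `isa_closure` (their transitive closure), `chains` (per disease, the
#'   planted local chain as state ids and links) and `state_parents`
#'   (the planted hierarchy).
#' @export
generate_ontology <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  states <- list()
  add_state <- function(s) states[[s$id]] <<- s
  resample <- function(x, n = 1L) x[sample.int(length(x), n)]

  l1_ids <- sprintf("g%02d_generic", seq_len(config$n_level1_states))
  for (i in seq_along(l1_ids))
    add_state(abnormal_state(l1_ids[i], sprintf("generic state %d", i),
                             level = 1))
  l2_ids <- sprintf("s%03d_organ_state", seq_len(config$n_level2_states))
  for (i in seq_along(l2_ids)) {
    pool <- c(l1_ids, l2_ids[seq_len(i - 1L)])
    add_state(abnormal_state(l2_ids[i], sprintf("organ state %d", i),
                             object = sprintf("organ %d", i %% 12 + 1),
                             attribute = "condition", value = "abnormal",
                             level = 2,
                             parents = resample(pool)))
  }

  fresh_n <- 0L
  fresh_chain_state <- function(context, allow_unknown = TRUE) {
    fresh_n <<- fresh_n + 1L
    id <- sprintf("c%04d_%s", fresh_n, context)
    if (allow_unknown && stats::runif(1) < config$p_unknown) {
      s <- abnormal_state(id, "unknown", level = 2, is_unknown = TRUE)
    } else {
      anchor <- resample(l2_ids)
      s <- abnormal_state(id, sprintf("state %d in %s", fresh_n, context),
                          object = states[[anchor]]$object,
                          attribute = "condition", value = "abnormal",
                          level = 3, parents = anchor)
    }
    add_state(s)
    id
  }
  specialize <- function(orig_id, context) {
    fresh_n <<- fresh_n + 1L
    id <- sprintf("c%04d_%s", fresh_n, context)
    orig <- states[[orig_id]]
    if (orig$is_unknown) {
      add_state(abnormal_state(id, "unknown", level = 2, is_unknown = TRUE,
                               parents = orig_id))
    } else {
      add_state(abnormal_state(id, sprintf("state %d in %s", fresh_n, context),
                               object = orig$object,
                               attribute = orig$attribute,
                               value = orig$value, level = 3,
                               parents = orig_id))
    }
    id
  }

  links_env <- new.env()
  links_env$cause <- character(); links_env$effect <- character()
  links_env$probable <- logical()
  add_link <- function(cause, effect, probable) {
    links_env$cause <- c(links_env$cause, cause)
    links_env$effect <- c(links_env$effect, effect)
    links_env$probable <- c(links_env$probable, probable)
  }

  # disease tree
  n <- config$n_diseases
  n_roots <- max(1L, n %/% 8L)
  parent_of <- rep(NA_integer_, n)
  depth_of <- rep(0L, n)
  for (i in seq_len(n)) {
    if (i <= n_roots) next
    eligible <- which(depth_of[seq_len(i - 1L)] < config$hierarchy_depth - 1L)
    parent_of[i] <- if (length(eligible) == 1L) eligible
                    else sample(eligible, 1)
    depth_of[i] <- depth_of[parent_of[i]] + 1L
  }

  chains <- vector("list", n)   # list(states=chr, links=df(cause,effect,probable))
  cores <- vector("list", n)
  diseases <- vector("list", n)
  for (i in seq_len(n)) {
    did <- sprintf("d%03d", i)
    if (is.na(parent_of[i])) {
      k <- resample(seq(config$chain_length[1], config$chain_length[2]))
      ids <- vapply(seq_len(k), function(j) fresh_chain_state(did), "")
      lk <- causal_links(ids[-k], ids[-1],
                         stats::runif(k - 1L) < config$p_probable)
      core <- ids[seq_len(ceiling(2 * k / 3))]
    } else {
      pc <- chains[[parent_of[i]]]
      repl <- stats::setNames(pc$states, pc$states)
      for (s in pc$states) {
        if (states[[s]]$is_unknown) next
        if (stats::runif(1) < config$p_refine) repl[s] <- specialize(s, did)
      }
      lk <- pc$links
      lk$cause <- unname(repl[lk$cause]); lk$effect <- unname(repl[lk$effect])
      ins <- if (nrow(lk)) stats::runif(nrow(lk)) < config$p_insert
             else logical()
      # pass 1: an inserted step must not leave the parent's direct link in
      # the subclass's induced graph, so its downstream state (when it
      # survived verbatim) is re-expressed as a planted child first
      for (j in which(ins)) {
        b <- lk$effect[j]
        if (b %in% pc$states) {  # still an original (unrefined) state
          b2 <- specialize(b, did)
          repl[b] <- b2
          lk$cause[lk$cause == b] <- b2
          lk$effect[lk$effect == b] <- b2
        }
      }
      # pass 2: split each chosen edge through a fresh intermediate
      if (any(ins)) {
        kept <- lk[!ins, , drop = FALSE]
        for (j in which(ins)) {
          m <- fresh_chain_state(did)
          kept <- rbind(kept, causal_links(c(lk$cause[j], m),
                                           c(m, lk$effect[j]),
                                           rep(lk$probable[j], 2)))
        }
        lk <- kept
      }
      ids <- unique(c(unname(repl), lk$cause, lk$effect))
      # extension: at least one genuinely new state up- or downstream
      n_ext <- resample(1:2)
      for (e in seq_len(n_ext)) {
        anchor <- resample(ids)
        ext <- fresh_chain_state(did)
        if (stats::runif(1) < 0.5)
          lk <- rbind(lk, causal_links(ext, anchor,
                                       stats::runif(1) < config$p_probable))
        else
          lk <- rbind(lk, causal_links(anchor, ext,
                                       stats::runif(1) < config$p_probable))
        ids <- c(ids, ext)
      }
      core <- unique(unname(repl[intersect(cores[[parent_of[i]]],
                                           names(repl))]))
    }
    chains[[i]] <- list(states = ids, links = lk)
    cores[[i]] <- core
    for (j in seq_len(nrow(lk)))
      add_link(lk$cause[j], lk$effect[j], lk$probable[j])
    diseases[[i]] <- disease(
      did, sprintf("disease %d", i),
      core_states = core,
      derived_states = setdiff(ids, core),
      supers = if (config$declare_supers && !is.na(parent_of[i]))
        sprintf("d%03d", parent_of[i]) else character(),
      area = sprintf("division %d", (if (is.na(parent_of[i])) i
                                     else parent_of[i]) %% 6 + 1))
  }

  links <- normalize_links(causal_links(links_env$cause, links_env$effect,
                                        links_env$probable))
  # a link may be emitted once certain and once probable by different
  # diseases; keep the certain version deterministically
  links <- links[order(links$cause, links$effect, links$probable), ,
                 drop = FALSE]
  links <- links[!duplicated(links[c("cause", "effect")]), , drop = FALSE]
  onto <- disease_ontology(unname(states), diseases, links)

  planted <- data.frame(
    sub = sprintf("d%03d", which(!is.na(parent_of))),
    super = sprintf("d%03d", parent_of[!is.na(parent_of)]),
    stringsAsFactors = FALSE)
  planted <- pairs_df(planted$sub, planted$super)
  names(chains) <- sprintf("d%03d", seq_len(n))
  gt <- list(isa_pairs = planted,
             isa_closure = transitive_closure_pairs(planted),
             chains = chains,
             state_parents = lapply(onto$states, function(s) s$parents))
  list(ontology = onto, ground_truth = gt)
}
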