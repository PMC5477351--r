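dia <- fixture_diabetes()

test_that("the diabetes core chain is included in every subclass chain", {
  core <- chain_graph("diabetes", "core", dia)
  for (sub in c("type_I_diabetes", "steroid_diabetes",
                "diabetes_caused_blindness")) {
    w <- chain_included_in(core, chain_graph(sub, "all", dia), dia, "path")
    expect_valid_witness(w, core, chain_graph(sub, "all", dia), dia, "path")
    # the subclass inherits the very same states: identity map expected
    expect_identical(unname(w$node_map[core$states]), core$states)
  }
})

test_that("the empty graph is vacuously included", {
  empty <- causal_graph()
  w <- chain_included_in(empty, chain_graph("diabetes", "all", dia), dia)
  expect_s3_class(w, "inclusion_witness")
  expect_length(w$node_map, 0L)
  expect_length(w$edge_map, 0L)
  w2 <- chain_included_in(empty, empty, dia, "strict")
  expect_s3_class(w2, "inclusion_witness")
})

test_that("disease_is_super_of matches the worked example", {
  expect_true(disease_is_super_of("diabetes", "type_I_diabetes", dia, "path"))
  expect_true(disease_is_super_of("diabetes", "steroid_diabetes", dia, "path"))
  expect_true(disease_is_super_of("diabetes", "diabetes_caused_blindness",
                                  dia, "path"))
  expect_false(disease_is_super_of("type_I_diabetes", "diabetes", dia, "path"))
  expect_false(disease_is_super_of("steroid_diabetes", "type_I_diabetes",
                                   dia, "path"))
  expect_error(disease_is_super_of("diabetes", "diabetes", dia),
               class = "riverflow_argument_error")
})

test_that("matcher agrees with the exhaustive oracle on random pairs", {
  set.seed(7)
  for (i in 1:40) {
    o <- random_hierarchy_ontology(10)
    A <- random_graph(o, sample.int(5, 1) - 1L, p_edge = 0.35)
    B <- random_graph(o, sample.int(8, 1), p_edge = 0.35)
    for (mode in c("path", "strict")) {
      got <- chain_included_in(A, B, o, mode)
      want <- oracle_included(A, B, o, mode)
      expect_identical(!is.null(got), want,
                       info = sprintf("case %d mode %s", i, mode))
      if (!is.null(got)) expect_valid_witness(got, A, B, o, mode)
    }
  }
})

test_that("inclusion is reflexive, transitive, monotone; strict implies path", {
  set.seed(11)
  for (i in 1:12) {
    o <- random_hierarchy_ontology(10)
    A <- random_graph(o, 4, p_edge = 0.4)
    expect_false(is.null(chain_included_in(A, A, o, "path")))
    expect_false(is.null(chain_included_in(A, A, o, "strict")))

    B <- random_graph(o, 6, p_edge = 0.4)
    C <- random_graph(o, 8, p_edge = 0.4)
    for (mode in c("path", "strict")) {
      ab <- !is.null(chain_included_in(A, B, o, mode))
      bc <- !is.null(chain_included_in(B, C, o, mode))
      if (ab && bc)
        expect_false(is.null(chain_included_in(A, C, o, mode)))
    }
    if (!is.null(chain_included_in(A, B, o, "strict")))
      expect_false(is.null(chain_included_in(A, B, o, "path")))

    # monotonicity: enlarging B never destroys a witness
    if (!is.null(chain_included_in(A, B, o, "path"))) {
      extra <- setdiff(names(o$states), B$states)
      if (length(extra)) {
        B2 <- causal_graph(c(B$states, extra[1]), B$links, B$branch_mode)
        expect_false(is.null(chain_included_in(A, B2, o, "path")))
      }
      if (nrow(B$links) == 0L && length(B$states) >= 2) {
        B3 <- causal_graph(B$states,
                           causal_links(B$states[1], B$states[2]))
        expect_false(is.null(chain_included_in(A, B3, o, "path")))
      }
    }
  }
})

test_that("unknown nodes map only to unknown nodes", {
  o <- disease_ontology(states = list(
    abnormal_state("k1", level = 1),
    abnormal_state("k2", level = 1),
    abnormal_state("u1", level = 2, is_unknown = TRUE),
    abnormal_state("u2", level = 2, is_unknown = TRUE)))
  A <- causal_graph("u1")
  expect_null(chain_included_in(A, causal_graph(c("k1", "k2")), o))
  w <- chain_included_in(A, causal_graph(c("k1", "u2")), o)
  expect_identical(unname(w$node_map), "u2")
  # and a known node never maps onto an unknown one
  expect_null(chain_included_in(causal_graph("k1"), causal_graph("u2"), o))
})

test_that("witnesses are deterministic across runs", {
  set.seed(3)
  o <- random_hierarchy_ontology(10)
  A <- random_graph(o, 4, p_edge = 0.5)
  B <- random_graph(o, 8, p_edge = 0.5)
  w1 <- chain_included_in(A, B, o, "path")
  w2 <- chain_included_in(A, B, o, "path")
  expect_identical(w1, w2)
})
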