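dia <- fixture_diabetes()

test_that("effective_states aggregates over super-diseases", {
  expect_setequal(
    effective_states("type_I_diabetes", "core", dia),
    c("destruction_of_pancreatic_beta_cells", "lack_of_insulin_in_blood",
      "deficiency_of_insulin", "elevated_glucose_in_blood"))
  expect_setequal(effective_states("diabetes", "core", dia),
                  c("deficiency_of_insulin", "elevated_glucose_in_blood"))
  empty <- disease_ontology(diseases = list(disease("lonely")))
  expect_identical(effective_states("lonely", "all", empty), character())
  expect_error(effective_states("ghost", "all", dia),
               class = "riverflow_id_error")
})

test_that("chain_graph induces the global links on the aggregated states", {
  g <- chain_graph("type_I_diabetes", "all", dia)
  expect_length(g$states, 4L)
  expect_identical(nrow(g$links), 3L)  # a 4-node path
  deg_out <- table(factor(g$links$cause, levels = g$states))
  expect_true(all(deg_out <= 1))

  g2 <- chain_graph("diabetes", "core", dia)
  expect_identical(g2$states,
                   sort(c("deficiency_of_insulin", "elevated_glucose_in_blood")))
  expect_identical(nrow(g2$links), 1L)

  iso <- disease_ontology(
    states = list(abnormal_state("a", level = 1), abnormal_state("b", level = 1)),
    diseases = list(disease("d", core_states = c("a", "b"))))
  g3 <- chain_graph("d", "all", iso)
  expect_length(g3$states, 2L)
  expect_identical(nrow(g3$links), 0L)
})

test_that("upstream/downstream closures trace the general graph and terminate on cycles", {
  gg <- general_graph(dia)
  down <- downstream_closure("deficiency_of_insulin", gg)
  expect_true(all(c("elevated_glucose_in_blood", "loss_of_sight") %in%
                    down$states))
  expect_false("long_term_steroid_treatment" %in% down$states)
  up <- upstream_closure("deficiency_of_insulin", gg)
  expect_true(all(c("long_term_steroid_treatment",
                    "destruction_of_pancreatic_beta_cells") %in% up$states))
  expect_false("loss_of_sight" %in% up$states)

  iso <- causal_graph("x")
  expect_identical(downstream_closure("x", iso)$states, "x")

  cyc <- disease_ontology(
    states = lapply(c("a", "b", "c"), abnormal_state, level = 1),
    links = causal_links(c("a", "b", "c"), c("b", "c", "a")))
  g <- general_graph(cyc)
  expect_setequal(downstream_closure("a", g)$states, c("a", "b", "c"))
  expect_setequal(upstream_closure("a", g)$states, c("a", "b", "c"))
  expect_identical(downstream_closure("a", g, max_depth = 1)$states,
                   sort(c("a", "b")))
  expect_error(downstream_closure("zz", g), class = "riverflow_id_error")
})

test_that("general_graph is the union of all authored links", {
  gg <- general_graph(dia)
  expect_setequal(gg$states, names(dia$states))
  expect_identical(nrow(gg$links), nrow(dia$links))
  chain_states <- unique(c(gg$links$cause, gg$links$effect))
  comp <- graph_components(gg)
  expect_identical(length(unique(comp[chain_states])), 1L)

  expect_length(general_graph(disease_ontology())$states, 0L)
  plus <- disease_ontology(states = c(unname(dia$states),
                                      list(abnormal_state("isolated", level = 1))),
                           diseases = unname(dia$diseases), links = dia$links)
  gp <- general_graph(plus)
  expect_true("isolated" %in% gp$states)
  expect_false("isolated" %in% c(gp$links$cause, gp$links$effect))
})

test_that("diseases_containing honours aggregation and the descendants flag", {
  expect_identical(
    diseases_containing("deficiency_of_insulin", dia),
    sort(c("diabetes", "type_I_diabetes", "steroid_diabetes",
           "diabetes_caused_blindness")))
  expect_identical(diseases_containing("loss_of_sight", dia),
                   "diabetes_caused_blindness")

  # descendants flag: disease uses the specific state, query the general one
  sten <- fixture_stenosis_hierarchy()
  sten2 <- disease_ontology(
    states = unname(sten$states),
    diseases = list(disease("cad", core_states = "coronary_artery_stenosis")))
  expect_identical(diseases_containing("vascular_stenosis", sten2, TRUE), "cad")
  expect_identical(diseases_containing("vascular_stenosis", sten2, FALSE),
                   character())
  expect_true(all(diseases_containing("vascular_stenosis", sten2, FALSE) %in%
                    diseases_containing("vascular_stenosis", sten2, TRUE)))
})

test_that("graph exports are well-formed", {
  g <- chain_graph("type_I_diabetes", "all", dia)
  tsv <- graph_as_tsv(g)
  expect_identical(tsv[1], "cause\teffect\tprobable")
  expect_length(tsv, 1L + nrow(g$links))
  dot <- graph_as_dot(g, dia)
  expect_identical(dot[1], "digraph causal_chain {")
  expect_identical(dot[length(dot)], "}")
  expect_identical(sum(grepl(" -> ", dot, fixed = TRUE)), nrow(g$links))
})
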