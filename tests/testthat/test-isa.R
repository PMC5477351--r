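dia <- fixture_diabetes()

test_that("is-a inference recovers the diabetes family", {
  isa <- infer_isa_hierarchy(dia, "path")
  expect_setequal(pair_key(isa$pairs),
                  c("type_I_diabetes diabetes", "steroid_diabetes diabetes",
                    "diabetes_caused_blindness diabetes"))
  expect_identical(isa$pairs, isa$reduced_pairs)  # flat family
  expect_identical(nrow(isa$equivalences), 0L)
  expect_identical(nrow(isa$discrepancies), 0L)
})

test_that("single-disease and equivalent-chain ontologies behave", {
  one <- disease_ontology(diseases = list(disease("solo")))
  isa <- infer_isa_hierarchy(one)
  expect_identical(nrow(isa$pairs), 0L)

  # two diseases with identical chains: an equivalence, not a cycle
  o <- disease_ontology(
    states = list(abnormal_state("a", level = 1),
                  abnormal_state("b", level = 1)),
    diseases = list(disease("d1", core_states = c("a", "b")),
                    disease("d2", core_states = c("a", "b"))),
    links = causal_links("a", "b"))
  isa <- infer_isa_hierarchy(o)
  expect_identical(nrow(isa$pairs), 0L)
  expect_identical(nrow(isa$equivalences), 1L)
  expect_setequal(c(isa$equivalences$a, isa$equivalences$b), c("d1", "d2"))
})

test_that("declared-but-unconfirmed subDiseaseOf is reported as a discrepancy", {
  # aggregation guarantees a declared subclass contains its super's chain,
  # so a declared pair can only fail the inferred test when the two chains
  # are indistinguishable (the subclass authors nothing of its own): the
  # pair lands in `equivalences` and is flagged as a discrepancy
  o <- disease_ontology(
    states = list(abnormal_state("a", level = 1),
                  abnormal_state("b", level = 1)),
    diseases = list(
      disease("p", core_states = "a"),
      disease("q", core_states = "b", supers = "p")))
  isa <- infer_isa_hierarchy(o)
  expect_identical(nrow(isa$discrepancies), 0L)
  expect_identical(pair_key(isa$pairs), "q p")

  o2 <- disease_ontology(
    states = list(abnormal_state("a", level = 1)),
    diseases = list(disease("p", core_states = "a"),
                    disease("q", supers = "p")))
  isa2 <- infer_isa_hierarchy(o2)
  expect_identical(nrow(isa2$equivalences), 1L)
  expect_identical(pair_key(isa2$discrepancies), "q p")
})

test_that("closure(reduced_pairs) equals pairs on deep synthetic trees", {
  gen <- generate_ontology(generator_config(n_diseases = 15, seed = 5,
                                            hierarchy_depth = 4))
  isa <- infer_isa_hierarchy(gen$ontology)
  closure <- riverflow:::transitive_closure_pairs(isa$reduced_pairs)
  expect_setequal(pair_key(closure), pair_key(isa$pairs))
  expect_true(all(pair_key(isa$reduced_pairs) %in% pair_key(isa$pairs)))
  # antisymmetry: no pair together with its reverse
  rev_keys <- paste(isa$pairs$super, isa$pairs$sub)
  expect_false(any(pair_key(isa$pairs) %in% rev_keys))
})

test_that("core_causal_chain extracts the printed diabetes core", {
  g <- core_causal_chain("diabetes", dia)
  expect_setequal(g$states,
                  c("deficiency_of_insulin", "elevated_glucose_in_blood"))
  expect_identical(nrow(g$links), 1L)
  expect_identical(g$links$cause, "deficiency_of_insulin")
  expect_identical(g$links$effect, "elevated_glucose_in_blood")
})

test_that("leaf diseases fall back to their declared core chain", {
  g <- core_causal_chain("type_I_diabetes", dia)
  expect_identical(g$states,
                   effective_states("type_I_diabetes", "core", dia))
})

test_that("per-element filtering drops uncovered states and their links", {
  # standalone subclasses: one of them lacks elevated_glucose_in_blood
  sts <- unname(fixture_diabetes()$states)
  o <- disease_ontology(
    states = sts,
    diseases = list(
      disease("diabetes", core_states = c("deficiency_of_insulin",
                                          "elevated_glucose_in_blood")),
      disease("subA", core_states = c("destruction_of_pancreatic_beta_cells",
                                      "lack_of_insulin_in_blood",
                                      "deficiency_of_insulin",
                                      "elevated_glucose_in_blood")),
      disease("subB", core_states = c("long_term_steroid_treatment",
                                      "deficiency_of_insulin"))),
    links = fixture_diabetes()$links)
  g <- core_causal_chain("diabetes", o, subclasses = c("subA", "subB"))
  expect_identical(g$states, "deficiency_of_insulin")
  expect_identical(nrow(g$links), 0L)
})

test_that("validate_core_against_subclasses reports uncovered elements", {
  expect_identical(nrow(validate_core_against_subclasses("diabetes", dia)), 0L)
  expect_identical(
    nrow(validate_core_against_subclasses("type_I_diabetes", dia)), 0L)

  sts <- unname(fixture_diabetes()$states)
  o <- disease_ontology(
    states = sts,
    diseases = list(
      disease("diabetes", core_states = c("deficiency_of_insulin",
                                          "elevated_glucose_in_blood")),
      disease("subB", core_states = c("long_term_steroid_treatment",
                                      "deficiency_of_insulin"))),
    links = fixture_diabetes()$links)
  v <- validate_core_against_subclasses("diabetes", o, subclasses = "subB")
  expect_true(nrow(v) >= 1L)
  expect_true(all(v$subclass == "subB"))
  expect_true("elevated_glucose_in_blood" %in% v$element[v$kind == "state"])
})
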