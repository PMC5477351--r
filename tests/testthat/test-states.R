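rules <- fixture_interop_rules()

test_that("quantize applies the tabled intervals", {
  ql <- quantize(quantitative_form("blood", "pressure", 180, "mmHg"), rules)
  expect_identical(ql$qualitative_value, "high")
  expect_identical(ql$object, "blood")

  ql2 <- quantize(quantitative_form("artery", "cross-sectional area", 5,
                                    "mm^2"), rules)
  expect_identical(ql2$qualitative_value, "small")

  expect_error(quantize(quantitative_form("bone", "density", 1, "g/cm^3"),
                        rules), class = "riverflow_missing_rule")
  expect_error(quantize(quantitative_form("blood", "pressure", 180, "kPa"),
                        rules), class = "riverflow_unit_error")
  expect_error(quantize(quantitative_form("blood", "pressure", -5, "mmHg"),
                        rules), class = "riverflow_out_of_range")
})

test_that("to_property / to_qualitative realize the published triples", {
  expect_identical(
    to_property(qualitative_form("blood", "pressure", "high"), rules),
    property_form("hypertension", TRUE))
  expect_identical(
    to_property(qualitative_form("artery", "cross-sectional area", "small"),
                rules),
    property_form("stenosis", TRUE))
  expect_error(to_property(qualitative_form("blood", "pressure", "soaring"),
                           rules), class = "riverflow_missing_rule")

  ql <- to_qualitative(property_form("hypertension", TRUE), rules)
  expect_identical(ql, qualitative_form("blood", "pressure", "high"))
  ql2 <- to_qualitative(property_form("colonic_polyposis", TRUE), rules)
  expect_identical(ql2,
                   qualitative_form("colon", "number", "many",
                                    sub_object = "polyp"))

  # round-trip identity on every tabled row, both directions
  pr <- rules$prop_rules
  for (i in seq_len(nrow(pr))) {
    ql <- qualitative_form(pr$object[i], pr$attribute[i],
                           pr$qualitative_value[i],
                           sub_object = pr$sub_object[i])
    expect_identical(to_qualitative(to_property(ql, rules), rules), ql)
    pf <- property_form(pr$property[i], pr$property_value[i])
    expect_identical(to_property(to_qualitative(pf, rules), rules), pf)
  }
})

test_that("interoperable compares across representation forms", {
  q180 <- quantitative_form("blood", "pressure", 180, "mmHg")
  expect_true(interoperable(q180, property_form("hypertension", TRUE), rules))
  expect_true(interoperable(q180, q180, rules))
  expect_true(interoperable(property_form("stenosis", TRUE),
                            property_form("stenosis", TRUE), rules))
  q120 <- quantitative_form("blood", "pressure", 120, "mmHg")
  expect_false(interoperable(q120, property_form("hypertension", TRUE), rules))
  # symmetry and transitivity on normalizable forms
  ql <- qualitative_form("blood", "pressure", "high")
  expect_true(interoperable(ql, q180, rules))
  expect_true(interoperable(q180, ql, rules))
  expect_error(interoperable(quantitative_form("bone", "density", 1, "x"),
                             q180, rules), class = "riverflow_missing_rule")
})

test_that("rule-table TSV round-trips and rejects overlapping intervals", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rule_table(rules, path)
  r2 <- read_rule_table(path)
  expect_identical(
    to_property(quantize(quantitative_form("blood", "pressure", 180, "mmHg"),
                         r2), r2),
    property_form("hypertension", TRUE))
  expect_identical(nrow(r2$quant_rules), nrow(rules$quant_rules))

  expect_error(rule_table(quant_rules = data.frame(
    object = "x", sub_object = NA, attribute = "a", unit = "u",
    lower = c(0, 5), upper = c(10, 15),
    qualitative_value = c("lo", "hi"))), "overlapping")
})

test_that("check_levels enforces the three-layer constraints", {
  expect_identical(nrow(check_levels(fixture_stenosis_hierarchy())), 0L)
  expect_identical(nrow(check_levels(disease_ontology())), 0L)

  bad <- disease_ontology(states = list(
    abnormal_state("g", level = 1),
    abnormal_state("orphan2", "x", object = "o", level = 2),  # no L1 ancestor
    abnormal_state("l3", "y", object = "o", level = 3, parents = "g")))
  v <- check_levels(bad)
  expect_true("orphan2" %in% v$state)
  expect_true("l3" %in% v$state)  # L3 parented only by L1

  inv <- disease_ontology(states = list(
    abnormal_state("deep", "d", object = "o", level = 3),
    abnormal_state("shallow", "s", object = "o", level = 2,
                   parents = "deep")))
  expect_true(any(grepl("greater level", check_levels(inv)$detail)))
})

test_that("match_external finds exact normalized matches only", {
  sten <- fixture_stenosis_hierarchy()
  vocabs <- fixture_vocabs()

  hits_hpo <- match_external(sten$states, vocabs$HPO, "HPO")
  expect_true("HP:0100749" %in%
                hits_hpo$external_id[hits_hpo$state == "chest_pain"])
  expect_true("HP:0005145" %in%
                hits_hpo$external_id[hits_hpo$state == "coronary_artery_stenosis"])
  expect_true(all(hits_hpo$status == "candidate"))
  expect_false(any(hits_hpo$accepted))

  hits_sno <- match_external(sten$states, vocabs$SNOMED, "SNOMED")
  expect_true("233970002" %in%
                hits_sno$external_id[hits_sno$state == "coronary_artery_stenosis"])

  # the too-abstract state matches nowhere
  for (v in names(vocabs)) {
    h <- match_external(sten$states, vocabs[[v]], v)
    expect_false("structural_abnormality" %in% h$state)
  }
  # Level-3 states match nowhere
  all_hits <- do.call(rbind, lapply(names(vocabs), function(v)
    match_external(sten$states, vocabs[[v]], v)))
  l3 <- c("coronary_artery_stenosis_in_arteriosclerosis",
          "esophageal_stenosis_in_esophagitis")
  expect_false(any(l3 %in% all_hits$state))

  expect_identical(nrow(match_external(sten$states,
                                       data.frame(id = character(),
                                                  label = character()))), 0L)
})

test_that("matching is invariant under vocab row permutation", {
  sten <- fixture_stenosis_hierarchy()
  v <- fixture_vocabs()$MeSH
  set.seed(1)
  h1 <- match_external(sten$states, v, "MeSH")
  h2 <- match_external(sten$states, v[sample.int(nrow(v)), ], "MeSH")
  rownames(h1) <- rownames(h2) <- NULL
  expect_identical(h1, h2)
})

test_that("mapping_summary counts accepted mappings per level", {
  sten <- fixture_stenosis_hierarchy()
  vocabs <- fixture_vocabs()
  cands <- do.call(rbind, lapply(names(vocabs), function(v)
    match_external(sten$states, vocabs[[v]], v)))
  tab <- mapping_summary(accept_candidates(cands), sten,
                         resources = names(vocabs))
  l3 <- tab[tab$level == "3", names(vocabs)]
  expect_true(all(l3 == 0))
  # totals row equals column sums
  for (v in intersect(names(vocabs), names(tab)))
    expect_identical(tab[[v]][tab$level == "total"],
                     sum(tab[[v]][tab$level != "total"]))

  empty <- mapping_summary(cands[0, ], sten)
  expect_identical(ncol(empty), 2L)

  # totals property on random candidate subsets, recomputed independently
  set.seed(9)
  for (i in 1:5) {
    sub <- cands[stats::runif(nrow(cands)) < 0.5, , drop = FALSE]
    sub$accepted <- stats::runif(nrow(sub)) < 0.7
    tab <- mapping_summary(sub, sten)
    for (v in setdiff(names(tab), c("level", "n_states"))) {
      acc <- sub[sub$accepted & sub$resource == v, ]
      expect_identical(tab[[v]][tab$level == "total"],
                       length(unique(acc$state)))
    }
  }
})
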