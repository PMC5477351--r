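# ---- packaged worked-example fixtures -----------------------------------

#' The diabetes worked example
#'
#' A small ontology with the classic diabetes family: diabetes (deficiency
#' of insulin -> elevated level of glucose in the blood) and three
#' subclasses that extend it - Type-I diabetes (destruction of pancreatic
#' beta cells -> lack of insulin I in the blood -> deficiency of insulin ->
#' ...), steroid diabetes (long-term steroid treatment -> ... -> deficiency
#' of insulin -> ...), and diabetes-caused blindness (... -> elevated
#' glucose -> ... -> loss of sight). Elided chain segments are realized as
#' single unknown nodes. Subclasses declare `subDiseaseOf` diabetes and
#' carry only their additional states; aggregation recovers the full
#' chains. A few generic Level-1 ancestors anchor the state hierarchy.
#'
#' @return A `disease_ontology` that passes [validate_ontology()] cleanly.
#' @export
fixture_diabetes <- function() {
  L1 <- function(id, label) abnormal_state(id, label, level = 1)
  states <- list(
    L1("hypofunction", "hypofunction"),
    L1("structural_abnormality", "structural abnormality"),
    L1("abnormal_amount_of_substance", "abnormal amount of substance"),
    L1("dysfunction", "dysfunction"),
    L1("exogenous_factor", "exogenous factor"),
    abnormal_state("deficiency_of_insulin", "deficiency of insulin",
                   object = "insulin", attribute = "functioning",
                   value = "deficient", level = 2,
                   parents = "hypofunction"),
    abnormal_state("elevated_glucose_in_blood",
                   "elevated level of glucose in the blood",
                   object = "blood", sub_object = "glucose",
                   attribute = "concentration", value = "high", level = 2,
                   parents = "abnormal_amount_of_substance"),
    abnormal_state("destruction_of_pancreatic_beta_cells",
                   "destruction of pancreatic beta cells",
                   object = "pancreatic beta cell", attribute = "structure",
                   value = "destroyed", level = 2,
                   parents = "structural_abnormality"),
    abnormal_state("lack_of_insulin_in_blood", "lack of insulin I in the blood",
                   object = "blood", sub_object = "insulin",
                   attribute = "concentration", value = "low", level = 2,
                   parents = "abnormal_amount_of_substance"),
    abnormal_state("long_term_steroid_treatment", "long-term steroid treatment",
                   object = "body", attribute = "steroid exposure",
                   value = "long-term", level = 2,
                   parents = "exogenous_factor"),
    abnormal_state("loss_of_sight", "loss of sight", object = "eye",
                   attribute = "visual function", value = "lost", level = 2,
                   parents = "dysfunction"),
    abnormal_state("unknown_steroid_pathway", "unknown", level = 2,
                   is_unknown = TRUE),
    abnormal_state("unknown_glucose_complication", "unknown", level = 2,
                   is_unknown = TRUE))
  links <- causal_links(
    cause = c("deficiency_of_insulin", "destruction_of_pancreatic_beta_cells",
              "lack_of_insulin_in_blood", "long_term_steroid_treatment",
              "unknown_steroid_pathway", "elevated_glucose_in_blood",
              "unknown_glucose_complication"),
    effect = c("elevated_glucose_in_blood", "lack_of_insulin_in_blood",
               "deficiency_of_insulin", "unknown_steroid_pathway",
               "deficiency_of_insulin", "unknown_glucose_complication",
               "loss_of_sight"))
  diseases <- list(
    disease("diabetes", "diabetes", area = "endocrinology",
            core_states = c("deficiency_of_insulin",
                            "elevated_glucose_in_blood")),
    disease("type_I_diabetes", "Type-I diabetes", area = "endocrinology",
            supers = "diabetes",
            core_states = c("destruction_of_pancreatic_beta_cells",
                            "lack_of_insulin_in_blood")),
    disease("steroid_diabetes", "steroid diabetes", area = "endocrinology",
            supers = "diabetes",
            core_states = c("long_term_steroid_treatment",
                            "unknown_steroid_pathway")),
    disease("diabetes_caused_blindness", "diabetes-caused blindness",
            area = "ophthalmology", supers = "diabetes",
            core_states = c("unknown_glucose_complication", "loss_of_sight")))
  disease_ontology(states, diseases, links)
}

#' The stenosis / mapping worked example
#'
#' A state hierarchy reproducing the is-a chain "arterial stenosis is-a
#' vascular stenosis is-a narrowing tube is-a small in area" (with a
#' coronary-artery specialization below it), together with a handful of
#' Level-1/2/3 states used by the external-mapping examples; accepted
#' external references are annotated on the states. No diseases or links:
#' this fixture exercises the states module.
#'
#' @return A `disease_ontology` (states only).
#' @export
fixture_stenosis_hierarchy <- function() {
  states <- list(
    abnormal_state("small_in_area", "small in area", level = 1),
    abnormal_state("structural_abnormality", "structural abnormality",
                   level = 1),
    abnormal_state("sensory_abnormality", "sensory abnormality", level = 1),
    abnormal_state("tube_narrowing", "narrowing tube",
                   object = "tubular structure",
                   attribute = "cross-sectional area", value = "small",
                   level = 2, parents = "small_in_area"),
    abnormal_state("vascular_stenosis", "vascular stenosis",
                   object = "blood vessel",
                   attribute = "cross-sectional area", value = "small",
                   level = 2, parents = "tube_narrowing"),
    abnormal_state("arterial_stenosis", "arterial stenosis",
                   object = "artery", attribute = "cross-sectional area",
                   value = "small", level = 2, parents = "vascular_stenosis"),
    abnormal_state("coronary_artery_stenosis", "coronary artery stenosis",
                   object = "coronary artery",
                   attribute = "cross-sectional area", value = "small",
                   level = 2, parents = "arterial_stenosis",
                   external_refs = list(HPO = "HP:0005145",
                                        MeSH = "D023921",
                                        SNOMED = "233970002")),
    abnormal_state("arterial_occlusion", "arterial occlusion",
                   object = "artery", attribute = "patency",
                   value = "occluded", level = 2,
                   parents = "structural_abnormality",
                   external_refs = list(SNOMED = "2929001")),
    abnormal_state("coronary_artery_occlusion", "coronary artery occlusion",
                   object = "coronary artery", attribute = "patency",
                   value = "occluded", level = 2,
                   parents = "arterial_occlusion",
                   external_refs = list(MeSH = "D054059",
                                        SNOMED = "63739005")),
    abnormal_state("chest_pain", "chest pain", object = "chest",
                   attribute = "sensation", value = "painful", level = 2,
                   parents = "sensory_abnormality",
                   external_refs = list(HPO = "HP:0100749", MeSH = "D002637",
                                        SNOMED = "29857009")),
    abnormal_state("cellular_tissue_necrosis", "cellular tissue necrosis",
                   object = "cellular tissue", attribute = "vitality",
                   value = "necrotic", level = 2,
                   parents = "structural_abnormality",
                   external_refs = list(PATO = "PATO:0000647",
                                        MeSH = "D009336")),
    abnormal_state("coronary_artery_stenosis_in_arteriosclerosis",
                   "coronary artery stenosis in arteriosclerosis",
                   object = "coronary artery",
                   attribute = "cross-sectional area", value = "small",
                   level = 3, parents = "coronary_artery_stenosis"),
    abnormal_state("esophageal_stenosis_in_esophagitis",
                   "esophageal stenosis in esophagitis",
                   object = "esophagus", attribute = "cross-sectional area",
                   value = "small", level = 3, parents = "tube_narrowing"))
  disease_ontology(states)
}

#' Packaged mini-vocabularies for the mapping examples
#'
#' Small id/label tables in the style of PATO, HPO, MeSH and SNOMED-CT,
#' containing the external entries of the published mapping examples.
#' Synthetic excerpts, not the real vocabularies.
#'
#' @return Named list of data.frames with columns `id`, `label`.
#' @export
fixture_vocabs <- function() {
  v <- function(id, label)
    data.frame(id = id, label = label, stringsAsFactors = FALSE)
  list(
    PATO = v(c("PATO:0000386", "PATO:0000586", "PATO:0000647",
               "PATO:0001625", "PATO:0002037"),
             c("hard", "increased size", "necrotic",
               "increased functionality", "degeneration")),
    HPO = v(c("HP:0005145", "HP:0100749"),
            c("Coronary artery stenosis", "Chest pain")),
    MeSH = v(c("D002637", "D009069", "D009336", "D023921", "D054059"),
             c("Chest pain", "Movement Disorders", "Necrosis",
               "Coronary Stenosis", "Coronary Occlusion")),
    SNOMED = v(c("233970002", "29857009", "2929001", "63739005"),
               c("Coronary artery stenosis", "Chest pain",
                 "Occlusion of artery", "Coronary occlusion")))
}

#' The interoperability rule-table fixture
#'
#' Covers the published conversion examples: blood pressure (mmHg) ->
#' hypertension, arterial cross-sectional area (mm^2) -> stenosis, blood
#' glucose concentration (mg/dL) -> hyperglycemia, and colonic polyp number
#' -> colonic polyposis. The numeric cut-points (140 mmHg, 10 mm^2,
#' 126 mg/dL, 10 polyps) are fixture parameters chosen as conventional
#' clinical thresholds - the representation framework itself fixes none.
#' Each property pairs `TRUE` with the abnormal category and `FALSE` with
#' the normal one, so normal measurements normalize without error.
#'
#' @return A `rule_table`.
#' @export
fixture_interop_rules <- function() {
  qr <- function(object, sub_object, attribute, unit, lower, upper, value)
    data.frame(object = object, sub_object = sub_object,
               attribute = attribute, unit = unit, lower = lower,
               upper = upper, qualitative_value = value,
               stringsAsFactors = FALSE)
  quant <- rbind(
    qr("blood", NA, "pressure", "mmHg", 0, 140, "normal"),
    qr("blood", NA, "pressure", "mmHg", 140, Inf, "high"),
    qr("artery", NA, "cross-sectional area", "mm^2", 0, 10, "small"),
    qr("artery", NA, "cross-sectional area", "mm^2", 10, Inf, "normal"),
    qr("blood", "glucose", "concentration", "mg/dL", 0, 126, "normal"),
    qr("blood", "glucose", "concentration", "mg/dL", 126, Inf, "high"),
    qr("colon", "polyp", "number", "count", 0, 10, "few"),
    qr("colon", "polyp", "number", "count", 10, Inf, "many"))
  pr <- function(object, sub_object, attribute, value, property, pv)
    data.frame(object = object, sub_object = sub_object,
               attribute = attribute, qualitative_value = value,
               property = property, property_value = pv,
               stringsAsFactors = FALSE)
  prop <- rbind(
    pr("blood", NA, "pressure", "high", "hypertension", TRUE),
    pr("blood", NA, "pressure", "normal", "hypertension", FALSE),
    pr("artery", NA, "cross-sectional area", "small", "stenosis", TRUE),
    pr("artery", NA, "cross-sectional area", "normal", "stenosis", FALSE),
    pr("blood", "glucose", "concentration", "high", "hyperglycemia", TRUE),
    pr("blood", "glucose", "concentration", "normal", "hyperglycemia", FALSE),
    pr("colon", "polyp", "number", "many", "colonic_polyposis", TRUE),
    pr("colon", "polyp", "number", "few", "colonic_polyposis", FALSE))
  rule_table(quant, prop)
}
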