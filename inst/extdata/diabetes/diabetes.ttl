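@prefix dont: <http://purl.example.org/diseasechain/> .
@prefix ext: <http://purl.example.org/diseasechain/ext/> .
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .

dont:abnormal_amount_of_substance rdf:type dont:Abnormal_State .
dont:abnormal_amount_of_substance rdfs:label "abnormal amount of substance" .
dont:deficiency_of_insulin ext:attribute "functioning" .
dont:deficiency_of_insulin ext:level "2" .
dont:deficiency_of_insulin ext:object "insulin" .
dont:deficiency_of_insulin ext:value "deficient" .
dont:deficiency_of_insulin dont:hasCause dont:lack_of_insulin_in_blood .
dont:deficiency_of_insulin dont:hasCause dont:unknown_steroid_pathway .
dont:deficiency_of_insulin dont:hasResult dont:elevated_glucose_in_blood .
dont:deficiency_of_insulin dont:subStateOf dont:hypofunction .
dont:deficiency_of_insulin rdf:type dont:Abnormal_State .
dont:deficiency_of_insulin rdfs:label "deficiency of insulin" .
dont:destruction_of_pancreatic_beta_cells ext:attribute "structure" .
dont:destruction_of_pancreatic_beta_cells ext:level "2" .
dont:destruction_of_pancreatic_beta_cells ext:object "pancreatic beta cell" .
dont:destruction_of_pancreatic_beta_cells ext:value "destroyed" .
dont:destruction_of_pancreatic_beta_cells dont:hasResult dont:lack_of_insulin_in_blood .
dont:destruction_of_pancreatic_beta_cells dont:subStateOf dont:structural_abnormality .
dont:destruction_of_pancreatic_beta_cells rdf:type dont:Abnormal_State .
dont:destruction_of_pancreatic_beta_cells rdfs:label "destruction of pancreatic beta cells" .
dont:diabetes ext:area "endocrinology" .
dont:diabetes dont:hasCoreState dont:deficiency_of_insulin .
dont:diabetes dont:hasCoreState dont:elevated_glucose_in_blood .
dont:diabetes rdf:type dont:Disease .
dont:diabetes rdfs:label "diabetes" .
dont:diabetes_caused_blindness ext:area "ophthalmology" .
dont:diabetes_caused_blindness dont:hasCoreState dont:loss_of_sight .
dont:diabetes_caused_blindness dont:hasCoreState dont:unknown_glucose_complication .
dont:diabetes_caused_blindness dont:subDiseaseOf dont:diabetes .
dont:diabetes_caused_blindness rdf:type dont:Disease .
dont:diabetes_caused_blindness rdfs:label "diabetes-caused blindness" .
dont:dysfunction rdf:type dont:Abnormal_State .
dont:dysfunction rdfs:label "dysfunction" .
dont:elevated_glucose_in_blood ext:attribute "concentration" .
dont:elevated_glucose_in_blood ext:level "2" .
dont:elevated_glucose_in_blood ext:object "blood" .
dont:elevated_glucose_in_blood ext:subObject "glucose" .
dont:elevated_glucose_in_blood ext:value "high" .
dont:elevated_glucose_in_blood dont:hasCause dont:deficiency_of_insulin .
dont:elevated_glucose_in_blood dont:hasResult dont:unknown_glucose_complication .
dont:elevated_glucose_in_blood dont:subStateOf dont:abnormal_amount_of_substance .
dont:elevated_glucose_in_blood rdf:type dont:Abnormal_State .
dont:elevated_glucose_in_blood rdfs:label "elevated level of glucose in the blood" .
dont:exogenous_factor rdf:type dont:Abnormal_State .
dont:exogenous_factor rdfs:label "exogenous factor" .
dont:hypofunction rdf:type dont:Abnormal_State .
dont:hypofunction rdfs:label "hypofunction" .
dont:lack_of_insulin_in_blood ext:attribute "concentration" .
dont:lack_of_insulin_in_blood ext:level "2" .
dont:lack_of_insulin_in_blood ext:object "blood" .
dont:lack_of_insulin_in_blood ext:subObject "insulin" .
dont:lack_of_insulin_in_blood ext:value "low" .
dont:lack_of_insulin_in_blood dont:hasCause dont:destruction_of_pancreatic_beta_cells .
dont:lack_of_insulin_in_blood dont:hasResult dont:deficiency_of_insulin .
dont:lack_of_insulin_in_blood dont:subStateOf dont:abnormal_amount_of_substance .
dont:lack_of_insulin_in_blood rdf:type dont:Abnormal_State .
dont:lack_of_insulin_in_blood rdfs:label "lack of insulin I in the blood" .
dont:long_term_steroid_treatment ext:attribute "steroid exposure" .
dont:long_term_steroid_treatment ext:level "2" .
dont:long_term_steroid_treatment ext:object "body" .
dont:long_term_steroid_treatment ext:value "long-term" .
dont:long_term_steroid_treatment dont:hasResult dont:unknown_steroid_pathway .
dont:long_term_steroid_treatment dont:subStateOf dont:exogenous_factor .
dont:long_term_steroid_treatment rdf:type dont:Abnormal_State .
dont:long_term_steroid_treatment rdfs:label "long-term steroid treatment" .
dont:loss_of_sight ext:attribute "visual function" .
dont:loss_of_sight ext:level "2" .
dont:loss_of_sight ext:object "eye" .
dont:loss_of_sight ext:value "lost" .
dont:loss_of_sight dont:hasCause dont:unknown_glucose_complication .
dont:loss_of_sight dont:subStateOf dont:dysfunction .
dont:loss_of_sight rdf:type dont:Abnormal_State .
dont:loss_of_sight rdfs:label "loss of sight" .
dont:steroid_diabetes ext:area "endocrinology" .
dont:steroid_diabetes dont:hasCoreState dont:long_term_steroid_treatment .
dont:steroid_diabetes dont:hasCoreState dont:unknown_steroid_pathway .
dont:steroid_diabetes dont:subDiseaseOf dont:diabetes .
dont:steroid_diabetes rdf:type dont:Disease .
dont:steroid_diabetes rdfs:label "steroid diabetes" .
dont:structural_abnormality rdf:type dont:Abnormal_State .
dont:structural_abnormality rdfs:label "structural abnormality" .
dont:type_I_diabetes ext:area "endocrinology" .
dont:type_I_diabetes dont:hasCoreState dont:destruction_of_pancreatic_beta_cells .
dont:type_I_diabetes dont:hasCoreState dont:lack_of_insulin_in_blood .
dont:type_I_diabetes dont:subDiseaseOf dont:diabetes .
dont:type_I_diabetes rdf:type dont:Disease .
dont:type_I_diabetes rdfs:label "Type-I diabetes" .
dont:unknown_glucose_complication ext:isUnknown "true" .
dont:unknown_glucose_complication ext:level "2" .
dont:unknown_glucose_complication dont:hasCause dont:elevated_glucose_in_blood .
dont:unknown_glucose_complication dont:hasResult dont:loss_of_sight .
dont:unknown_glucose_complication rdf:type dont:Abnormal_State .
dont:unknown_glucose_complication rdfs:label "unknown" .
dont:unknown_steroid_pathway ext:isUnknown "true" .
dont:unknown_steroid_pathway ext:level "2" .
dont:unknown_steroid_pathway dont:hasCause dont:long_term_steroid_treatment .
dont:unknown_steroid_pathway dont:hasResult dont:deficiency_of_insulin .
dont:unknown_steroid_pathway rdf:type dont:Abnormal_State .
dont:unknown_steroid_pathway rdfs:label "unknown" .
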