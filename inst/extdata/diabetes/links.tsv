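cause	effect	probable
deficiency_of_insulin	elevated_glucose_in_blood	false
destruction_of_pancreatic_beta_cells	lack_of_insulin_in_blood	false
elevated_glucose_in_blood	unknown_glucose_complication	false
lack_of_insulin_in_blood	deficiency_of_insulin	false
long_term_steroid_treatment	unknown_steroid_pathway	false
unknown_glucose_complication	loss_of_sight	false
unknown_steroid_pathway	deficiency_of_insulin	false
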