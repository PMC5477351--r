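id	label	area	supers	core_states	derived_states
diabetes	diabetes	endocrinology		deficiency_of_insulin|elevated_glucose_in_blood	
diabetes_caused_blindness	diabetes-caused blindness	ophthalmology	diabetes	unknown_glucose_complication|loss_of_sight	
steroid_diabetes	steroid diabetes	endocrinology	diabetes	long_term_steroid_treatment|unknown_steroid_pathway	
type_I_diabetes	Type-I diabetes	endocrinology	diabetes	destruction_of_pancreatic_beta_cells|lack_of_insulin_in_blood	
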