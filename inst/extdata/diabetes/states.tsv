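id	label	level	object	sub_object	attribute	value	parents	is_unknown	external_refs
abnormal_amount_of_substance	abnormal amount of substance	1						false	
deficiency_of_insulin	deficiency of insulin	2	insulin		functioning	deficient	hypofunction	false	
destruction_of_pancreatic_beta_cells	destruction of pancreatic beta cells	2	pancreatic beta cell		structure	destroyed	structural_abnormality	false	
dysfunction	dysfunction	1						false	
elevated_glucose_in_blood	elevated level of glucose in the blood	2	blood	glucose	concentration	high	abnormal_amount_of_substance	false	
exogenous_factor	exogenous factor	1						false	
hypofunction	hypofunction	1						false	
lack_of_insulin_in_blood	lack of insulin I in the blood	2	blood	insulin	concentration	low	abnormal_amount_of_substance	false	
long_term_steroid_treatment	long-term steroid treatment	2	body		steroid exposure	long-term	exogenous_factor	false	
loss_of_sight	loss of sight	2	eye		visual function	lost	dysfunction	false	
structural_abnormality	structural abnormality	1						false	
unknown_glucose_complication	unknown	2						true	
unknown_steroid_pathway	unknown	2						true	
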