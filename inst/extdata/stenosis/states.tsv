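id	label	level	object	sub_object	attribute	value	parents	is_unknown	external_refs
arterial_occlusion	arterial occlusion	2	artery		patency	occluded	structural_abnormality	false	SNOMED=2929001
arterial_stenosis	arterial stenosis	2	artery		cross-sectional area	small	vascular_stenosis	false	
cellular_tissue_necrosis	cellular tissue necrosis	2	cellular tissue		vitality	necrotic	structural_abnormality	false	MeSH=D009336|PATO=PATO:0000647
chest_pain	chest pain	2	chest		sensation	painful	sensory_abnormality	false	HPO=HP:0100749|MeSH=D002637|SNOMED=29857009
coronary_artery_occlusion	coronary artery occlusion	2	coronary artery		patency	occluded	arterial_occlusion	false	MeSH=D054059|SNOMED=63739005
coronary_artery_stenosis	coronary artery stenosis	2	coronary artery		cross-sectional area	small	arterial_stenosis	false	HPO=HP:0005145|MeSH=D023921|SNOMED=233970002
coronary_artery_stenosis_in_arteriosclerosis	coronary artery stenosis in arteriosclerosis	3	coronary artery		cross-sectional area	small	coronary_artery_stenosis	false	
esophageal_stenosis_in_esophagitis	esophageal stenosis in esophagitis	3	esophagus		cross-sectional area	small	tube_narrowing	false	
sensory_abnormality	sensory abnormality	1						false	
small_in_area	small in area	1						false	
structural_abnormality	structural abnormality	1						false	
tube_narrowing	narrowing tube	2	tubular structure		cross-sectional area	small	small_in_area	false	
vascular_stenosis	vascular stenosis	2	blood vessel		cross-sectional area	small	tube_narrowing	false	
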