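kind	object	sub_object	attribute	unit	lower	upper	qualitative_value	property	property_value
interval	blood		pressure	mmHg	0	140	normal		
interval	blood		pressure	mmHg	140	Inf	high		
interval	artery		cross-sectional area	mm^2	0	10	small		
interval	artery		cross-sectional area	mm^2	10	Inf	normal		
interval	blood	glucose	concentration	mg/dL	0	126	normal		
interval	blood	glucose	concentration	mg/dL	126	Inf	high		
interval	colon	polyp	number	count	0	10	few		
interval	colon	polyp	number	count	10	Inf	many		
property	blood		pressure				high	hypertension	true
property	blood		pressure				normal	hypertension	false
property	artery		cross-sectional area				small	stenosis	true
property	artery		cross-sectional area				normal	stenosis	false
property	blood	glucose	concentration				high	hyperglycemia	true
property	blood	glucose	concentration				normal	hyperglycemia	false
property	colon	polyp	number				many	colonic_polyposis	true
property	colon	polyp	number				few	colonic_polyposis	false
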