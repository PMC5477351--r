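@prefix dont: <http://purl.example.org/diseasechain/> .
@prefix ext: <http://purl.example.org/diseasechain/ext/> .
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .

dont:arterial_occlusion ext:attribute "patency" .
dont:arterial_occlusion ext:externalRef "SNOMED=2929001" .
dont:arterial_occlusion ext:level "2" .
dont:arterial_occlusion ext:object "artery" .
dont:arterial_occlusion ext:value "occluded" .
dont:arterial_occlusion dont:subStateOf dont:structural_abnormality .
dont:arterial_occlusion rdf:type dont:Abnormal_State .
dont:arterial_occlusion rdfs:label "arterial occlusion" .
dont:arterial_stenosis ext:attribute "cross-sectional area" .
dont:arterial_stenosis ext:level "2" .
dont:arterial_stenosis ext:object "artery" .
dont:arterial_stenosis ext:value "small" .
dont:arterial_stenosis dont:subStateOf dont:vascular_stenosis .
dont:arterial_stenosis rdf:type dont:Abnormal_State .
dont:arterial_stenosis rdfs:label "arterial stenosis" .
dont:cellular_tissue_necrosis ext:attribute "vitality" .
dont:cellular_tissue_necrosis ext:externalRef "MeSH=D009336" .
dont:cellular_tissue_necrosis ext:externalRef "PATO=PATO:0000647" .
dont:cellular_tissue_necrosis ext:level "2" .
dont:cellular_tissue_necrosis ext:object "cellular tissue" .
dont:cellular_tissue_necrosis ext:value "necrotic" .
dont:cellular_tissue_necrosis dont:subStateOf dont:structural_abnormality .
dont:cellular_tissue_necrosis rdf:type dont:Abnormal_State .
dont:cellular_tissue_necrosis rdfs:label "cellular tissue necrosis" .
dont:chest_pain ext:attribute "sensation" .
dont:chest_pain ext:externalRef "HPO=HP:0100749" .
dont:chest_pain ext:externalRef "MeSH=D002637" .
dont:chest_pain ext:externalRef "SNOMED=29857009" .
dont:chest_pain ext:level "2" .
dont:chest_pain ext:object "chest" .
dont:chest_pain ext:value "painful" .
dont:chest_pain dont:subStateOf dont:sensory_abnormality .
dont:chest_pain rdf:type dont:Abnormal_State .
dont:chest_pain rdfs:label "chest pain" .
dont:coronary_artery_occlusion ext:attribute "patency" .
dont:coronary_artery_occlusion ext:externalRef "MeSH=D054059" .
dont:coronary_artery_occlusion ext:externalRef "SNOMED=63739005" .
dont:coronary_artery_occlusion ext:level "2" .
dont:coronary_artery_occlusion ext:object "coronary artery" .
dont:coronary_artery_occlusion ext:value "occluded" .
dont:coronary_artery_occlusion dont:subStateOf dont:arterial_occlusion .
dont:coronary_artery_occlusion rdf:type dont:Abnormal_State .
dont:coronary_artery_occlusion rdfs:label "coronary artery occlusion" .
dont:coronary_artery_stenosis ext:attribute "cross-sectional area" .
dont:coronary_artery_stenosis ext:externalRef "HPO=HP:0005145" .
dont:coronary_artery_stenosis ext:externalRef "MeSH=D023921" .
dont:coronary_artery_stenosis ext:externalRef "SNOMED=233970002" .
dont:coronary_artery_stenosis ext:level "2" .
dont:coronary_artery_stenosis ext:object "coronary artery" .
dont:coronary_artery_stenosis ext:value "small" .
dont:coronary_artery_stenosis dont:subStateOf dont:arterial_stenosis .
dont:coronary_artery_stenosis rdf:type dont:Abnormal_State .
dont:coronary_artery_stenosis rdfs:label "coronary artery stenosis" .
dont:coronary_artery_stenosis_in_arteriosclerosis ext:attribute "cross-sectional area" .
dont:coronary_artery_stenosis_in_arteriosclerosis ext:level "3" .
dont:coronary_artery_stenosis_in_arteriosclerosis ext:object "coronary artery" .
dont:coronary_artery_stenosis_in_arteriosclerosis ext:value "small" .
dont:coronary_artery_stenosis_in_arteriosclerosis dont:subStateOf dont:coronary_artery_stenosis .
dont:coronary_artery_stenosis_in_arteriosclerosis rdf:type dont:Abnormal_State .
dont:coronary_artery_stenosis_in_arteriosclerosis rdfs:label "coronary artery stenosis in arteriosclerosis" .
dont:esophageal_stenosis_in_esophagitis ext:attribute "cross-sectional area" .
dont:esophageal_stenosis_in_esophagitis ext:level "3" .
dont:esophageal_stenosis_in_esophagitis ext:object "esophagus" .
dont:esophageal_stenosis_in_esophagitis ext:value "small" .
dont:esophageal_stenosis_in_esophagitis dont:subStateOf dont:tube_narrowing .
dont:esophageal_stenosis_in_esophagitis rdf:type dont:Abnormal_State .
dont:esophageal_stenosis_in_esophagitis rdfs:label "esophageal stenosis in esophagitis" .
dont:sensory_abnormality rdf:type dont:Abnormal_State .
dont:sensory_abnormality rdfs:label "sensory abnormality" .
dont:small_in_area rdf:type dont:Abnormal_State .
dont:small_in_area rdfs:label "small in area" .
dont:structural_abnormality rdf:type dont:Abnormal_State .
dont:structural_abnormality rdfs:label "structural abnormality" .
dont:tube_narrowing ext:attribute "cross-sectional area" .
dont:tube_narrowing ext:level "2" .
dont:tube_narrowing ext:object "tubular structure" .
dont:tube_narrowing ext:value "small" .
dont:tube_narrowing dont:subStateOf dont:small_in_area .
dont:tube_narrowing rdf:type dont:Abnormal_State .
dont:tube_narrowing rdfs:label "narrowing tube" .
dont:vascular_stenosis ext:attribute "cross-sectional area" .
dont:vascular_stenosis ext:level "2" .
dont:vascular_stenosis ext:object "blood vessel" .
dont:vascular_stenosis ext:value "small" .
dont:vascular_stenosis dont:subStateOf dont:tube_narrowing .
dont:vascular_stenosis rdf:type dont:Abnormal_State .
dont:vascular_stenosis rdfs:label "vascular stenosis" .
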