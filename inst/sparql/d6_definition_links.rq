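PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX dont: <http://purl.example.org/diseasechain/>
SELECT ?s ?p ?o WHERE { <dis_id> dont:subDiseaseOf* ?d1 . ?d1 (dont:hasCoreState|dont:hasDerivedState) ?s . <dis_id> dont:subDiseaseOf* ?d2 . ?d2 (dont:hasCoreState|dont:hasDerivedState) ?o . ?s ?p ?o . FILTER (?p IN (dont:hasCause, dont:hasResult, dont:hasProbableCause, dont:hasProbableResult)) }
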