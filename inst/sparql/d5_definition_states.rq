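PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX dont: <http://purl.example.org/diseasechain/>
SELECT ?state WHERE { <dis_id> dont:subDiseaseOf* ?d . ?d (dont:hasCoreState|dont:hasDerivedState) ?state . }
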