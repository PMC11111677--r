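<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic stand-in ontology for the metadata-sheet exporter: declares
     the class and property shapes the RDF/OWL individuals export consumes.
     Not an authored domain ontology. -->
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
         xmlns:owl="http://www.w3.org/2002/07/owl#"
         xml:base="http://example.org/metadatasheet">
  <owl:Ontology rdf:about="http://example.org/metadatasheet"/>

  <owl:Class rdf:about="http://example.org/metadatasheet#Metadatasheet">
    <rdfs:label>Metadatasheet</rdfs:label>
  </owl:Class>
  <owl:Class rdf:about="http://example.org/metadatasheet#MeasuredUnit">
    <rdfs:label>measured unit</rdfs:label>
  </owl:Class>

  <owl:ObjectProperty rdf:about="http://example.org/metadatasheet#partOfSheet">
    <rdfs:label>part of sheet</rdfs:label>
  </owl:ObjectProperty>

  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#name"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#affiliation"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#email"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#project_title"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#experimental_system"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#line"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#genotype"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#tissue"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#sex"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#diet"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#treatment"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#age"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#temperature"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#other"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#measurement_type"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#instrument"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#library_prep"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#used_facility">
    <rdfs:label>used facility</rdfs:label>
  </owl:DatatypeProperty>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#cell_type">
    <rdfs:label>cell type</rdfs:label>
  </owl:DatatypeProperty>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#protocol"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#date"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#timepoints"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#personal_ID"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#final_group"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#replicate"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#subsamples"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#subsubsamples"/>
  <owl:DatatypeProperty rdf:about="http://example.org/metadatasheet#instance"/>
</rdf:RDF>
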