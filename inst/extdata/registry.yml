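# Built-in dataset registry: numeric ids are assigned in file order, so this
# file is the reproducibility anchor for builds. `spec` entries use the same
# shapes as default_registry().
relations:
  taxchild: taxonomy
datasets:
  - name: taxonomy
    format: xml
    spec:
      record_element: taxon
      id: {from: attr, attr: id}
      attrs:
        scientific_name: {path: name, from: text, type: s}
        rank: {from: attr, attr: rank, type: s}
      keywords:
        - {path: name, from: text}
      xrefs:
        - {from: attr, attr: parent, target: taxonomy, forward: no,
           reverse: yes, reverse_label: taxchild}
  - name: ensembl
    format: gff3
    spec: ~
  - name: transcript
    format: gff3
    spec: ~
  - name: uniprot
    format: xml
    spec:
      record_element: entry
      id: {path: accession, from: text}
      attrs:
        reviewed: {from: attr, attr: reviewed, type: b}
        names: {path: protein/name, from: text, many: yes, type: s}
      keywords: []
      xrefs:
        - {path: dbReference, target_attr: type, id_attr: id,
           forward: yes, reverse_targets: ensembl}
  - name: go
    format: tsv
    spec:
      header: yes
      id_col: 1
      attrs:
        name: {col: 2, type: s}
        type: {col: 3, type: s}
      xrefs: []
      keywords: []
  - name: hgnc
    format: json
    spec:
      path: response.docs
      id_field: hgnc_id
      attrs:
        symbol: {field: symbol, type: s}
      keywords: [symbol]
      xrefs:
        - {field: ensembl_gene_id, target: ensembl, forward: yes, reverse: yes}
  - name: affy_hg_u133_plus_2
    format: tsv
    spec:
      header: no
      id_col: 1
      attrs: {}
      xrefs:
        - {col: 2, target: transcript, forward: yes, reverse: yes, split: ","}
      keywords: []
  - name: literature
    format: csv
    spec:
      header: yes
      id_col: 1
      attrs:
        pmcid: {col: 2, type: s}
        doi: {col: 3, type: s}
      xrefs:
        - {col: 4, target: uniprot, forward: yes, reverse: yes}
      keywords: []
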