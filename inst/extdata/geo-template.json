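{
  "version": "synthetic-config-1.0",
  "comment": "Column map for the GEO bulk-sequencing submission metadata spreadsheet. Synthetic configuration: field names follow the public GEO metadata template; edit to track template revisions.",
  "characteristics_prefix": "characteristics: ",
  "default_molecule": "total RNA",
  "mandatory_study": ["title", "contributor"],
  "mandatory_sample": ["library name", "title", "organism"]
}
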