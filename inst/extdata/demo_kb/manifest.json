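{
  "version": "demo-1.0",
  "provenance": "printed CYP2C9 excerpt, printed warfarin/azathioprine rules, synthetic TPMT panel",
  "registry": "snp_registry.tsv",
  "tables": [
    {
      "gene": "CYP2C9",
      "file": "cyp2c9.tsv"
    },
    {
      "gene": "TPMT",
      "file": "tpmt_synthetic.tsv"
    }
  ],
  "taxonomy": "taxonomy.tsv",
  "rules": [
    "rules.json"
  ]
}
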