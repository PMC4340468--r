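{
  "rules": [
    {
      "id": "rule_warfarin_fda",
      "kind": "cds",
      "drug": "warfarin",
      "source": "FDA drug label",
      "importance": "important_modification",
      "message": "0.5-2 mg warfarin per day should be considered as a starting dose range for a patient with this genotype according to the warfarin drug label",
      "when": {
        "and": [
          {
            "hap": "CYP2C9*1",
            "min": 1
          },
          {
            "hap": "CYP2C9*3",
            "min": 1
          },
          {
            "snp": "rs9923231",
            "allele": "T",
            "exactly": 2
          }
        ]
      }
    },
    {
      "id": "rule_27",
      "kind": "cds",
      "drug": "azathioprine",
      "source": "CPIC",
      "importance": "important_modification",
      "message": "If disease treatment normally starts at the “full dose”, consider starting at 30-70% of target dose (e.g., 1–1.5 mg/kg/d), and titrate based on tolerance. Allow 2–4 weeks to reach steady state after each dose adjustment.",
      "when": {
        "and": [
          {
            "hap": "TPMT*1",
            "min": 1
          },
          {
            "or": [
              {
                "hap": "TPMT*2",
                "min": 1
              },
              {
                "hap": "TPMT*3A",
                "min": 1
              },
              {
                "hap": "TPMT*3B",
                "min": 1
              },
              {
                "hap": "TPMT*3C",
                "min": 1
              },
              {
                "hap": "TPMT*4",
                "min": 1
              }
            ]
          }
        ]
      }
    },
    {
      "id": "rule_35",
      "kind": "cds",
      "drug": "azathioprine",
      "source": "Dutch Pharmacogenomics Working Group",
      "importance": "important_modification",
      "message": "Select alternative drug or reduce dose by 50%. Increase dose in response of hematologic monitoring and efficacy.",
      "when": {
        "and": [
          {
            "hap": "TPMT*1",
            "min": 1
          },
          {
            "or": [
              {
                "hap": "TPMT*2",
                "min": 1
              },
              {
                "hap": "TPMT*3",
                "min": 1
              },
              {
                "hap": "TPMT*4",
                "min": 1
              },
              {
                "hap": "TPMT*5",
                "min": 1
              },
              {
                "hap": "TPMT*6",
                "min": 1
              },
              {
                "hap": "TPMT*7",
                "min": 1
              },
              {
                "hap": "TPMT*8",
                "min": 1
              },
              {
                "hap": "TPMT*9",
                "min": 1
              },
              {
                "hap": "TPMT*10",
                "min": 1
              },
              {
                "hap": "TPMT*11",
                "min": 1
              },
              {
                "hap": "TPMT*12",
                "min": 1
              },
              {
                "hap": "TPMT*13",
                "min": 1
              },
              {
                "hap": "TPMT*14",
                "min": 1
              },
              {
                "hap": "TPMT*15",
                "min": 1
              },
              {
                "hap": "TPMT*16",
                "min": 1
              },
              {
                "hap": "TPMT*17",
                "min": 1
              },
              {
                "hap": "TPMT*18",
                "min": 1
              }
            ]
          }
        ]
      }
    },
    {
      "id": "phen_tpmt_intermediate",
      "kind": "phenotype",
      "phenotype_label": "TPMT intermediate metabolizer",
      "source": "curated demo",
      "when": {
        "and": [
          {
            "hap": "TPMT*1",
            "min": 1
          },
          {
            "or": [
              {
                "hap": "TPMT*2",
                "min": 1
              },
              {
                "hap": "TPMT*3",
                "min": 1
              },
              {
                "hap": "TPMT*4",
                "min": 1
              }
            ]
          }
        ]
      }
    }
  ]
}
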