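{
  "spec": {
    "groups": [
      {
        "group": "Porifera",
        "clade": "basal",
        "target_HYD": 0.73,
        "tsn_factor": 0.97,
        "M": 1,
        "C": 0.3,
        "alpha": 0.75,
        "MLS": 20,
        "target_TC": 1.6110771082193,
        "target_SC": 1.28886168657544,
        "target_CC": 1.27111383134246
      },
      {
        "group": "Nematoda",
        "clade": "protostome",
        "target_HYD": 0.745,
        "tsn_factor": 0.85,
        "M": 0.001,
        "C": 0.3,
        "alpha": 0.72,
        "MLS": 1,
        "target_TC": 1.4790274808455,
        "target_SC": 1.1832219846764,
        "target_CC": 1.28167780153236
      },
      {
        "group": "Aves",
        "clade": "deuterostome",
        "target_HYD": 0.58,
        "tsn_factor": 0.93,
        "M": 300,
        "C": 4.5,
        "alpha": 0.67,
        "MLS": 18,
        "target_TC": 4.23764228231509,
        "target_SC": 3.39011382585208,
        "target_CC": 1.06098861741479
      }
    ],
    "n_species": 3,
    "gene_length_scale": 0.35,
    "power_a": 0.429,
    "power_b": -4.2045,
    "noise_sd": 0.35,
    "noise_hyd": 0.015,
    "block_structure": false,
    "seed": 42
  },
  "species_targets": [
    {
      "species_id": "Porifera_sp01",
      "group": "Porifera",
      "target_TC": 2.12567686114557,
      "target_SC": 0.687046479654205,
      "target_CC": 1.44977908319736,
      "target_HYD": 0.723634139048821
    },
    {
      "species_id": "Porifera_sp02",
      "group": "Porifera",
      "target_TC": 2.00903084643764,
      "target_SC": 1.39308199604912,
      "target_CC": 1.22901347769586,
      "target_HYD": 0.730912482200549
    },
    {
      "species_id": "Porifera_sp03",
      "group": "Porifera",
      "target_TC": 2.05565767317424,
      "target_SC": 1.15788039468139,
      "target_CC": 1.1280142764454,
      "target_HYD": 0.744063502509478
    },
    {
      "species_id": "Nematoda_sp01",
      "group": "Nematoda",
      "target_TC": 1.74802803948229,
      "target_SC": 1.33988757367244,
      "target_CC": 1.18451814883161,
      "target_HYD": 0.757517327719021
    },
    {
      "species_id": "Nematoda_sp02",
      "group": "Nematoda",
      "target_TC": 1.2575718483186,
      "target_SC": 1.26105789626349,
      "target_CC": 1.37632369342611,
      "target_HYD": 0.735687775867359
    },
    {
      "species_id": "Nematoda_sp03",
      "group": "Nematoda",
      "target_TC": 1.16162265049062,
      "target_SC": 1.49346216902235,
      "target_CC": 1.44560184128631,
      "target_HYD": 0.7426129956834
    },
    {
      "species_id": "Aves_sp01",
      "group": "Aves",
      "target_TC": 4.16069150649872,
      "target_SC": 3.23494664892192,
      "target_CC": 0.65156157607398,
      "target_HYD": 0.591819825041655
    },
    {
      "species_id": "Aves_sp02",
      "group": "Aves",
      "target_TC": 4.10864001175655,
      "target_SC": 3.0682937048911,
      "target_CC": 0.977909872903311,
      "target_HYD": 0.592120599858376
    },
    {
      "species_id": "Aves_sp03",
      "group": "Aves",
      "target_TC": 4.53543426530495,
      "target_SC": 3.04361060728665,
      "target_CC": 0.975337646713382,
      "target_HYD": 0.573602056252856
    }
  ]
}
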