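{
  "culling": [
    {
      "age": 10
    }
  ],
  "edges": [
    {
      "action": "selection",
      "from": "foundersM",
      "generation_time": 0,
      "selection": {
        "criterion": "phenotype",
        "index": "main",
        "n_selected": 5
      },
      "to": "sires"
    },
    {
      "action": "reproduction",
      "from": "sires",
      "generation_time": 1,
      "reproduction": {
        "second_parent": "foundersF"
      },
      "to": "offspring"
    },
    {
      "action": "repeat",
      "from": "offspring",
      "generation_time": 1,
      "link_action": "aging",
      "repeat_count": 3,
      "to": "foundersM"
    }
  ],
  "format_version": "1.0",
  "general": {
    "litter_size": 1,
    "map": {
      "n_chromosomes": 5,
      "n_markers": 250,
      "total_length": 5
    },
    "scale": 1,
    "species": "generic"
  },
  "nodes": [
    {
      "founder": true,
      "genotyped_share": 0,
      "housing_class": "default",
      "id": "foundersM",
      "n_individuals": 20,
      "phenotyping_class": [],
      "sex": "male",
      "time_point": 0
    },
    {
      "founder": true,
      "genotyped_share": 0,
      "housing_class": "default",
      "id": "foundersF",
      "n_individuals": 40,
      "phenotyping_class": {
        "yield": 1
      },
      "sex": "female",
      "time_point": 0
    },
    {
      "founder": false,
      "genotyped_share": 0,
      "housing_class": "default",
      "id": "sires",
      "n_individuals": 5,
      "phenotyping_class": [],
      "sex": "male",
      "time_point": 0
    },
    {
      "founder": false,
      "genotyped_share": 0,
      "housing_class": "default",
      "id": "offspring",
      "n_individuals": 60,
      "phenotyping_class": {
        "yield": 1
      },
      "sex": "mixed",
      "time_point": 0
    }
  ],
  "traits": {
    "defs": [
      {
        "gsd": 10,
        "h2": 0.3,
        "id": "yield",
        "mean": 100,
        "n_qtl": 50,
        "repeatability": 0.4
      }
    ],
    "genetic_correlation": [
      1
    ],
    "indices": {
      "main": {
        "yield": 1
      }
    },
    "residual_correlation": [
      1
    ]
  }
}
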