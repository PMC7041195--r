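{
  "metabolites": [
    {
      "id": "A",
      "name": "A",
      "compartment": "c"
    },
    {
      "id": "B",
      "name": "B",
      "compartment": "c"
    },
    {
      "id": "C",
      "name": "C",
      "compartment": "c"
    }
  ],
  "reactions": [
    {
      "id": "EX_glc",
      "stoich": {
        "A": 1
      },
      "lb": 0,
      "ub": 10
    },
    {
      "id": "R1",
      "stoich": {
        "A": -1,
        "B": 1
      },
      "lb": 0,
      "ub": 1000
    },
    {
      "id": "R2",
      "stoich": {
        "A": -1,
        "C": 1
      },
      "lb": 0,
      "ub": 1000
    },
    {
      "id": "R2b",
      "stoich": {
        "A": -1,
        "C": 1
      },
      "lb": 0,
      "ub": 1000
    },
    {
      "id": "EX_bio",
      "stoich": {
        "B": -1
      },
      "lb": 0,
      "ub": 1000
    },
    {
      "id": "EX_prod",
      "stoich": {
        "C": -1
      },
      "lb": 0,
      "ub": 1000
    }
  ],
  "biomass": "EX_bio",
  "targets": [
    "EX_prod"
  ],
  "essential": [
    "EX_glc",
    "EX_bio",
    "EX_prod"
  ]
}
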