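{
  "classes": ["NoColor", "Eye1", "Eye2", "Holstein", "Watson", "FullCoat"],
  "loci": [
    {
      "name": "C",
      "chromosome": "Vu07",
      "alleles": ["C0", "C1", "C2"]
    },
    {
      "name": "W",
      "chromosome": "Vu09",
      "alleles": ["W0", "W1"]
    },
    {
      "name": "H",
      "chromosome": "Vu10",
      "alleles": ["H0", "H1"]
    }
  ],
  "series": [
    {
      "locus": "C",
      "dominance": [
        ["C2", "C0"],
        ["C2", "C1"]
      ],
      "unresolved": [
        ["C1", "C0"]
      ]
    },
    {
      "locus": "W",
      "dominance": [
        ["W1", "W0"]
      ],
      "unresolved": []
    },
    {
      "locus": "H",
      "dominance": [
        ["H1", "H0"]
      ],
      "unresolved": []
    }
  ],
  "rules": [
    {
      "when": {
        "C": "C0"
      },
      "class": "NoColor"
    },
    {
      "when": {
        "C": "C1"
      },
      "class": "Eye1"
    },
    {
      "when": {
        "C": "C2",
        "W": "W0",
        "H": "H0"
      },
      "class": "Eye2"
    },
    {
      "when": {
        "C": "C2",
        "W": "W0",
        "H": "H1"
      },
      "class": "Holstein"
    },
    {
      "when": {
        "C": "C2",
        "W": "W1",
        "H": "H0"
      },
      "class": "Watson"
    },
    {
      "when": {
        "C": "C2",
        "W": "W1",
        "H": "H1"
      },
      "class": "FullCoat"
    }
  ]
}
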