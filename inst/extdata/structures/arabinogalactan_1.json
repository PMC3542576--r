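{
  "name": "arabinogalactan_1",
  "root": 1,
  "residues": [
    {
      "id": 1,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 2,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 3,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 4,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 5,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 6,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 7,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 8,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 9,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 10,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 11,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 12,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 13,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 14,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 15,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 16,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 17,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 18,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 19,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 20,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 21,
      "sugar": "Ara",
      "ring_carbons": 5,
      "anomeric_carbon": 1,
      "backbone": false
    },
    {
      "id": 22,
      "sugar": "Ara",
      "ring_carbons": 5,
      "anomeric_carbon": 1,
      "backbone": false
    },
    {
      "id": 23,
      "sugar": "Ara",
      "ring_carbons": 5,
      "anomeric_carbon": 1,
      "backbone": false
    },
    {
      "id": 24,
      "sugar": "Ara",
      "ring_carbons": 5,
      "anomeric_carbon": 1,
      "backbone": false
    },
    {
      "id": 25,
      "sugar": "Ara",
      "ring_carbons": 5,
      "anomeric_carbon": 1,
      "backbone": false
    }
  ],
  "linkages": [
    {
      "parent": 1,
      "child": 2,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 2,
      "child": 3,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 3,
      "child": 4,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 4,
      "child": 5,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 5,
      "child": 6,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 6,
      "child": 7,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 7,
      "child": 8,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 8,
      "child": 9,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 9,
      "child": 10,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 10,
      "child": 11,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 11,
      "child": 12,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 12,
      "child": 13,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 13,
      "child": 14,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 14,
      "child": 15,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 15,
      "child": 16,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 16,
      "child": 17,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 17,
      "child": 18,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 18,
      "child": 19,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 19,
      "child": 20,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 1,
      "child": 21,
      "config": "alpha",
      "parent_carbon": 3,
      "child_carbon": 1
    },
    {
      "parent": 5,
      "child": 22,
      "config": "alpha",
      "parent_carbon": 3,
      "child_carbon": 1
    },
    {
      "parent": 10,
      "child": 23,
      "config": "alpha",
      "parent_carbon": 3,
      "child_carbon": 1
    },
    {
      "parent": 11,
      "child": 24,
      "config": "alpha",
      "parent_carbon": 3,
      "child_carbon": 1
    },
    {
      "parent": 12,
      "child": 25,
      "config": "alpha",
      "parent_carbon": 3,
      "child_carbon": 1
    }
  ]
}
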