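{
  "name": "inulin",
  "root": 1,
  "residues": [
    {
      "id": 1,
      "sugar": "Glc",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 2,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 3,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 4,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 5,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 6,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 7,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 8,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 9,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 10,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 11,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 12,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 13,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 14,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 15,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 16,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 17,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 18,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 19,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    },
    {
      "id": 20,
      "sugar": "Fru",
      "ring_carbons": 6,
      "anomeric_carbon": 2,
      "backbone": true
    }
  ],
  "linkages": [
    {
      "parent": 1,
      "child": 2,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 2,
      "child": 3,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 3,
      "child": 4,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 4,
      "child": 5,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 5,
      "child": 6,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 6,
      "child": 7,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 7,
      "child": 8,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 8,
      "child": 9,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 9,
      "child": 10,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 10,
      "child": 11,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 11,
      "child": 12,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 12,
      "child": 13,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 13,
      "child": 14,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 14,
      "child": 15,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 15,
      "child": 16,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 16,
      "child": 17,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 17,
      "child": 18,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 18,
      "child": 19,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    },
    {
      "parent": 19,
      "child": 20,
      "config": "beta",
      "parent_carbon": 1,
      "child_carbon": 2
    }
  ]
}
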