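{
  "name": "rhamnogalacturonan_1",
  "root": 1,
  "residues": [
    {
      "id": 1,
      "sugar": "GalA",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true,
      "modifications": [
        {
          "kind": "acetyl",
          "carbon": 3
        }
      ]
    },
    {
      "id": 2,
      "sugar": "Rha",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 3,
      "sugar": "GalA",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 4,
      "sugar": "Rha",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 5,
      "sugar": "GalA",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 6,
      "sugar": "Rha",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 7,
      "sugar": "GalA",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 8,
      "sugar": "Rha",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 9,
      "sugar": "GalA",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true,
      "modifications": [
        {
          "kind": "acetyl",
          "carbon": 3
        }
      ]
    },
    {
      "id": 10,
      "sugar": "Rha",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 11,
      "sugar": "GalA",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 12,
      "sugar": "Rha",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 13,
      "sugar": "GalA",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 14,
      "sugar": "Rha",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 15,
      "sugar": "GalA",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 16,
      "sugar": "Rha",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 17,
      "sugar": "GalA",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 18,
      "sugar": "Rha",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true
    },
    {
      "id": 19,
      "sugar": "GalA",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": true,
      "modifications": [
        {
          "kind": "acetyl",
          "carbon": 3
        }
      ]
    },
    {
      "id": 20,
      "sugar": "Rha",
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
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": false
    },
    {
      "id": 26,
      "sugar": "Ara",
      "ring_carbons": 5,
      "anomeric_carbon": 1,
      "backbone": false
    },
    {
      "id": 27,
      "sugar": "Ara",
      "ring_carbons": 5,
      "anomeric_carbon": 1,
      "backbone": false
    },
    {
      "id": 28,
      "sugar": "Ara",
      "ring_carbons": 5,
      "anomeric_carbon": 1,
      "backbone": false
    },
    {
      "id": 29,
      "sugar": "Ara",
      "ring_carbons": 5,
      "anomeric_carbon": 1,
      "backbone": false
    },
    {
      "id": 30,
      "sugar": "Gal",
      "ring_carbons": 6,
      "anomeric_carbon": 1,
      "backbone": false
    }
  ],
  "linkages": [
    {
      "parent": 1,
      "child": 2,
      "config": "alpha",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 2,
      "child": 3,
      "config": "alpha",
      "parent_carbon": 2,
      "child_carbon": 1
    },
    {
      "parent": 3,
      "child": 4,
      "config": "alpha",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 4,
      "child": 5,
      "config": "alpha",
      "parent_carbon": 2,
      "child_carbon": 1
    },
    {
      "parent": 5,
      "child": 6,
      "config": "alpha",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 6,
      "child": 7,
      "config": "alpha",
      "parent_carbon": 2,
      "child_carbon": 1
    },
    {
      "parent": 7,
      "child": 8,
      "config": "alpha",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 8,
      "child": 9,
      "config": "alpha",
      "parent_carbon": 2,
      "child_carbon": 1
    },
    {
      "parent": 9,
      "child": 10,
      "config": "alpha",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 10,
      "child": 11,
      "config": "alpha",
      "parent_carbon": 2,
      "child_carbon": 1
    },
    {
      "parent": 11,
      "child": 12,
      "config": "alpha",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 12,
      "child": 13,
      "config": "alpha",
      "parent_carbon": 2,
      "child_carbon": 1
    },
    {
      "parent": 13,
      "child": 14,
      "config": "alpha",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 14,
      "child": 15,
      "config": "alpha",
      "parent_carbon": 2,
      "child_carbon": 1
    },
    {
      "parent": 15,
      "child": 16,
      "config": "alpha",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 16,
      "child": 17,
      "config": "alpha",
      "parent_carbon": 2,
      "child_carbon": 1
    },
    {
      "parent": 17,
      "child": 18,
      "config": "alpha",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 18,
      "child": 19,
      "config": "alpha",
      "parent_carbon": 2,
      "child_carbon": 1
    },
    {
      "parent": 19,
      "child": 20,
      "config": "alpha",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 2,
      "child": 21,
      "config": "alpha",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 21,
      "child": 22,
      "config": "alpha",
      "parent_carbon": 5,
      "child_carbon": 1
    },
    {
      "parent": 4,
      "child": 23,
      "config": "alpha",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 23,
      "child": 24,
      "config": "alpha",
      "parent_carbon": 5,
      "child_carbon": 1
    },
    {
      "parent": 8,
      "child": 25,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 16,
      "child": 26,
      "config": "alpha",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 26,
      "child": 27,
      "config": "alpha",
      "parent_carbon": 5,
      "child_carbon": 1
    },
    {
      "parent": 18,
      "child": 28,
      "config": "alpha",
      "parent_carbon": 4,
      "child_carbon": 1
    },
    {
      "parent": 28,
      "child": 29,
      "config": "alpha",
      "parent_carbon": 5,
      "child_carbon": 1
    },
    {
      "parent": 20,
      "child": 30,
      "config": "beta",
      "parent_carbon": 4,
      "child_carbon": 1
    }
  ]
}
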