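{
  "nodes": [
    {
      "name": "DAMPs",
      "cardinality": 3,
      "scale": "intracellular",
      "role": "input"
    },
    {
      "name": "M2",
      "cardinality": 2,
      "scale": "intracellular",
      "role": "input"
    },
    {
      "name": "ROS",
      "cardinality": 2,
      "scale": "intracellular",
      "role": "output"
    },
    {
      "name": "CCL2",
      "cardinality": 3,
      "scale": "intracellular",
      "role": "output"
    },
    {
      "name": "TRIF",
      "cardinality": 3,
      "scale": "intracellular",
      "role": "internal"
    },
    {
      "name": "CD13",
      "cardinality": 2,
      "scale": "intracellular",
      "role": "internal"
    },
    {
      "name": "IRF3",
      "cardinality": 3,
      "scale": "intracellular",
      "role": "internal"
    },
    {
      "name": "IFNb",
      "cardinality": 3,
      "scale": "intracellular",
      "role": "internal"
    },
    {
      "name": "MyD88",
      "cardinality": 3,
      "scale": "intracellular",
      "role": "internal"
    },
    {
      "name": "pIRAK",
      "cardinality": 3,
      "scale": "intracellular",
      "role": "internal"
    },
    {
      "name": "NFkB",
      "cardinality": 3,
      "scale": "intracellular",
      "role": "internal"
    }
  ],
  "rules": [
    {
      "target": "ROS",
      "inputs": ["IFNb"],
      "table": [
        [
          [0],
          0
        ],
        [
          [1],
          0
        ],
        [
          [2],
          1
        ]
      ]
    },
    {
      "target": "CCL2",
      "inputs": ["NFkB"],
      "table": [
        [
          [0],
          0
        ],
        [
          [1],
          1
        ],
        [
          [2],
          2
        ]
      ]
    },
    {
      "target": "TRIF",
      "inputs": ["DAMPs", "CD13"],
      "table": [
        [
          [0, 0],
          0
        ],
        [
          [0, 1],
          0
        ],
        [
          [1, 0],
          2
        ],
        [
          [1, 1],
          1
        ],
        [
          [2, 0],
          2
        ],
        [
          [2, 1],
          2
        ]
      ]
    },
    {
      "target": "CD13",
      "inputs": ["DAMPs"],
      "table": [
        [
          [0],
          0
        ],
        [
          [1],
          1
        ],
        [
          [2],
          1
        ]
      ]
    },
    {
      "target": "IRF3",
      "inputs": ["TRIF"],
      "table": [
        [
          [0],
          0
        ],
        [
          [1],
          1
        ],
        [
          [2],
          2
        ]
      ]
    },
    {
      "target": "IFNb",
      "inputs": ["IRF3"],
      "table": [
        [
          [0],
          0
        ],
        [
          [1],
          1
        ],
        [
          [2],
          2
        ]
      ]
    },
    {
      "target": "MyD88",
      "inputs": ["DAMPs"],
      "table": [
        [
          [0],
          0
        ],
        [
          [1],
          1
        ],
        [
          [2],
          2
        ]
      ]
    },
    {
      "target": "pIRAK",
      "inputs": ["MyD88"],
      "table": [
        [
          [0],
          0
        ],
        [
          [1],
          1
        ],
        [
          [2],
          2
        ]
      ]
    },
    {
      "target": "NFkB",
      "inputs": ["pIRAK", "M2"],
      "table": [
        [
          [0, 0],
          0
        ],
        [
          [0, 1],
          0
        ],
        [
          [1, 0],
          1
        ],
        [
          [1, 1],
          0
        ],
        [
          [2, 0],
          2
        ],
        [
          [2, 1],
          2
        ]
      ]
    }
  ],
  "clamps": []
}
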