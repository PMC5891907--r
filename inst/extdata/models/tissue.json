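{
  "nodes": [
    {
      "name": "DAMPs",
      "cardinality": 3,
      "scale": "tissue",
      "role": "internal"
    },
    {
      "name": "M1",
      "cardinality": 3,
      "scale": "tissue",
      "role": "internal"
    },
    {
      "name": "M2",
      "cardinality": 2,
      "scale": "tissue",
      "role": "internal"
    },
    {
      "name": "Injury",
      "cardinality": 2,
      "scale": "tissue",
      "role": "internal"
    },
    {
      "name": "ROS",
      "cardinality": 2,
      "scale": "tissue",
      "role": "internal"
    },
    {
      "name": "CCL2",
      "cardinality": 3,
      "scale": "tissue",
      "role": "internal"
    }
  ],
  "rules": [
    {
      "target": "DAMPs",
      "inputs": ["Injury", "ROS", "M2", "DAMPs"],
      "table": [
        [
          [0, 0, 0, 0],
          0
        ],
        [
          [0, 0, 0, 1],
          0
        ],
        [
          [0, 0, 0, 2],
          0
        ],
        [
          [0, 0, 1, 0],
          0
        ],
        [
          [0, 0, 1, 1],
          0
        ],
        [
          [0, 0, 1, 2],
          0
        ],
        [
          [0, 1, 0, 0],
          1
        ],
        [
          [0, 1, 0, 1],
          1
        ],
        [
          [0, 1, 0, 2],
          2
        ],
        [
          [0, 1, 1, 0],
          0
        ],
        [
          [0, 1, 1, 1],
          0
        ],
        [
          [0, 1, 1, 2],
          0
        ],
        [
          [1, 0, 0, 0],
          1
        ],
        [
          [1, 0, 0, 1],
          1
        ],
        [
          [1, 0, 0, 2],
          2
        ],
        [
          [1, 0, 1, 0],
          0
        ],
        [
          [1, 0, 1, 1],
          0
        ],
        [
          [1, 0, 1, 2],
          0
        ],
        [
          [1, 1, 0, 0],
          2
        ],
        [
          [1, 1, 0, 1],
          2
        ],
        [
          [1, 1, 0, 2],
          2
        ],
        [
          [1, 1, 1, 0],
          1
        ],
        [
          [1, 1, 1, 1],
          1
        ],
        [
          [1, 1, 1, 2],
          1
        ]
      ]
    },
    {
      "target": "M1",
      "inputs": ["CCL2"],
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
      "target": "M2",
      "inputs": ["M1"],
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
          0
        ]
      ]
    },
    {
      "target": "Injury",
      "inputs": ["Injury", "M2"],
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
        ]
      ]
    },
    {
      "target": "ROS",
      "inputs": ["DAMPs"],
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
      "inputs": ["DAMPs", "M2"],
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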