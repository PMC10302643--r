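{
  "name": "CyPtBu2",
  "root": "P",
  "nodes": [
    {
      "id": 1,
      "element": "C"
    },
    {
      "id": 2,
      "element": "C"
    },
    {
      "id": 3,
      "element": "C"
    },
    {
      "id": 4,
      "element": "C"
    },
    {
      "id": 5,
      "element": "C"
    },
    {
      "id": 6,
      "element": "C"
    },
    {
      "id": 7,
      "element": "C"
    },
    {
      "id": 8,
      "element": "C"
    },
    {
      "id": 9,
      "element": "C"
    },
    {
      "id": 10,
      "element": "C"
    },
    {
      "id": 11,
      "element": "C"
    },
    {
      "id": 12,
      "element": "C"
    },
    {
      "id": 13,
      "element": "C"
    },
    {
      "id": 14,
      "element": "C"
    }
  ],
  "edges": [
    {
      "i": "P",
      "j": 1,
      "order": 1
    },
    {
      "i": "P",
      "j": 7,
      "order": 1
    },
    {
      "i": "P",
      "j": 11,
      "order": 1
    },
    {
      "i": 1,
      "j": 2,
      "order": 1
    },
    {
      "i": 1,
      "j": 6,
      "order": 1
    },
    {
      "i": 2,
      "j": 3,
      "order": 1
    },
    {
      "i": 3,
      "j": 4,
      "order": 1
    },
    {
      "i": 4,
      "j": 5,
      "order": 1
    },
    {
      "i": 5,
      "j": 6,
      "order": 1
    },
    {
      "i": 7,
      "j": 8,
      "order": 1
    },
    {
      "i": 7,
      "j": 9,
      "order": 1
    },
    {
      "i": 7,
      "j": 10,
      "order": 1
    },
    {
      "i": 11,
      "j": 12,
      "order": 1
    },
    {
      "i": 11,
      "j": 13,
      "order": 1
    },
    {
      "i": 11,
      "j": 14,
      "order": 1
    }
  ]
}
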