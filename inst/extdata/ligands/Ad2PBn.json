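{
  "name": "Ad2PBn",
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
    },
    {
      "id": 15,
      "element": "C"
    },
    {
      "id": 16,
      "element": "C"
    },
    {
      "id": 17,
      "element": "C"
    },
    {
      "id": 18,
      "element": "C"
    },
    {
      "id": 19,
      "element": "C"
    },
    {
      "id": 20,
      "element": "C"
    },
    {
      "id": 21,
      "element": "C"
    },
    {
      "id": 22,
      "element": "C"
    },
    {
      "id": 23,
      "element": "C"
    },
    {
      "id": 24,
      "element": "C"
    },
    {
      "id": 25,
      "element": "C"
    },
    {
      "id": 26,
      "element": "C"
    },
    {
      "id": 27,
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
      "j": 11,
      "order": 1
    },
    {
      "i": "P",
      "j": 21,
      "order": 1
    },
    {
      "i": 1,
      "j": 2,
      "order": 1
    },
    {
      "i": 1,
      "j": 3,
      "order": 1
    },
    {
      "i": 1,
      "j": 4,
      "order": 1
    },
    {
      "i": 2,
      "j": 5,
      "order": 1
    },
    {
      "i": 3,
      "j": 6,
      "order": 1
    },
    {
      "i": 4,
      "j": 7,
      "order": 1
    },
    {
      "i": 5,
      "j": 8,
      "order": 1
    },
    {
      "i": 5,
      "j": 10,
      "order": 1
    },
    {
      "i": 6,
      "j": 8,
      "order": 1
    },
    {
      "i": 6,
      "j": 9,
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
    },
    {
      "i": 12,
      "j": 15,
      "order": 1
    },
    {
      "i": 13,
      "j": 16,
      "order": 1
    },
    {
      "i": 14,
      "j": 17,
      "order": 1
    },
    {
      "i": 15,
      "j": 18,
      "order": 1
    },
    {
      "i": 15,
      "j": 20,
      "order": 1
    },
    {
      "i": 16,
      "j": 18,
      "order": 1
    },
    {
      "i": 16,
      "j": 19,
      "order": 1
    },
    {
      "i": 17,
      "j": 19,
      "order": 1
    },
    {
      "i": 17,
      "j": 20,
      "order": 1
    },
    {
      "i": 21,
      "j": 22,
      "order": 1
    },
    {
      "i": 22,
      "j": 23,
      "order": 1.5
    },
    {
      "i": 22,
      "j": 27,
      "order": 1.5
    },
    {
      "i": 23,
      "j": 24,
      "order": 1.5
    },
    {
      "i": 24,
      "j": 25,
      "order": 1.5
    },
    {
      "i": 25,
      "j": 26,
      "order": 1.5
    },
    {
      "i": 26,
      "j": 27,
      "order": 1.5
    }
  ]
}
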