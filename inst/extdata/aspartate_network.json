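{
  "pools": [
    {
      "name": "X1",
      "measured": true
    },
    {
      "name": "X2",
      "measured": true
    },
    {
      "name": "X3",
      "measured": true
    },
    {
      "name": "X4",
      "measured": true
    },
    {
      "name": "X5",
      "measured": true
    },
    {
      "name": "X6",
      "measured": true
    },
    {
      "name": "X7",
      "measured": true
    }
  ],
  "fluxes": [
    {
      "id": "EXTERNAL->X1",
      "from": "EXTERNAL",
      "to": "X1",
      "modifiers": []
    },
    {
      "id": "X1->X2",
      "from": "X1",
      "to": "X2",
      "modifiers": []
    },
    {
      "id": "X2->X3",
      "from": "X2",
      "to": "X3",
      "modifiers": []
    },
    {
      "id": "X2->X4",
      "from": "X2",
      "to": "X4",
      "modifiers": []
    },
    {
      "id": "X4->X5",
      "from": "X4",
      "to": "X5",
      "modifiers": []
    },
    {
      "id": "X5->X6",
      "from": "X5",
      "to": "X6",
      "modifiers": []
    },
    {
      "id": "X6->X7",
      "from": "X6",
      "to": "X7",
      "modifiers": []
    },
    {
      "id": "X3->EXTERNAL",
      "from": "X3",
      "to": "EXTERNAL",
      "modifiers": []
    },
    {
      "id": "X7->EXTERNAL",
      "from": "X7",
      "to": "EXTERNAL",
      "modifiers": []
    }
  ]
}
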