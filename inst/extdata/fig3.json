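{
  "floor_height": 4,
  "start": "A",
  "rooms": [
    {
      "id": "A",
      "name": "Corridor A",
      "floor": 0,
      "block": null,
      "x": 0,
      "y": 0,
      "category": "corridor",
      "corner": false
    },
    {
      "id": "B",
      "name": "Corridor B",
      "floor": 0,
      "block": null,
      "x": 4,
      "y": 0,
      "category": "corridor",
      "corner": false
    },
    {
      "id": "C",
      "name": "Room C",
      "floor": 0,
      "block": null,
      "x": 8,
      "y": 3,
      "category": "room",
      "corner": false
    },
    {
      "id": "D",
      "name": "Room D",
      "floor": 0,
      "block": null,
      "x": 8,
      "y": -3,
      "category": "room",
      "corner": false
    },
    {
      "id": "E",
      "name": "Room E",
      "floor": 0,
      "block": null,
      "x": 8,
      "y": 0,
      "category": "room",
      "corner": false
    }
  ],
  "edges": [
    {
      "from": "A",
      "to": "B",
      "link_type": "corridor"
    },
    {
      "from": "B",
      "to": "C",
      "link_type": "door"
    },
    {
      "from": "B",
      "to": "D",
      "link_type": "door"
    },
    {
      "from": "B",
      "to": "E",
      "link_type": "door"
    }
  ],
  "door_visibility": []
}
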