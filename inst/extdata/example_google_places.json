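{
  "status": "OK",
  "results": [
    {
      "place_id": "gp001",
      "name": "Backstube am Platz",
      "geometry": {"location": {"lat": 48.13712, "lng": 11.57481}},
      "types": ["bakery", "food", "store"]
    },
    {
      "place_id": "gp002",
      "name": "Studio Fit",
      "geometry": {"location": {"lat": 48.13758, "lng": 11.57542}},
      "types": ["gym", "health"]
    },
    {
      "place_id": "gp003",
      "name": "Praxis Dr. Huber",
      "geometry": {"location": {"lat": 48.13672, "lng": 11.57611}},
      "types": ["doctor", "health"]
    },
    {
      "place_id": "gp003",
      "name": "Praxis Dr. Huber",
      "geometry": {"location": {"lat": 48.13672, "lng": 11.57611}},
      "types": ["physiotherapist"]
    },
    {
      "place_id": "gp004",
      "name": "Trattoria Nuova",
      "geometry": {"location": {"lat": 48.13731, "lng": 11.57459}},
      "types": ["restaurant", "food"]
    }
  ]
}
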