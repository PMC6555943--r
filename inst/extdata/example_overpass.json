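{
  "version": 0.6,
  "generator": "example export",
  "elements": [
    {
      "type": "node",
      "id": 5001,
      "lat": 48.13705,
      "lon": 11.57493,
      "tags": {"amenity": "fast_food", "name": "Imbiss Eck", "cuisine": "kebab"}
    },
    {
      "type": "node",
      "id": 5002,
      "lat": 48.13741,
      "lon": 11.57553,
      "tags": {"amenity": "cafe", "name": "Cafe Alt"}
    },
    {
      "type": "way",
      "id": 6001,
      "center": {"lat": 48.13688, "lon": 11.57529},
      "tags": {"amenity": "school", "name": "Grundschule Mitte"}
    },
    {
      "type": "node",
      "id": 5003,
      "lat": 48.13725,
      "lon": 11.57601
    }
  ]
}
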