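{
  "scale": "Porcine Thoracic Injury Behaviour Scale (PTIBS)",
  "note": "Levels marked provisional carry structural placeholder wording; substitute the original scale's descriptors for formal use.",
  "levels": [
    {"level": 1, "category": "dragging", "provisional": false,
     "descriptor": "no active hindlimb movements"},
    {"level": 2, "category": "dragging", "provisional": false,
     "descriptor": "active hindlimb movements, rump and knees on ground"},
    {"level": 3, "category": "dragging", "provisional": true,
     "descriptor": "active hindlimb movements with weight-bearing extensions, rump and knees mostly on ground"},
    {"level": 4, "category": "stepping", "provisional": true,
     "descriptor": "occasional steps, rump and knees off ground"},
    {"level": 5, "category": "stepping", "provisional": true,
     "descriptor": "frequent steps, rump and knees off ground, poor coordination"},
    {"level": 6, "category": "stepping", "provisional": true,
     "descriptor": "consistent stepping, rump and knees off ground"},
    {"level": 7, "category": "walking", "provisional": true,
     "descriptor": "walking with marked trunk instability"},
    {"level": 8, "category": "walking", "provisional": false,
     "descriptor": "more than six steps with knees fully extended, plantar hoof placement, unbalanced trunk"},
    {"level": 9, "category": "walking", "provisional": true,
     "descriptor": "near-normal ambulation, mild imbalance"},
    {"level": 10, "category": "walking", "provisional": false,
     "descriptor": "normal ambulation, normal balance"}
  ]
}
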