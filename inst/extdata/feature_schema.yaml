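channels:
- channel: aa
  dims: 20
  window: 9
  padding: 0.0
- channel: conservation
  dims: 1
  window: 9
  padding: 0.0
- channel: entropy
  dims: 1
  window: 9
  padding: 0.0
- channel: n_align
  dims: 1
  window: 1
  padding: 0.0
- channel: ss3
  dims: 3
  window: 7
  padding: 0.0
- channel: disorder
  dims: 1
  window: 7
  padding: 0.0
- channel: accessibility
  dims: 2
  window: 7
  padding: 0.0
- channel: physchem
  dims: 5
  window: 1
  padding: 0.0
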