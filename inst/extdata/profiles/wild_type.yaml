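# Canonical wild-type subclone profile: few, small, simple events.
base: wild_type
nEvents: [8, 12]
classProbs:
  deletion: 0.50
  tandem_duplication: 0.35
  inversion: 0.15
sizes:
  deletion: [500, 10000]
  tandem_duplication: [500, 10000]
  inversion: [1000, 10000]
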