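# Canonical Rtel1-deficient subclone profile: more events, larger
# deletions, templated insertions, fold-back/BFB tails, occasional
# chromothripsis.
base: rtel1_null
nEvents: [15, 35]
classProbs:
  deletion: 0.40
  tandem_duplication: 0.18
  inversion: 0.07
  templated_insertion: 0.20
  bfb: 0.10
  chromothripsis: 0.05
sizes:
  deletion: [1000, 500000]
  tandem_duplication: [1000, 100000]
  inversion: [1000, 100000]
bfb:
  cycles: [1, 3]
  windowFrac: 0.1
chromothripsis:
  regionLen: [1000000, 2000000]
  nFragments: [12, 20]
  retainProb: 0.7
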