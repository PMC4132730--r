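markerPositions:
- 0.425
- 0.475
- 0.525
chromLength: 1.0
nu: 7.0
lambda1: 1.8
lambda2: 0.2
obligateCo: yes
nChromPairs: 5
nMeioses: 2000
seed: 2026
markerPhase: coupling
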