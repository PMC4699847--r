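# full strain survey at desk scale
seed: 2026
decode_sample: 25
experiments:
  parental_TT64:
    strain: parental
    lesion: TT64
    construct: pLL1_2c
    h: 0.895
    t: 0.002
    lambda_opp: 0.8
    n_integrations: 5000
  parental_GAAF:
    strain: parental
    lesion: G-AAF
    construct: pLL1_7
    h: 0.88
    t: 0.02
    lambda_opp: 0.8
    n_integrations: 5000
  recA_TT64:
    strain: recA
    lesion: TT64
    construct: pLL1_2c
    h: 0.05
    t: 0.01
    lambda_opp: 0.8
    n_integrations: 5000
  recF_TT64:
    strain: recF
    lesion: TT64
    construct: pLL1_2c
    h: 0.46
    t: 0.002
    lambda_opp: 0.8
    n_integrations: 5000
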