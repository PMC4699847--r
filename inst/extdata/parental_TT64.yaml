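seed: 4242
decode_sample: 40
experiments:
  parental_TT64:
    strain: parental
    lesion: TT64
    construct: pLL1_2c
    h: 0.895
    t: 0.002
    lambda_opp: 0.8
    lambda_uv: 0.0
    conversion: 0.05
    n_integrations: 20000
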