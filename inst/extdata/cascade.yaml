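# Packaged cascade inputs: the audit's published sorting distribution,
# per-tier correct-treatment rates and referral rates, plus the underlying
# counts used by the parametric bootstrap.
policy: additive_credit
sorting: {VC: 0.39, THC: 0.32, CH: 0.29}
quality: {VC: 0.283, THC: 0.367, CH: 0.323}
referral:
  vc_thc: 0.152      # VC starters referred to a THC
  vc_ch: 0.217       # VC starters referred directly to a CH
  vc_thc_ch: 0.022   # VC starters later referred on from the THC to a CH
  thc_ch: 0.143      # THC starters referred to a CH
  ch_out: 0.032      # CH patients referred out of the modelled system
counts:
  quality:
    VC: [13, 46]
    THC: [18, 49]
    CH: [10, 31]
  referral:
    vc_thc: [7, 46]
    vc_ch: [10, 46]
    vc_thc_ch: [1, 46]
    thc_ch: [7, 49]
    ch_out: [1, 31]
  sorting_n: 750
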