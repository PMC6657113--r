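parameter,rest,stress
hr_bpm,83.4,110.9
edv_ml,164.4,156.8
esv_ml,83.6,64.8
sv_ml,80.8,92.0
ef_pct,49.1,58.6
co_l_min,6.4,9.7
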