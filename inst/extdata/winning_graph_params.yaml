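b:
  I: 0.0265
  II: 0.3767
  III: 0.081
  IV: 0.011
  V: 0.0213
  VII: 0.0216
t:
  I->II: 0.6676
  II->III: 0.0949
  III->IV: 0.1448
  IV->V: 0.1457
p_late: 0.3834
p_early: 0.3
t_max: 10
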