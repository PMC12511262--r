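# Fixed structural parameters of the quizartinib popPK model (median values).
units:
  dose: mg
  volume: L
  clearance: L/h
  absorption_rate: 1/h
  concentration: ng/mL
  time: h
parameters:
  cl: 1.76
  v2: 227.32
  v3: 176.03
  v4: 39.30
  q3: 26.56
  q4: 0.56
  ka: 1.68
  f1: 0.75
iiv:
  omega: {cl: 0.09, v2: 0.09, f1: 0.04}
  sigma_prop: 0.2
  sigma_add: 1
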