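g1:
  shape: 18.16
  scale: 0.03
g2:
  shape: 29.9
  scale: 0.02
g3:
  shape: 29.14
  scale: 0.005
g4:
  shape: 30.77
  scale: 0.007
delta:
  shape: 22.87
  scale: 0.51
tau_i:
  shape: 34.67
  scale: 0.23
h_i:
  shape: 20.44
  scale: 0.96
tau_e:
  shape: 33.02
  scale: 0.16
h_e:
  shape: 24.17
  scale: 0.07
u:
  shape: 23.62
  scale: 0.13
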