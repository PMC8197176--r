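# Calibrated rates, CTL transfer without costimulation (units: day^-1,
# except s in TC^-2/3 day^-1)
g: 0.5
s: 0.7
k_e: 0.75
k_i: 49.6
d_i: 10.0
k_r: 3.8
d_r: 0.0
k_q: 9.2
d_q: 0.03
transfer_day: 3
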