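# nominal parameter preset (times in ms, distances in um)
preset: nominal
tau_W: 6000
tau_P: 5
tau_B: 5
tau_Y: 300
tau_M: 600
tau_u: 300
tau_v: 600
eta: 0.45
phi: 0.06            # per ms; effective drive is phi * x_dur
alpha: 1
beta: 1
sigma_c: 6
x_dur: 50
W_thr: 0.02
A_th: 25
B_amp: 5
bap_prob: 0.25
bap_sigma: 75
bap_refractory: 200
gamma: 0
c1: 0.5
c2: 35
c3: 0.125
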