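# fast spike-timing control preset: accumulator time constants shortened so
# the plasticity window no longer matches slow developmental activity
preset: stdp
tau_M: 60
tau_v: 60
tau_Y: 1
tau_u: 1
eta: 0.3
phi: 0.6             # 3/5 per ms
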