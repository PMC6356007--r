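# Bistable regime: the healthy fixed point coexists with a ~3 Hz
# spike-wave attractor; alpha chosen so 20 s stochastic runs show
# noise-driven transitions in both directions.
tau1: 0.006
tau2: 0.012
tau3: 0.25
tau4: 0.25
c1: 13.5
c2: 12.0
c3: 10.0
c4: 0.2
c5: 3.0
c6: 2.0
c7: 1.5
c8: 4.1
c9: 6.0
h_py: -1.0
h_in: -2.0
h_tc: 6.9
h_re: -2.0
a: 1.0
theta: 4.0
alpha: 0.2
dt: 6.6666666666666671e-05
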