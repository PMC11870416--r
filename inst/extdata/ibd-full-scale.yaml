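# Cluster-scale configuration for `argspace simulate ibd --config ...`.
# Desk-scale defaults are built into simulateIbd(); this reproduces the
# large individual-based setup (expect hours of runtime and a large ARG).
n0: 10000
area: [100, 100]
sigmaD2: 0.25
sigmaM2: 0.25
sigmaC2: 0.25
generations: 2000
sequenceLength: 1000000
recombRate: 1.0e-8
nSamples: 1000
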