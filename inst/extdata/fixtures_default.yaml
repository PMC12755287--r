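# Default synthetic trial-collection specification. Produces a heterogeneous
# mix of null and non-null effects at desk scale so that every evidence
# pattern (CP, SFW, concordant_null and the two residual classes) occurs.
n_trials: 200
effect_mixture:
  rr: [1.0, 0.8, 0.6, 0.4, 1.5]
  weight: [0.35, 0.15, 0.20, 0.15, 0.15]
size_range: [20, 2000]
cer_range: [0.05, 0.5]
seed: 1
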