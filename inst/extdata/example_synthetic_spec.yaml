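# Minimal synthetic-cohort specification for `agedelta generate-cohort`.
# One volumetric-style feature tracking age and one cognitive-style score
# carrying the diagnostic signal. All parameters are synthetic stand-ins.
n_per_group: {CN: 120, MCI: 80, AD: 60}
age_range: [55, 90]
latent_loading: 0.4
features:
  - name: Grey Matter
    age_slope: -0.07
    noise_sd: 0.45
    shares_latent: true
    group_offsets: {MCI: -0.2, AD: -0.5}
  - name: Hippocampus
    age_slope: -0.06
    noise_sd: 0.45
    shares_latent: true
    group_offsets: {MCI: -0.3, AD: -0.7}
  - name: MMSE
    age_slope: -0.01
    noise_sd: 0.9
    group_offsets: {MCI: -0.8, AD: -1.8}
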