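# Example configuration: flat group.field keys in snake_case, 2022 USD.
# Any omitted key keeps its default point estimate.
costs.endoscopy: 44.64          # low end of the documented price range
accuracy.prevalence_hrv: 0.25
econ.psa_iterations: 2000
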