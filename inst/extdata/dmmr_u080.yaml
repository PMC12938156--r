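# Alternative dMMR scenario: on-treatment utility 0.80 instead of 0.84
preset: dmmr
curves: parametric
seed: 1
utilities:
  on_treatment: 0.80
  progressive: 0.50
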