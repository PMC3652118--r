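# Alternative risk-output parameterization: negative (0 0 0.5) /
# positive (0.51 1 1.5) on [0, 1.5]. Swap for the output block of
# risk_model.yaml when the risk score is consumed on that scale.
name: R
universe: [0, 1.5]
sets:
  - {label: negative, shape: triangle, params: [0, 0, 0.5]}
  - {label: positive, shape: triangle, params: [0.51, 1, 1.5]}
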