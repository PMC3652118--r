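# Clinical-background risk model: seven input variables, one risk output.
# The risk output uses the negative (0.5 1 1.5) / positive (1.51 2 2.5)
# parameterization so the defuzzified risk score feeds the injury-resolution
# model directly. An alternative parameterization on [0, 1.5] is shipped as
# risk_output_alt.yaml.
name: risk
inputs:
  - name: E            # age, years
    universe: [10, 90]
    sets:
      - {label: young,  shape: trapezoid, params: [10, 15, 18, 22]}
      - {label: adult,  shape: trapezoid, params: [18, 22, 34, 45]}
      - {label: mature, shape: trapezoid, params: [38, 44, 90, 90]}
  - name: IVSA         # onset of sexual activity, years
    universe: [10, 90]
    sets:
      - {label: young,  shape: trapezoid, params: [10, 15, 18, 22]}
      - {label: adult,  shape: trapezoid, params: [18, 22, 34, 45]}
      - {label: mature, shape: trapezoid, params: [38, 44, 90, 90]}
  - name: PS           # number of sexual partners
    universe: [0, 20]
    sets:
      - {label: few,     shape: trapezoid, params: [0, 2, 3, 4]}
      - {label: many,    shape: trapezoid, params: [3, 5, 9, 10]}
      - {label: unusual, shape: trapezoid, params: [9, 15, 20, 20]}
  - name: NG           # number of pregnancies
    universe: [0, 18]
    sets:
      - {label: "null", shape: triangle,  params: [0, 0, 0.5]}
      - {label: few,    shape: triangle,  params: [0.51, 4, 8]}
      - {label: many,   shape: trapezoid, params: [7, 8, 18, 18]}
  - name: PG           # age at first pregnancy, years
    universe: [10, 90]
    sets:
      - {label: young,  shape: trapezoid, params: [10, 15, 18, 22]}
      - {label: adult,  shape: trapezoid, params: [18, 22, 34, 45]}
      - {label: mature, shape: trapezoid, params: [38, 44, 90, 90]}
  - name: ETS          # sexually transmitted disease history (0 = no, 1 = yes)
    universe: [0, 1.5]
    sets:
      - {label: "no",  shape: triangle, params: [0, 0, 0.5]}
      - {label: "yes", shape: triangle, params: [0.51, 1, 1.5]}
  - name: LE           # cervical lesions on exploration (0 = no, 1 = yes)
    universe: [0, 1.5]
    sets:
      - {label: "no",  shape: triangle, params: [0, 0, 0.5]}
      - {label: "yes", shape: triangle, params: [0.51, 1, 1.5]}
output:
  name: R
  universe: [0.5, 2.5]
  sets:
    - {label: negative, shape: triangle, params: [0.5, 1, 1.5]}
    - {label: positive, shape: triangle, params: [1.51, 2, 2.5]}
engine:
  and: min
  implication: min
  aggregation: max
  defuzzification: centroid
  resolution: 1001
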