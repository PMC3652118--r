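# Injury-resolution model: nucleus morphometry (DN, TN, HN, PN) plus the
# crisp risk score R, fused into a Normal / AGC / Positive-to-malignity call.
name: injury
inputs:
  - name: DN           # mean nucleus area, pixels
    universe: [0, 25000]
    sets:
      - {label: small,  shape: trapezoid, params: [0, 0, 5000, 6000]}
      - {label: medium, shape: trapezoid, params: [4500, 6800, 9000, 10000]}
      - {label: large,  shape: trapezoid, params: [9000, 9900, 25000, 25000]}
  - name: TN           # mean nucleus staining (inverted-grayscale scale)
    universe: [50, 150]
    sets:
      - {label: clear, shape: trapezoid, params: [50, 50, 80, 82]}
      - {label: medium, shape: trapezoid, params: [79, 82, 87, 92]}
      - {label: dark,  shape: trapezoid, params: [87, 92, 150, 150]}
  - name: HN           # mean nucleus eccentricity (homogeneous nucleation)
    universe: [0.5, 1]
    sets:
      - {label: regular,   shape: trapezoid, params: [0.5, 0.5, 0.74, 0.77]}
      - {label: irregular, shape: trapezoid, params: [0.75, 0.8, 1, 1]}
  - name: PN           # total nucleolus count across nuclei
    universe: [0, 150]
    sets:
      - {label: "null", shape: triangle,  params: [0, 0, 2]}
      - {label: few,    shape: trapezoid, params: [2, 9, 20, 30]}
      - {label: many,   shape: trapezoid, params: [24, 40, 150, 150]}
  - name: R            # crisp risk score from the risk model
    universe: [0.5, 2.5]
    sets:
      - {label: negative, shape: triangle, params: [0.5, 1, 1.5]}
      - {label: positive, shape: triangle, params: [1.51, 2, 2.5]}
output:
  name: DL
  universe: [0, 100]
  sets:
    - {label: normal,   shape: trapezoid, params: [0, 0, 31, 41]}
    - {label: agc,      shape: trapezoid, params: [31, 41, 58, 68]}
    - {label: positive, shape: trapezoid, params: [58, 68, 100, 100]}
engine:
  and: min
  implication: min
  aggregation: max
  defuzzification: centroid
  resolution: 1001
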