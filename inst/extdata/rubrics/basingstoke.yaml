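# Basingstoke predictive index (Rees, 2008), preoperative form rescaled to
# integer points (max 30); high risk at >= 10. The extrahepatic-disease
# criterion is structurally disabled for liver-only cohorts.
name: basingstoke
high_risk_threshold: 10
base_points: 0
criteria:
  - label: node-positive primary tumor
    field: nodal_status
    op: eq
    value: positive
    points: 5
  - label: poorly differentiated primary
    field: differentiation
    op: eq
    value: poor
    points: 5
  - label: more than three metastases
    field: n_metastases
    op: gt
    value: 3
    points: 5
  - label: largest metastasis >= 5 cm
    field: largest_metastasis_cm
    op: ge
    value: 5
    points: 5
  - label: preoperative CEA > 60 ng/ml
    field: preop_cea
    op: gt
    value: 60
    points: 5
  - label: extrahepatic disease
    field: extrahepatic_disease
    op: eq
    value: 1
    points: 5
    enabled: false
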