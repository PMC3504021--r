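# Nordlinger prognostic score (AFC, 1996): one point per factor; the
# published grouping puts >= 4 factors in the high-risk band. Serosal
# invasion of the primary is approximated by stage >= 3.
name: nordlinger
high_risk_threshold: 4
base_points: 0
criteria:
  - label: age >= 60 years
    field: age
    op: ge
    value: 60
    points: 1
  - label: primary stage >= 3 (serosal invasion)
    field: primary_stage
    op: ge
    value: 3
    points: 1
  - label: node-positive primary tumor
    field: nodal_status
    op: eq
    value: positive
    points: 1
  - label: interval to metastasis < 24 months
    field: interval_to_metastasis
    op: lt
    value: 24
    points: 1
  - label: largest metastasis >= 5 cm
    field: largest_metastasis_cm
    op: ge
    value: 5
    points: 1
  - label: four or more metastases
    field: n_metastases
    op: ge
    value: 4
    points: 1
  - label: resection margin positive (R1)
    field: margin
    op: eq
    value: R1
    points: 1
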