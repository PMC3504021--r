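# Mayo Clinic / Zakaria DFS score (2007): hepatoduodenal nodal involvement,
# perioperative transfusion and a short interval each score one point; high
# risk at >= 2 points. With hepatoduodenal nodal status unrecorded the
# score cannot exceed 2.
name: mayo
high_risk_threshold: 2
base_points: 0
criteria:
  - label: positive hepatoduodenal lymph nodes
    field: hepatoduodenal_nodes
    op: eq
    value: positive
    points: 1
  - label: perioperative blood transfusion
    field: blood_transfusion
    op: eq
    value: 1
    points: 1
  - label: interval to metastasis <= 30 months
    field: interval_to_metastasis
    op: le
    value: 30
    points: 1
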