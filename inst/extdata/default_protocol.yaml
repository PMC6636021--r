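# Packaged default protocol in scenario-config form: five provider types,
# six clinician-frequency combinations, 6-month re-assessment with
# equal-thirds outcome probabilities (boundary mass on unchanged).
protocol:
  reassessment_interval_months: 6
  providers:
  - id: nurse
    display_name: Nurse
    escalation_rank: 1
    is_lead_capable: yes
  - id: clinical_officer
    display_name: Clinical officer
    escalation_rank: 2
    is_lead_capable: yes
  - id: physician
    display_name: Physician
    escalation_rank: 3
    is_lead_capable: yes
  - id: pharmacist
    display_name: Pharmacist
    escalation_rank: 0
    is_lead_capable: no
  - id: triage
    display_name: Triage staff
    escalation_rank: 0
    is_lead_capable: no
  combos:
  - id: Nq1
    lead: nurse
    interval_months: 1
    trip_schedule:
    - nurse
    - pharmacist
    - triage
  - id: Nq2
    lead: nurse
    interval_months: 2
    trip_schedule:
    - nurse
    - pharmacist
    - triage
  - id: Nq6
    lead: nurse
    interval_months: 6
    trip_schedule:
    - nurse
    - pharmacist
    - triage
  - id: Cq1
    lead: clinical_officer
    interval_months: 1
    trip_schedule:
    - clinical_officer
    - pharmacist
    - triage
  - id: Cq2
    lead: clinical_officer
    interval_months: 2
    trip_schedule:
    - clinical_officer
    - pharmacist
    - triage
  - id: Pq1
    lead: physician
    interval_months: 1
    trip_schedule:
    - physician
    - pharmacist
    - triage
  transitions:
  - source: Nq1
    improve:
      probability: 0.333333333333333
      destination: Nq2
    unchanged:
      probability: 0.333333333333333
      destination: Nq1
    worsen:
      probability: 0.333333333333333
      destination: Cq1
  - source: Nq2
    improve:
      probability: 0.333333333333333
      destination: Nq6
    unchanged:
      probability: 0.333333333333333
      destination: Nq2
    worsen:
      probability: 0.333333333333333
      destination: Cq1
  - source: Nq6
    improve:
      probability: 0.0
      destination: Nq6
    unchanged:
      probability: 0.666666666666667
      destination: Nq6
    worsen:
      probability: 0.333333333333333
      destination: Nq1
  - source: Cq1
    improve:
      probability: 0.333333333333333
      destination: Cq2
    unchanged:
      probability: 0.333333333333333
      destination: Cq1
    worsen:
      probability: 0.333333333333333
      destination: Pq1
  - source: Cq2
    improve:
      probability: 0.333333333333333
      destination: Nq1
    unchanged:
      probability: 0.333333333333333
      destination: Cq2
    worsen:
      probability: 0.333333333333333
      destination: Cq1
  - source: Pq1
    improve:
      probability: 0.333333333333333
      destination: Cq1
    unchanged:
      probability: 0.666666666666667
      destination: Pq1
    worsen:
      probability: 0.0
      destination: Pq1
  categories:
  - id: 2
    state_label: SBP controlled on repeat measurement
    management_label: continue nurse-managed care, 2-monthly review
    combo: Nq2
  - id: 7
    state_label: SBP >= 140 and < 180, not on medication
    management_label: enroll nurse-managed care, initiate pharmacotherapy
    combo: Nq1
  - id: 8
    state_label: SBP >= 140 and < 180 on repeat measurement
    management_label: continue nurse-managed care, titrate therapy
    combo: Nq1
  - id: 12
    state_label: SBP >= 180, uncontrolled on therapy
    management_label: refer to clinical officer, monthly review
    combo: Cq1
  - id: 13
    state_label: SBP >= 180 with complications
    management_label: refer to clinical officer, monthly review
    combo: Cq1
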