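# Ramp-up scenario: zero initial volume, cumulative enrollment targets of
# 1000 / 3000 / 7000 patients at the end of years 1-3, constant within-year
# monthly enrollment.
protocol:
  default: true
scenario:
  type: rampup
  year_targets: [1000, 3000, 7000]
initial_distribution:
  Nq1: 0.60
  Nq2: 0.32
  Nq6: 0.08
attrition: 0
horizon_months: 36
mode: phase
yearly_rule: year_average
capacity:
  nurse:
    days_per_month: 2
    hours_per_day: 6
    minutes_per_encounter: 8.9
  # Non-nurse encounter times are package assumptions, not measured values:
  # override with program data.
  clinical_officer:
    days_per_month: 2
    hours_per_day: 6
    minutes_per_encounter: 15
  physician:
    days_per_month: 2
    hours_per_day: 6
    minutes_per_encounter: 20
  pharmacist:
    days_per_month: 2
    hours_per_day: 6
    minutes_per_encounter: 3
  triage:
    days_per_month: 2
    hours_per_day: 6
    minutes_per_encounter: 3
seed: 1
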