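# Steady-state scenario: zero initial volume, a constant 100 new patients
# enrolled every month over a 36-month horizon.
protocol:
  default: true
scenario:
  type: steady
  monthly_rate: 100
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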