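# Single-combo protocols for hand-checkable trajectories.

one_combo_protocol <- function(q = 1L, id = sprintf("Nq%d", q)) {
  protocol(
    providers = list(
      provider_type("nurse", escalation_rank = 1L, is_lead_capable = TRUE),
      provider_type("pharmacist"),
      provider_type("triage")
    ),
    combos = list(cf_combo(id, "nurse", q, c("nurse", "pharmacist", "triage"))),
    transitions = list(transition_rule(
      id,
      improve   = list(probability = 0, destination = id),
      unchanged = list(probability = 1, destination = id),
      worsen    = list(probability = 0, destination = id)
    ))
  )
}

point_mass <- function(combo) stats::setNames(1, combo)

default_pi <- function() c(Nq1 = 0.60, Nq2 = 0.32, Nq6 = 0.08)

# replace one transition rule in a protocol (revalidates)
with_transition <- function(p, rule) {
  p$transitions[[rule$source]] <- rule
  validate_protocol(p)
}
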