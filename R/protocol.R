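#' @keywords internal
protocol_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("protocol_error", "htnworkforce_error")))
}

#' Define a provider type
#'
#' A provider type is a cadre of health worker that patients encounter at the
#' clinic: nurse, clinical officer, physician, pharmacist, triage staff.
#' Lead-capable providers (nurse, clinical officer, physician) can own a
#' patient's management; their `escalation_rank` orders the referral
#' hierarchy, so "worsen to a higher level of care" means moving to a
#' lead-capable provider with a larger rank.
#'
#' @param id short name token, unique within a protocol (e.g. `"nurse"`)
#' @param display_name human-readable name; defaults to `id`
#' @param escalation_rank non-negative integer; higher = more specialized
#' @param is_lead_capable can this cadre lead a patient's management?
#' @return an object of class `provider_type`
#' @examples
#' provider_type("nurse", "Nurse", escalation_rank = 1, is_lead_capable = TRUE)
#' @export
provider_type <- function(id, display_name = id, escalation_rank = 0L,
                          is_lead_capable = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(escalation_rank) || length(escalation_rank) != 1L ||
      escalation_rank < 0 || escalation_rank != round(escalation_rank)) {
    protocol_error("provider '%s': escalation_rank must be an integer >= 0", id)
  }
  structure(
    list(id = id, display_name = display_name,
         escalation_rank = as.integer(escalation_rank),
         is_lead_capable = isTRUE(is_lead_capable)),
    class = "provider_type"
  )
}

#' Define a clinician-frequency combination
#'
#' A clinician-frequency combination ("combo") summarizes a patient's care
#' intensity as a pairing of lead provider and visit interval: e.g. `Nq1` is
#' nurse-led care with a visit every month, `Cq2` clinical-officer-led care
#' every 2 months. On every trip to the facility the patient encounters each
#' provider in `trip_schedule` (typically the lead clinician, the pharmacist
#' for the medication refill, and triage for intake).
#'
#' @param id token, e.g. `"Nq1"`
#' @param lead provider id of the lead clinician (must be lead-capable)
#' @param interval_months visit interval q in months (integer >= 1)
#' @param trip_schedule character vector of provider ids seen at every trip;
#'   must contain `lead`
#' @return an object of class `cf_combo`
#' @examples
#' cf_combo("Nq1", "nurse", 1, c("nurse", "pharmacist", "triage"))
#' @export
cf_combo <- function(id, lead, interval_months, trip_schedule) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(interval_months) || length(interval_months) != 1L ||
      interval_months < 1 || interval_months != round(interval_months)) {
    protocol_error("combo '%s': interval_months must be an integer >= 1", id)
  }
  if (!lead %in% trip_schedule) {
    protocol_error("combo '%s': lead '%s' not in trip_schedule", id, lead)
  }
  structure(
    list(id = id, lead = lead, interval_months = as.integer(interval_months),
         trip_schedule = unique(as.character(trip_schedule))),
    class = "cf_combo"
  )
}

#' Define a 6-month outcome transition rule
#'
#' At every re-assessment a patient in a given combo can improve (blood
#' pressure controlled), remain unchanged, or worsen, each with a stated
#' probability and a destination combo. The `unchanged` destination is the
#' source combo itself. A boundary combo that cannot improve (or worsen) has
#' that outcome's probability reassigned to `unchanged`; encode this by
#' setting the missing outcome's probability to 0 with destination = source.
#'
#' @param source combo id the rule applies to
#' @param improve,unchanged,worsen each a `list(probability =, destination =)`
#' @return an object of class `transition_rule`
#' @examples
#' transition_rule("Nq1",
#'   improve   = list(probability = 1/3, destination = "Nq2"),
#'   unchanged = list(probability = 1/3, destination = "Nq1"),
#'   worsen    = list(probability = 1/3, destination = "Cq1"))
#' @export
transition_rule <- function(source, improve, unchanged, worsen) {
  out <- list(improve = improve, unchanged = unchanged, worsen = worsen)
  for (nm in names(out)) {
    o <- out[[nm]]
    if (!is.list(o) || !all(c("probability", "destination") %in% names(o))) {
      protocol_error("transition for '%s': outcome '%s' needs probability and destination",
                     source, nm)
    }
    if (o$probability < 0 || o$probability > 1) {
      protocol_error("transition for '%s': probability of '%s' outside [0,1]", source, nm)
    }
  }
  structure(list(source = source, outcomes = out), class = "transition_rule")
}

#' Assemble a clinical protocol
#'
#' The protocol is the clinical algorithm as data: provider types, the
#' clinician-frequency combinations patients are managed under, one
#' transition rule per combo applied at each re-assessment, and an optional
#' patient-category metadata layer mapping protocol categories (blood
#' pressure state + management plan) many-to-one onto combos.
#'
#' @param providers list of [provider_type()] objects
#' @param combos list of [cf_combo()] objects
#' @param transitions list of [transition_rule()] objects, one per combo
#' @param categories optional data.frame with columns `id` (integer),
#'   `state_label`, `management_label`, `combo`
#' @param reassessment_interval_months re-assessment cadence R (default 6)
#' @return a validated object of class `protocol`
#' @seealso [default_protocol()], [validate_protocol()]
#' @export
protocol <- function(providers, combos, transitions, categories = NULL,
                     reassessment_interval_months = 6L) {
  p <- structure(
    list(
      providers = stats::setNames(providers, vapply(providers, `[[`, "", "id")),
      combos = stats::setNames(combos, vapply(combos, `[[`, "", "id")),
      transitions = stats::setNames(transitions, vapply(transitions, `[[`, "", "source")),
      categories = categories,
      reassessment_interval_months = as.integer(reassessment_interval_months)
    ),
    class = "protocol"
  )
  validate_protocol(p)
}

#' Validate a protocol
#'
#' Checks referential integrity (every combo lead, trip-schedule member and
#' transition destination names a declared id), that leads are lead-capable
#' with strictly ordered escalation ranks, that every combo has exactly one
#' transition rule whose outcome probabilities sum to 1, that the unchanged
#' destination equals the source, and that visit intervals do not exceed the
#' re-assessment interval.
#'
#' @param p a `protocol`
#' @return `p`, unchanged, if valid; otherwise signals a `protocol_error`
#'   naming the first violated invariant and the offending id
#' @export
validate_protocol <- function(p) {
  stopifnot(inherits(p, "protocol"))
  prov_ids <- names(p$providers)
  if (anyDuplicated(prov_ids)) protocol_error("duplicate provider ids")
  combo_ids <- names(p$combos)
  if (anyDuplicated(combo_ids)) protocol_error("duplicate combo ids")
  if (p$reassessment_interval_months < 1L) {
    protocol_error("reassessment_interval_months must be >= 1")
  }

  leads <- Filter(function(x) x$is_lead_capable, p$providers)
  ranks <- vapply(leads, `[[`, 0L, "escalation_rank")
  if (anyDuplicated(ranks)) {
    protocol_error("escalation_rank not strictly ordered among lead-capable providers")
  }

  for (cb in p$combos) {
    if (!cb$lead %in% prov_ids) {
      protocol_error("combo '%s': unknown lead provider '%s'", cb$id, cb$lead)
    }
    if (!p$providers[[cb$lead]]$is_lead_capable) {
      protocol_error("combo '%s': lead '%s' not lead-capable", cb$id, cb$lead)
    }
    missing <- setdiff(cb$trip_schedule, prov_ids)
    if (length(missing)) {
      protocol_error("combo '%s': unknown provider '%s' in trip_schedule",
                     cb$id, missing[[1L]])
    }
    if (cb$interval_months > p$reassessment_interval_months) {
      protocol_error("combo '%s': interval %d exceeds reassessment interval %d",
                     cb$id, cb$interval_months, p$reassessment_interval_months)
    }
  }

  if (!setequal(names(p$transitions), combo_ids) ||
      length(p$transitions) != length(combo_ids)) {
    protocol_error("exactly one transition rule per combo required")
  }
  for (tr in p$transitions) {
    probs <- vapply(tr$outcomes, `[[`, 0, "probability")
    if (abs(sum(probs) - 1) > 1e-9) {
      protocol_error("transition for '%s': probabilities sum != 1 (%.6f)",
                     tr$source, sum(probs))
    }
    if (tr$outcomes$unchanged$destination != tr$source) {
      protocol_error("transition for '%s': unchanged destination must equal source",
                     tr$source)
    }
    for (o in tr$outcomes) {
      if (!o$destination %in% combo_ids) {
        protocol_error("transition for '%s': unknown destination combo '%s'",
                       tr$source, o$destination)
      }
    }
  }

  if (!is.null(p$categories)) {
    cat <- p$categories
    need <- c("id", "combo")
    if (!is.data.frame(cat) || !all(need %in% names(cat))) {
      protocol_error("categories must be a data.frame with columns id and combo")
    }
    if (anyDuplicated(cat$id)) protocol_error("duplicate category ids")
    bad <- setdiff(cat$combo, combo_ids)
    if (length(bad)) {
      protocol_error("category mapped to unknown combo '%s'", bad[[1L]])
    }
  }
  p
}

#' The default hypertension task-shifting protocol
#'
#' Five provider types (nurse, clinical officer, physician in escalating
#' rank; pharmacist and triage as non-lead support staff) and six
#' clinician-frequency combinations: nurse-led care every 1, 2 or 6 months
#' (`Nq1`, `Nq2`, `Nq6`), clinical-officer-led care every 1 or 2 months
#' (`Cq1`, `Cq2`), and physician-led care every month (`Pq1`). Every trip
#' includes the lead clinician, the pharmacist and triage. Re-assessment is
#' every 6 months with equal probability (1/3) of improving, staying
#' unchanged, or worsening wherever all three outcomes exist.
#'
#' Default transition destinations: improvement relaxes care one step
#' (Nq1 to Nq2 to Nq6; Cq1 to Cq2; Cq2 steps down to intensive nurse care
#' Nq1; Pq1 steps down to Cq1). Worsening under intensive nurse care
#' escalates to the clinical officer (Nq1 and Nq2 to Cq1); a controlled
#' 6-monthly patient who worsens resumes monthly nurse visits (Nq6 to Nq1);
#' clinical-officer patients escalate toward the physician (Cq1 to Pq1,
#' Cq2 to Cq1). At the boundaries, Nq6 cannot improve further and Pq1
#' cannot worsen further: the unavailable outcome's probability mass is
#' reassigned to unchanged (2/3).
#'
#' The bundled category table is an illustrative subset of the 26-category
#' protocol layer (the worked-example categories only); the full enumeration
#' is configuration, not fixed by the package.
#'
#' @return a validated `protocol` with 6 combos and a 6-month
#'   re-assessment interval
#' @examples
#' p <- default_protocol()
#' names(p$combos)
#' @export
default_protocol <- function() {
  providers <- list(
    provider_type("nurse", "Nurse", escalation_rank = 1L, is_lead_capable = TRUE),
    provider_type("clinical_officer", "Clinical officer", escalation_rank = 2L,
                  is_lead_capable = TRUE),
    provider_type("physician", "Physician", escalation_rank = 3L,
                  is_lead_capable = TRUE),
    provider_type("pharmacist", "Pharmacist"),
    provider_type("triage", "Triage staff")
  )
  sched <- function(lead) c(lead, "pharmacist", "triage")
  combos <- list(
    cf_combo("Nq1", "nurse", 1L, sched("nurse")),
    cf_combo("Nq2", "nurse", 2L, sched("nurse")),
    cf_combo("Nq6", "nurse", 6L, sched("nurse")),
    cf_combo("Cq1", "clinical_officer", 1L, sched("clinical_officer")),
    cf_combo("Cq2", "clinical_officer", 2L, sched("clinical_officer")),
    cf_combo("Pq1", "physician", 1L, sched("physician"))
  )
  tr <- function(source, improve_dest, worsen_dest) {
    # boundary: a missing outcome keeps its mass on unchanged
    p_imp <- if (is.null(improve_dest)) 0 else 1 / 3
    p_wor <- if (is.null(worsen_dest)) 0 else 1 / 3
    transition_rule(
      source,
      improve   = list(probability = p_imp,
                       destination = if (is.null(improve_dest)) source else improve_dest),
      unchanged = list(probability = 1 - p_imp - p_wor, destination = source),
      worsen    = list(probability = p_wor,
                       destination = if (is.null(worsen_dest)) source else worsen_dest)
    )
  }
  transitions <- list(
    tr("Nq1", "Nq2", "Cq1"),
    tr("Nq2", "Nq6", "Cq1"),
    tr("Nq6", NULL,  "Nq1"),
    tr("Cq1", "Cq2", "Pq1"),
    tr("Cq2", "Nq1", "Cq1"),
    tr("Pq1", "Cq1", NULL)
  )
  categories <- data.frame(
    id = c(2L, 7L, 8L, 12L, 13L),
    state_label = c("SBP controlled on repeat measurement",
                    "SBP >= 140 and < 180, not on medication",
                    "SBP >= 140 and < 180 on repeat measurement",
                    "SBP >= 180, uncontrolled on therapy",
                    "SBP >= 180 with complications"),
    management_label = c("continue nurse-managed care, 2-monthly review",
                         "enroll nurse-managed care, initiate pharmacotherapy",
                         "continue nurse-managed care, titrate therapy",
                         "refer to clinical officer, monthly review",
                         "refer to clinical officer, monthly review"),
    combo = c("Nq2", "Nq1", "Nq1", "Cq1", "Cq1"),
    stringsAsFactors = FALSE
  )
  protocol(providers, combos, transitions, categories)
}

#' Look up the combo for a patient category
#'
#' Patient categories (protocol states pairing a blood-pressure band with a
#' management plan) map many-to-one onto clinician-frequency combinations;
#' the demand engine operates on combos and the category layer is metadata.
#'
#' @param p a `protocol` with a categories table
#' @param category_id integer category id
#' @return the mapped combo id (character scalar)
#' @export
combo_for_category <- function(p, category_id) {
  stopifnot(inherits(p, "protocol"))
  if (is.null(p$categories)) protocol_error("protocol has no category table")
  i <- match(category_id, p$categories$id)
  if (is.na(i)) protocol_error("unknown patient category '%s'", category_id)
  p$categories$combo[[i]]
}

#' Expected-value transition matrix of a protocol
#'
#' Row c gives the probability distribution over destination combos for a
#' patient in combo c at a re-assessment (outcome probabilities accumulated
#' onto destinations).
#'
#' @param p a `protocol`
#' @return a row-stochastic matrix with combo ids as dimnames
#' @export
transition_matrix <- function(p) {
  ids <- names(p$combos)
  M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (tr in p$transitions) {
    for (o in tr$outcomes) {
      M[tr$source, o$destination] <- M[tr$source, o$destination] + o$probability
    }
  }
  M
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol> %d providers, %d combos, re-assessment every %d months\n",
              length(x$providers), length(x$combos),
              x$reassessment_interval_months))
  for (cb in x$combos) {
    cat(sprintf("  %-4s lead=%s q=%d trip={%s}\n", cb$id, cb$lead,
                cb$interval_months, paste(cb$trip_schedule, collapse = ",")))
  }
  invisible(x)
}
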