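#' Monthly patient-contact minutes from clinic time allocation
#'
#' @param days clinic days per month dedicated to hypertension patients
#' @param hours clinical hours per day available to see patients
#' @return contact minutes per month, `days * hours * 60`
#' @examples
#' contact_minutes(2, 6)  # 720
#' @export
contact_minutes <- function(days, hours) {
  if (any(days < 0) || any(hours < 0)) stop("days and hours must be >= 0")
  days * hours * 60
}

#' Encounters per month one FTE can deliver
#'
#' Capacity is contact time divided by productivity: `E_j = t_j / m_j`.
#'
#' @param t_j patient-contact minutes per month
#' @param m_j minutes per clinical encounter (> 0)
#' @return encounters per month per full-time equivalent
#' @examples
#' monthly_capacity(720, 8.9)  # 80.89888
#' @export
monthly_capacity <- function(t_j, m_j) {
  if (any(m_j <= 0)) stop("minutes_per_encounter must be > 0")
  if (any(t_j < 0)) stop("contact minutes must be >= 0")
  t_j / m_j
}

#' Work parameters for one provider type
#'
#' @param provider provider id
#' @param clinic_days_per_month days per month on hypertension clinic
#' @param hours_per_day clinical hours per day
#' @param minutes_per_encounter average encounter duration m_j (> 0)
#' @param contact_minutes_per_month optional explicit override of
#'   t_j = days x hours x 60
#' @return an object of class `provider_capacity`
#' @export
provider_capacity <- function(provider, clinic_days_per_month, hours_per_day,
                              minutes_per_encounter,
                              contact_minutes_per_month = NULL) {
  if (minutes_per_encounter <= 0) stop("minutes_per_encounter must be > 0")
  t_j <- if (is.null(contact_minutes_per_month)) {
    contact_minutes(clinic_days_per_month, hours_per_day)
  } else {
    contact_minutes_per_month
  }
  if (t_j < 0) stop("contact_minutes_per_month must be >= 0")
  structure(
    list(provider = provider,
         clinic_days_per_month = clinic_days_per_month,
         hours_per_day = hours_per_day,
         minutes_per_encounter = minutes_per_encounter,
         contact_minutes_per_month = t_j),
    class = "provider_capacity"
  )
}

#' Assemble a capacity model
#'
#' One [provider_capacity()] per provider type; must cover every provider
#' that appears in any combo's trip schedule when paired with a protocol.
#'
#' @param ... `provider_capacity` objects
#' @return an object of class `capacity_model`
#' @export
capacity_model <- function(...) {
  caps <- list(...)
  if (length(caps) == 1L && is.list(caps[[1L]]) &&
      !inherits(caps[[1L]], "provider_capacity")) {
    caps <- caps[[1L]]
  }
  ids <- vapply(caps, `[[`, "", "provider")
  if (anyDuplicated(ids)) stop("duplicate provider in capacity model")
  structure(stats::setNames(caps, ids), class = "capacity_model")
}

#' Default capacity parameters
#'
#' All providers work 2 clinic days per month and 6 hours per day on
#' hypertension care (720 contact minutes). The nurse encounter time is
#' 8.9 minutes (measured; observed range 3.5 to 20.2). The non-nurse
#' encounter times are package assumptions, not measured values, and should
#' be overridden with program data: clinical officer 15, physician 20,
#' pharmacist 3, triage 3 minutes.
#'
#' @return a `capacity_model` covering the default protocol's five providers
#' @export
default_capacity <- function() {
  mk <- function(id, m) provider_capacity(id, 2, 6, m)
  capacity_model(
    mk("nurse", 8.9),
    mk("clinical_officer", 15),
    mk("physician", 20),
    mk("pharmacist", 3),
    mk("triage", 3)
  )
}

#' Encounters-per-month capacity per FTE for every provider in a model
#'
#' @param cm a `capacity_model`
#' @return named numeric vector of E_j values
#' @export
capacity_per_fte <- function(cm) {
  stopifnot(inherits(cm, "capacity_model"))
  vapply(cm, function(x) {
    monthly_capacity(x$contact_minutes_per_month, x$minutes_per_encounter)
  }, 0)
}

#' @export
print.capacity_model <- function(x, ...) {
  cat("<capacity_model>\n")
  for (pc in x) {
    cat(sprintf("  %-18s t=%6.0f min/month, m=%5.1f min/encounter, E=%7.2f/month\n",
                pc$provider, pc$contact_minutes_per_month,
                pc$minutes_per_encounter,
                pc$contact_minutes_per_month / pc$minutes_per_encounter))
  }
  invisible(x)
}
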