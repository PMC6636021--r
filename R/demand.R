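#' Build an enrollment stream
#'
#' The demand driver: how many new patients enroll in each month of the
#' horizon, plus the distribution over clinician-frequency combinations that
#' newly enrolled patients are assigned to.
#'
#' @param new_patients numeric vector of length T, new enrollees per month
#'   (month 1 is the first model month); entries >= 0
#' @param initial_distribution named numeric vector, weights over combo ids
#'   summing to 1
#' @return an object of class `enrollment_stream`
#' @export
enrollment_stream <- function(new_patients, initial_distribution) {
  if (any(new_patients < 0)) stop("new_patients must be >= 0")
  if (any(initial_distribution < 0)) stop("initial_distribution weights must be >= 0")
  if (abs(sum(initial_distribution) - 1) > 1e-9) {
    stop("initial_distribution weights must sum to 1")
  }
  if (is.null(names(initial_distribution))) {
    stop("initial_distribution must be named by combo id")
  }
  structure(
    list(new_patients = as.numeric(new_patients),
         initial_distribution = initial_distribution),
    class = "enrollment_stream"
  )
}

#' Constant monthly enrollment (steady-state scenario)
#'
#' @param rate new patients per month (>= 0)
#' @param T horizon in months
#' @param pi named initial distribution over combos
#' @return an `enrollment_stream` of length `T`
#' @examples
#' e <- constant_enrollment(100, 36, c(Nq1 = 0.60, Nq2 = 0.32, Nq6 = 0.08))
#' sum(e$new_patients)  # 3600
#' @export
constant_enrollment <- function(rate, T, pi) {
  if (rate < 0) stop("enrollment rate must be >= 0")
  stopifnot(T >= 1)
  enrollment_stream(rep(rate, T), pi)
}

#' Enrollment from cumulative year-end targets (ramp-up scenario)
#'
#' Enrollment is constant within each year at
#' `(target_y - target_{y-1}) / 12` so the cumulative count at month `12 * y`
#' equals `target_y` exactly.
#'
#' @param targets non-decreasing cumulative patient counts at the end of each
#'   year; the horizon is `12 * length(targets)` months
#' @param pi named initial distribution over combos
#' @return an `enrollment_stream`
#' @examples
#' e <- enrollment_from_year_targets(c(1000, 3000, 7000),
#'                                   c(Nq1 = 0.60, Nq2 = 0.32, Nq6 = 0.08))
#' cumulative_enrollment(e)[c(12, 24, 36)]  # 1000 3000 7000
#' @export
enrollment_from_year_targets <- function(targets, pi) {
  if (any(targets < 0)) stop("cumulative targets must be >= 0")
  if (is.unsorted(targets)) stop("cumulative targets must be non-decreasing")
  increments <- diff(c(0, targets))
  enrollment_stream(rep(increments / 12, each = 12), pi)
}

#' Cumulative enrollment by month
#'
#' @param e an `enrollment_stream`
#' @return numeric vector, cumulative new enrollees through each month
#' @export
cumulative_enrollment <- function(e) {
  stopifnot(inherits(e, "enrollment_stream"))
  cumsum(e$new_patients)
}

# trips due in a block-month for a combo: phase mode puts trips at
# block-relative ages 0, q, 2q, ... (the re-assessment visit resets phase);
# smoothed mode spreads 1/q expected trips over every month.
trip_weight <- function(block_age, q, mode) {
  if (mode == "phase") as.numeric(block_age %% q == 0) else 1 / q
}

#' Project a unit cohort through the protocol
#'
#' Expected-value trajectory of one unit of enrollment entering at
#' `start_month` with the given combo distribution: occupancy mixes over the
#' transition rules at every re-assessment boundary, survival declines
#' geometrically with monthly attrition, and each trip contributes one
#' encounter to every provider in the combo's trip schedule. In `phase` mode
#' a combo with interval q generates a trip at block-relative months
#' 0, q, 2q, ... within each re-assessment block (the first trip falls in
#' the enrollment month, and the re-assessment itself is a visit); in
#' `smoothed` mode each member generates 1/q expected trips every month.
#'
#' @param p a `protocol`
#' @param start_month enrollment month (1-based, <= `T`)
#' @param T horizon in months
#' @param attrition_rate monthly probability of leaving care, in [0, 1)
#'   for the deterministic engine (1 allowed: only the enrollment-month
#'   trip remains)
#' @param pi named initial distribution over combo ids; defaults to the
#'   60/32/8 split over Nq1/Nq2/Nq6
#' @param mode `"phase"` or `"smoothed"`
#' @return an object of class `cohort_trajectory` with elements
#'   `start_month`, `occupancy` (T x combos matrix of expected fractions)
#'   and `encounters` (T x providers matrix of expected encounters per
#'   enrolled patient)
#' @export
project_unit_cohort <- function(p, start_month, T,
                                attrition_rate = 0,
                                pi = default_initial_distribution(),
                                mode = c("phase", "smoothed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "protocol"), start_month >= 1, start_month <= T,
            attrition_rate >= 0, attrition_rate <= 1)
  ids <- names(p$combos)
  prov <- names(p$providers)
  R <- p$reassessment_interval_months
  q <- vapply(p$combos, `[[`, 0L, "interval_months")

  pi_full <- stats::setNames(numeric(length(ids)), ids)
  unknown <- setdiff(names(pi), ids)
  if (length(unknown)) stop("initial distribution names unknown combo '", unknown[[1]], "'")
  pi_full[names(pi)] <- pi

  # provider incidence: one trip in combo c -> one encounter per provider in
  # c's trip schedule
  S <- matrix(0, length(ids), length(prov), dimnames = list(ids, prov))
  for (cb in p$combos) S[cb$id, cb$trip_schedule] <- 1

  M <- transition_matrix(p)
  occupancy <- matrix(0, T, length(ids), dimnames = list(NULL, ids))
  encounters <- matrix(0, T, length(prov), dimnames = list(NULL, prov))

  o <- pi_full
  for (t in start_month:T) {
    a <- t - start_month
    if (a > 0 && a %% R == 0) o <- drop(o %*% M)
    surv <- (1 - attrition_rate)^a
    occ_t <- o * surv
    occupancy[t, ] <- occ_t
    w <- vapply(q, function(qi) trip_weight(a %% R, qi, mode), 0)
    encounters[t, ] <- drop((occ_t * w) %*% S)
  }
  structure(
    list(start_month = start_month, occupancy = occupancy, encounters = encounters),
    class = "cohort_trajectory"
  )
}

#' Default initial distribution over combos
#'
#' 60% of enrollees need monthly follow-up, 32% 2-monthly and 8% 6-monthly,
#' all initially under nurse-led care.
#'
#' @return named numeric vector over Nq1/Nq2/Nq6
#' @export
default_initial_distribution <- function() {
  c(Nq1 = 0.60, Nq2 = 0.32, Nq6 = 0.08)
}

#' Aggregate encounter demand over an enrollment stream
#'
#' Superposition of [project_unit_cohort()] over every enrollment month,
#' scaled by that month's new enrollees: the worksheet-model projection of
#' expected total encounters per provider per month, `v_j(t)`, and expected
#' patient occupancy per combo per month, `n_c(t)`. Linear in the enrollment
#' stream.
#'
#' @inheritParams project_unit_cohort
#' @param e an `enrollment_stream` (its initial distribution is used)
#' @param T horizon in months; defaults to the stream length
#' @return an object of class `demand_grid` with elements `months`,
#'   `encounters` (T x providers) and `occupancy` (T x combos)
#' @examples
#' d <- aggregate_demand(default_protocol(),
#'                       constant_enrollment(100, 12, default_initial_distribution()))
#' d$encounters[1, "nurse"]  # 100: every new patient has an enrollment-month trip
#' @export
aggregate_demand <- function(p, e, attrition_rate = 0, T = NULL,
                             mode = c("phase", "smoothed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(e, "enrollment_stream"))
  if (is.null(T)) T <- length(e$new_patients)
  if (length(e$new_patients) < T) stop("enrollment stream shorter than horizon")
  ids <- names(p$combos)
  prov <- names(p$providers)
  encounters <- matrix(0, T, length(prov), dimnames = list(NULL, prov))
  occupancy <- matrix(0, T, length(ids), dimnames = list(NULL, ids))
  for (s in seq_len(T)) {
    n_s <- e$new_patients[[s]]
    if (n_s == 0) next
    u <- project_unit_cohort(p, s, T, attrition_rate,
                             pi = e$initial_distribution, mode = mode)
    encounters <- encounters + n_s * u$encounters
    occupancy <- occupancy + n_s * u$occupancy
  }
  structure(
    list(months = seq_len(T), encounters = encounters, occupancy = occupancy,
         mode = mode, attrition_rate = attrition_rate),
    class = "demand_grid"
  )
}

#' Tidy long-format view of a demand grid
#'
#' @param d a `demand_grid`
#' @return a data.frame with columns `month`, `provider`,
#'   `expected_encounters`
#' @export
demand_tidy <- function(d) {
  stopifnot(inherits(d, "demand_grid"))
  prov <- colnames(d$encounters)
  data.frame(
    month = rep(d$months, times = length(prov)),
    provider = rep(prov, each = length(d$months)),
    expected_encounters = as.vector(d$encounters),
    stringsAsFactors = FALSE
  )
}

#' Tidy long-format occupancy view of a demand grid
#'
#' @param d a `demand_grid`
#' @return a data.frame with columns `month`, `combo`, `expected_patients`
#' @export
occupancy_tidy <- function(d) {
  stopifnot(inherits(d, "demand_grid"))
  ids <- colnames(d$occupancy)
  data.frame(
    month = rep(d$months, times = length(ids)),
    combo = rep(ids, each = length(d$months)),
    expected_patients = as.vector(d$occupancy),
    stringsAsFactors = FALSE
  )
}

#' Worksheet-style wide view (rows = provider or combo, columns = M1..MT)
#'
#' @param d a `demand_grid`
#' @param what `"encounters"` (rows = providers) or `"occupancy"`
#'   (rows = combos)
#' @return a data.frame in wide layout with columns `M1` .. `MT`
#' @export
demand_wide <- function(d, what = c("encounters", "occupancy")) {
  what <- match.arg(what)
  m <- t(d[[what]])
  out <- data.frame(row = rownames(m), stringsAsFactors = FALSE)
  names(out) <- if (what == "encounters") "provider" else "combo"
  wide <- as.data.frame(m)
  names(wide) <- paste0("M", d$months)
  cbind(out, wide, row.names = NULL)
}

#' @export
print.demand_grid <- function(x, ...) {
  cat(sprintf("<demand_grid> %d months x %d providers (%s mode, attrition %.3g)\n",
              length(x$months), ncol(x$encounters), x$mode, x$attrition_rate))
  tot <- colSums(x$encounters)
  for (j in names(tot)) cat(sprintf("  %-18s %10.1f encounters\n", j, tot[[j]]))
  invisible(x)
}
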