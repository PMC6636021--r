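#' Configure a patient-level microsimulation
#'
#' The stochastic counterpart of the deterministic cohort engine: individual
#' patients are enrolled, assigned a combo by a categorical draw, make trips
#' on the phase schedule, survive each month with probability `1 - rho`, and
#' draw an improve/unchanged/worsen outcome at every re-assessment boundary.
#' Used as a brute-force oracle to validate the expected-value projection.
#'
#' @param protocol a `protocol`
#' @param enrollment an `enrollment_stream` with integer monthly counts
#'   (see [integerize_enrollment()])
#' @param attrition_rate monthly probability of leaving care, in [0, 1]
#' @param horizon months to simulate; defaults to the stream length
#' @param n_replicates number of independent replicates (>= 1)
#' @param seed integer master seed; expands to per-replicate substreams so
#'   increasing `n_replicates` never alters earlier replicates
#' @return an object of class `sim_config`
#' @export
sim_config <- function(protocol, enrollment, attrition_rate = 0,
                       horizon = NULL, n_replicates = 200L, seed = 1L) {
  stopifnot(inherits(protocol, "protocol"), inherits(enrollment, "enrollment_stream"),
            attrition_rate >= 0, attrition_rate <= 1, n_replicates >= 1)
  if (is.null(horizon)) horizon <- length(enrollment$new_patients)
  if (any(enrollment$new_patients != round(enrollment$new_patients))) {
    stop("microsimulation needs integer patients/month; see integerize_enrollment()")
  }
  structure(
    list(protocol = validate_protocol(protocol), enrollment = enrollment,
         attrition_rate = attrition_rate, horizon = as.integer(horizon),
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Round an enrollment stream to whole patients
#'
#' Largest-remainder rounding on the cumulative enrollment curve: month t
#' receives `round(cum_t) - round(cum_{t-1})` patients, so the cumulative
#' count never drifts more than half a patient from the fractional stream
#' and year-end totals that are whole numbers are preserved exactly.
#'
#' @param e an `enrollment_stream`
#' @return an `enrollment_stream` with integer monthly counts
#' @export
integerize_enrollment <- function(e) {
  stopifnot(inherits(e, "enrollment_stream"))
  cum <- round(cumsum(e$new_patients))
  enrollment_stream(diff(c(0, cum)), e$initial_distribution)
}

# one categorical draw per row of u, probabilities taken per-element from the
# rows of P indexed by `from`
draw_categorical <- function(u, P, from) {
  cumP <- t(apply(P, 1L, cumsum))
  dest <- integer(length(u))
  for (c_idx in unique(from)) {
    rows <- which(from == c_idx)
    dest[rows] <- findInterval(u[rows], cumP[c_idx, ]) + 1L
  }
  dest
}

#' Run the microsimulation
#'
#' @param cfg a `sim_config`
#' @return an object of class `sim_result` with `encounters`
#'   (replicates x months x providers integer array), `occupancy`
#'   (replicates x months x combos), and `summary` (per provider-month mean
#'   and standard error of the encounter counts across replicates)
#' @export
simulate_patients <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- cfg$protocol
  Th <- cfg$horizon
  rho <- cfg$attrition_rate
  ids <- names(p$combos)
  prov <- names(p$providers)
  R <- p$reassessment_interval_months
  q <- vapply(p$combos, `[[`, 0L, "interval_months")
  nC <- length(ids)

  S <- matrix(0, nC, length(prov), dimnames = list(ids, prov))
  for (cb in p$combos) S[cb$id, cb$trip_schedule] <- 1
  M <- transition_matrix(p)

  pi_full <- stats::setNames(numeric(nC), ids)
  pi_named <- cfg$enrollment$initial_distribution
  pi_full[names(pi_named)] <- pi_named
  cum_pi <- cumsum(pi_full)

  np <- cfg$enrollment$new_patients[seq_len(Th)]
  s_all <- rep(seq_len(Th), times = np)
  n_pat <- length(s_all)
  n_blocks <- (Th - 1L) %/% R + 1L

  enc <- array(0L, dim = c(cfg$n_replicates, Th, length(prov)),
               dimnames = list(NULL, NULL, prov))
  occ <- array(0L, dim = c(cfg$n_replicates, Th, nC),
               dimnames = list(NULL, NULL, ids))

  for (r in seq_len(cfg$n_replicates)) {
    set.seed((cfg$seed + 62869L * (r - 1L)) %% .Machine$integer.max)
    if (n_pat == 0L) next
    path <- matrix(0L, n_pat, n_blocks)
    path[, 1L] <- findInterval(stats::runif(n_pat), cum_pi) + 1L
    if (n_blocks > 1L) {
      for (b in 2:n_blocks) {
        path[, b] <- draw_categorical(stats::runif(n_pat), M, path[, b - 1L])
      }
    }
    # months survived beyond enrollment; active at age a iff a <= L
    L <- if (rho == 0) rep(Inf, n_pat) else stats::rgeom(n_pat, rho)
    for (t in seq_len(Th)) {
      a <- t - s_all
      alive <- which(a >= 0L & a <= L)
      if (!length(alive)) next
      ages <- a[alive]
      cb <- path[cbind(alive, ages %/% R + 1L)]
      occ[r, t, ] <- tabulate(cb, nC)
      trip <- (ages %% R) %% q[cb] == 0L
      enc[r, t, ] <- as.integer(tabulate(cb[trip], nC) %*% S)
    }
  }

  mean_enc <- apply(enc, c(2, 3), mean)
  se_enc <- apply(enc, c(2, 3), stats::sd) / sqrt(cfg$n_replicates)
  structure(
    list(encounters = enc, occupancy = occ,
         summary = list(mean = mean_enc, se = se_enc),
         config = cfg),
    class = "sim_result"
  )
}

#' Tidy summary of a simulation result
#'
#' @param sim a `sim_result`
#' @return a data.frame with columns `month`, `provider`, `mean`, `se`
#' @export
sim_summary_tidy <- function(sim) {
  stopifnot(inherits(sim, "sim_result"))
  prov <- dimnames(sim$encounters)[[3]]
  Th <- dim(sim$encounters)[2]
  data.frame(
    month = rep(seq_len(Th), times = length(prov)),
    provider = rep(prov, each = Th),
    mean = as.vector(sim$summary$mean),
    se = as.vector(sim$summary$se),
    stringsAsFactors = FALSE
  )
}

#' Tidy per-replicate encounter counts
#'
#' @param sim a `sim_result`
#' @return a data.frame with columns `replicate`, `month`, `provider`,
#'   `encounters`
#' @export
sim_replicates_tidy <- function(sim) {
  stopifnot(inherits(sim, "sim_result"))
  d <- dim(sim$encounters)
  prov <- dimnames(sim$encounters)[[3]]
  data.frame(
    replicate = rep(seq_len(d[1]), times = d[2] * d[3]),
    month = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    provider = rep(prov, each = d[1] * d[2]),
    encounters = as.vector(sim$encounters),
    stringsAsFactors = FALSE
  )
}

#' Compare the deterministic projection with the microsimulation
#'
#' For every provider-month cell, flags whether the deterministic expected
#' encounter count lies within `k_se` standard errors of the Monte-Carlo
#' replicate mean. Cells whose replicate spread is exactly zero (count
#' deterministic under the protocol) must match to 1e-9.
#'
#' @param det a `demand_grid`
#' @param sim a `sim_result` over the same protocol, enrollment and horizon
#' @param k_se tolerance in standard errors (default 4)
#' @return a list with `table` (provider, month, det, mean, se, z, pass),
#'   `max_abs_z` and `all_pass`
#' @export
check_agreement <- function(det, sim, k_se = 4) {
  stopifnot(inherits(det, "demand_grid"), inherits(sim, "sim_result"))
  prov <- colnames(det$encounters)
  if (!identical(dim(det$encounters), dim(sim$summary$mean)) ||
      !identical(prov, dimnames(sim$encounters)[[3]])) {
    stop("deterministic grid and simulation have mismatched dimensions")
  }
  diff <- det$encounters - sim$summary$mean
  se <- sim$summary$se
  z <- ifelse(se > 0, diff / se, ifelse(abs(diff) <= 1e-9, 0, Inf))
  pass <- abs(z) <= k_se
  tab <- data.frame(
    provider = rep(prov, each = nrow(diff)),
    month = rep(det$months, times = length(prov)),
    det = as.vector(det$encounters),
    mean = as.vector(sim$summary$mean),
    se = as.vector(se),
    z = as.vector(z),
    pass = as.vector(pass),
    stringsAsFactors = FALSE
  )
  list(table = tab, max_abs_z = max(abs(z)), all_pass = all(pass))
}

#' @export
print.sim_result <- function(x, ...) {
  d <- dim(x$encounters)
  cat(sprintf("<sim_result> %d replicates x %d months x %d providers (seed %d)\n",
              d[1], d[2], d[3], x$config$seed))
  invisible(x)
}
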