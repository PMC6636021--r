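#' @keywords internal
config_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("config_error", "htnworkforce_error")))
}

check_keys <- function(x, known, where, lax) {
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    if (lax) {
      message("ignoring unknown key '", unknown[[1L]], "' in ", where)
    } else {
      config_error("unknown key '%s' in %s", unknown[[1L]], where)
    }
  }
}

#' Serialize a protocol to plain-list (config) form
#'
#' @param p a `protocol`
#' @return a nested list suitable for the `protocol:` section of a scenario
#'   configuration file
#' @export
protocol_to_config <- function(p) {
  stopifnot(inherits(p, "protocol"))
  out <- list(
    reassessment_interval_months = p$reassessment_interval_months,
    providers = lapply(unname(p$providers), function(x) {
      list(id = x$id, display_name = x$display_name,
           escalation_rank = x$escalation_rank,
           is_lead_capable = x$is_lead_capable)
    }),
    combos = lapply(unname(p$combos), function(x) {
      list(id = x$id, lead = x$lead, interval_months = x$interval_months,
           trip_schedule = x$trip_schedule)
    }),
    transitions = lapply(unname(p$transitions), function(tr) {
      c(list(source = tr$source), tr$outcomes)
    })
  )
  if (!is.null(p$categories)) {
    out$categories <- lapply(seq_len(nrow(p$categories)), function(i) {
      as.list(p$categories[i, , drop = FALSE])
    })
  }
  out
}

#' Build a protocol from its plain-list (config) form
#'
#' @param x a nested list as produced by [protocol_to_config()] or parsed
#'   from the `protocol:` section of a configuration file
#' @return a validated `protocol`
#' @export
protocol_from_config <- function(x) {
  if (isTRUE(x$default)) return(default_protocol())
  providers <- lapply(x$providers, function(pv) {
    provider_type(pv$id, pv$display_name %||% pv$id,
                  pv$escalation_rank %||% 0L,
                  isTRUE(pv$is_lead_capable))
  })
  combos <- lapply(x$combos, function(cb) {
    cf_combo(cb$id, cb$lead, cb$interval_months, unlist(cb$trip_schedule))
  })
  transitions <- lapply(x$transitions, function(tr) {
    transition_rule(tr$source, tr$improve, tr$unchanged, tr$worsen)
  })
  categories <- NULL
  if (!is.null(x$categories)) {
    categories <- do.call(rbind, lapply(x$categories, function(ct) {
      data.frame(id = as.integer(ct$id),
                 state_label = ct$state_label %||% "",
                 management_label = ct$management_label %||% "",
                 combo = ct$combo, stringsAsFactors = FALSE)
    }))
  }
  protocol(providers, combos, transitions, categories,
           x$reassessment_interval_months %||% 6L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate and normalize a scenario configuration
#'
#' Fills documented defaults, checks the schema (unknown keys rejected
#' unless `lax`), and enforces that exactly one of `year_targets` /
#' `monthly_rate` is present and that the horizon covers whole years.
#'
#' @param cfg a nested list (typically parsed from YAML/JSON)
#' @param lax if `TRUE`, unknown keys are dropped with a message instead of
#'   raising a `config_error`
#' @return the normalized configuration, classed `scenario_config`
#' @export
validate_config <- function(cfg, lax = FALSE) {
  known <- c("protocol", "scenario", "initial_distribution", "attrition",
             "horizon_months", "mode", "yearly_rule", "capacity",
             "output_dir", "seed")
  check_keys(cfg, known, "configuration", lax)

  if (is.null(cfg$scenario) || is.null(cfg$scenario$type)) {
    config_error("missing scenario section or scenario type")
  }
  check_keys(cfg$scenario, c("type", "year_targets", "monthly_rate"),
             "scenario", lax)
  has_t <- !is.null(cfg$scenario$year_targets)
  has_r <- !is.null(cfg$scenario$monthly_rate)
  if (has_t && has_r) {
    config_error("scenario must specify exactly one of year_targets / monthly_rate (both present)")
  }
  if (!has_t && !has_r) {
    config_error("scenario must specify exactly one of year_targets / monthly_rate (neither present)")
  }
  if (!cfg$scenario$type %in% c("rampup", "steady")) {
    config_error("unknown scenario type '%s'", cfg$scenario$type)
  }
  if (cfg$scenario$type == "rampup" && !has_t) {
    config_error("rampup scenario requires year_targets")
  }
  if (cfg$scenario$type == "steady" && !has_r) {
    config_error("steady scenario requires monthly_rate")
  }

  cfg$protocol <- cfg$protocol %||% list(default = TRUE)
  cfg$initial_distribution <- unlist(cfg$initial_distribution) %||%
    default_initial_distribution()
  if (is.null(names(cfg$initial_distribution)) ||
      any(!nzchar(names(cfg$initial_distribution)))) {
    config_error("initial_distribution entries must be named by combo id")
  }
  cfg$attrition <- as.numeric(cfg$attrition %||% 0)
  if (cfg$attrition < 0 || cfg$attrition > 1) {
    config_error("attrition must be in [0, 1]")
  }
  if (has_t) {
    cfg$scenario$year_targets <- as.numeric(cfg$scenario$year_targets)
    cfg$horizon_months <- as.integer(cfg$horizon_months %||%
                                       (12L * length(cfg$scenario$year_targets)))
  } else {
    cfg$scenario$monthly_rate <- as.numeric(cfg$scenario$monthly_rate)
    cfg$horizon_months <- as.integer(cfg$horizon_months %||% 36L)
  }
  if (cfg$horizon_months %% 12 != 0) {
    config_error("horizon_months must be a multiple of 12 for yearly reporting")
  }
  cfg$mode <- cfg$mode %||% "phase"
  if (!cfg$mode %in% c("phase", "smoothed")) {
    config_error("mode must be 'phase' or 'smoothed'")
  }
  cfg$yearly_rule <- cfg$yearly_rule %||% "year_average"
  if (!cfg$yearly_rule %in% c("year_average", "year_end")) {
    config_error("yearly_rule must be 'year_average' or 'year_end'")
  }
  if (is.null(cfg$capacity)) {
    warning("no capacity section: applying package default capacity parameters",
            call. = FALSE)
    cm <- default_capacity()
    cfg$capacity <- lapply(cm, function(x) {
      list(days_per_month = x$clinic_days_per_month,
           hours_per_day = x$hours_per_day,
           minutes_per_encounter = x$minutes_per_encounter)
    })
  }
  cap_keys <- c("days_per_month", "hours_per_day", "minutes_per_encounter",
                "contact_minutes_per_month")
  for (j in names(cfg$capacity)) {
    check_keys(cfg$capacity[[j]], cap_keys, paste0("capacity.", j), lax)
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg[intersect(known, names(cfg))], class = "scenario_config")
}

#' Load a scenario configuration file
#'
#' @param path YAML (or JSON, a YAML subset) configuration file
#' @param lax tolerate unknown keys (dropped with a message)
#' @return a validated `scenario_config`
#' @export
load_config <- function(path, lax = FALSE) {
  if (!file.exists(path)) config_error("config file not found: %s", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) config_error("cannot parse %s: %s",
                                                   path, conditionMessage(e)))
  validate_config(raw, lax = lax)
}

#' Write a scenario configuration file
#'
#' @param cfg a `scenario_config` (or raw list; it is validated first)
#' @param path output YAML path
#' @return `path`, invisibly
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(unclass(cfg))
  out <- unclass(cfg)
  # yaml serializes named atomic vectors as plain sequences; keep the map form
  out$initial_distribution <- as.list(out$initial_distribution)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Build the model objects described by a configuration
#'
#' @param cfg a `scenario_config`
#' @return a list with `protocol`, `enrollment` and `capacity`
#' @export
build_scenario <- function(cfg) {
  cfg <- validate_config(unclass(cfg))
  p <- protocol_from_config(cfg$protocol)
  pi <- cfg$initial_distribution
  e <- if (cfg$scenario$type == "rampup") {
    enrollment_from_year_targets(cfg$scenario$year_targets, pi)
  } else {
    constant_enrollment(cfg$scenario$monthly_rate, cfg$horizon_months, pi)
  }
  if (length(e$new_patients) < cfg$horizon_months) {
    config_error("enrollment stream (%d months) shorter than horizon (%d)",
                 length(e$new_patients), cfg$horizon_months)
  }
  caps <- lapply(names(cfg$capacity), function(j) {
    x <- cfg$capacity[[j]]
    provider_capacity(j, x$days_per_month %||% 2, x$hours_per_day %||% 6,
                      x$minutes_per_encounter,
                      x$contact_minutes_per_month)
  })
  list(protocol = p, enrollment = e, capacity = capacity_model(caps))
}

#' Run a scenario end to end
#'
#' Executes the protocol-to-demand-to-capacity-to-FTE pipeline. With an
#' output directory, writes the worksheet-style CSVs (A: per-patient
#' encounter schedule of a month-1 unit cohort; B: expected occupancy per
#' combo; C: expected encounters per provider; D: yearly FTE), tidy CSVs and
#' a JSON run manifest.
#'
#' @param cfg a `scenario_config` (see [load_config()])
#' @param outdir optional output directory, created if missing
#' @return a list with `demand` (`demand_grid`), `fte` (`fte_report`),
#'   `yearly` (data.frame), `scenario` (model objects) and `files`
#' @export
run_scenario <- function(cfg, outdir = NULL) {
  cfg <- validate_config(unclass(cfg))
  sc <- build_scenario(cfg)
  d <- aggregate_demand(sc$protocol, sc$enrollment,
                        attrition_rate = cfg$attrition,
                        T = cfg$horizon_months, mode = cfg$mode)
  r <- fte_series(d, sc$capacity)
  y <- yearly_fte(r, rule = cfg$yearly_rule)

  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, name) {
      f <- file.path(outdir, name)
      utils::write.csv(x, f, row.names = FALSE)
      f
    }
    unit <- project_unit_cohort(sc$protocol, 1L, cfg$horizon_months,
                                cfg$attrition, pi = sc$enrollment$initial_distribution,
                                mode = cfg$mode)
    ws_a <- demand_wide(structure(
      list(months = seq_len(cfg$horizon_months), encounters = unit$encounters,
           occupancy = unit$occupancy, mode = cfg$mode,
           attrition_rate = cfg$attrition), class = "demand_grid"))
    files <- c(
      w(ws_a, "worksheet_A.csv"),
      w(demand_wide(d, "occupancy"), "worksheet_B.csv"),
      w(demand_wide(d, "encounters"), "worksheet_C.csv"),
      w(y, "worksheet_D.csv"),
      w(demand_tidy(d), "demand_monthly.csv"),
      w(occupancy_tidy(d), "occupancy_monthly.csv"),
      w(fte_tidy(r), "fte_monthly.csv"),
      w(y, "fte_yearly.csv")
    )
    manifest <- list(
      package = "htnworkforce",
      version = as.character(utils::packageVersion("htnworkforce")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
      config = unclass(cfg)
    )
    mf <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
    files <- c(files, mf)
  }
  list(demand = d, fte = r, yearly = y, scenario = sc, config = cfg,
       files = files)
}

#' Path to a packaged example configuration
#'
#' @param name file name under the package's `extdata/` (default lists them)
#' @return full path, or the available names when `name` is missing
#' @export
example_config <- function(name = NULL) {
  if (is.null(name)) {
    return(dir(system.file("extdata", package = "htnworkforce")))
  }
  path <- system.file("extdata", name, package = "htnworkforce")
  if (!nzchar(path)) config_error("no packaged example '%s'", name)
  path
}
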