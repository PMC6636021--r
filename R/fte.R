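#' @keywords internal
infeasible_capacity_error <- function(provider, month) {
  stop(errorCondition(
    sprintf("zero capacity for provider '%s' with positive demand at month %d",
            provider, month),
    class = c("infeasible_capacity_error", "htnworkforce_error")
  ))
}

#' Monthly FTE requirement series
#'
#' The model's final output: for every provider and month, the full-time
#' equivalents needed to meet demand, `F_j(t) = v_j(t) / E_j`.
#'
#' @param d a `demand_grid`
#' @param cm a `capacity_model` covering every provider with nonzero demand
#' @return an object of class `fte_report` with element `monthly`
#'   (T x providers matrix of FTEs) plus the capacity vector used
#' @export
fte_series <- function(d, cm) {
  stopifnot(inherits(d, "demand_grid"), inherits(cm, "capacity_model"))
  prov <- colnames(d$encounters)
  E <- capacity_per_fte(cm)
  missing <- setdiff(prov[colSums(d$encounters) > 0], names(E))
  if (length(missing)) {
    stop("no capacity defined for provider '", missing[[1L]], "'")
  }
  monthly <- matrix(0, nrow(d$encounters), length(prov),
                    dimnames = list(NULL, prov))
  for (j in prov) {
    v <- d$encounters[, j]
    if (!j %in% names(E) || E[[j]] == 0) {
      bad <- which(v > 0)
      if (length(bad)) infeasible_capacity_error(j, bad[[1L]])
      next  # zero demand throughout: FTE stays 0
    }
    monthly[, j] <- v / E[[j]]
  }
  structure(
    list(monthly = monthly, months = d$months, capacity = E, mode = d$mode),
    class = "fte_report"
  )
}

#' Yearly FTE summary
#'
#' Collapses the monthly FTE series to one figure per provider per year:
#' `year_average` is the mean of the 12 monthly values (equivalently, total
#' yearly encounters divided by 12 E_j); `year_end` takes the December
#' (month 12, 24, 36, ...) value.
#'
#' @param r an `fte_report`
#' @param rule aggregation rule, `"year_average"` (default) or `"year_end"`
#' @return a data.frame with columns `year`, `provider`, `fte`,
#'   `fte_ceiling` (the smallest whole-staff count covering the requirement)
#' @export
yearly_fte <- function(r, rule = c("year_average", "year_end")) {
  rule <- match.arg(rule)
  stopifnot(inherits(r, "fte_report"))
  T <- nrow(r$monthly)
  if (T %% 12 != 0) stop("horizon must cover whole years for yearly reporting")
  years <- T %/% 12
  prov <- colnames(r$monthly)
  agg <- function(y, j) {
    rows <- (12 * (y - 1) + 1):(12 * y)
    if (rule == "year_average") mean(r$monthly[rows, j]) else r$monthly[12 * y, j]
  }
  out <- expand.grid(year = seq_len(years), provider = prov,
                     stringsAsFactors = FALSE)
  out$fte <- mapply(agg, out$year, out$provider)
  out$fte_ceiling <- ceiling(out$fte - 1e-9)
  out
}

#' Tidy long-format view of a monthly FTE report
#'
#' @param r an `fte_report`
#' @return a data.frame with columns `month`, `provider`, `fte`
#' @export
fte_tidy <- function(r) {
  stopifnot(inherits(r, "fte_report"))
  prov <- colnames(r$monthly)
  data.frame(
    month = rep(r$months, times = length(prov)),
    provider = rep(prov, each = length(r$months)),
    fte = as.vector(r$monthly),
    stringsAsFactors = FALSE
  )
}

#' @export
print.fte_report <- function(x, ...) {
  cat(sprintf("<fte_report> %d months x %d providers\n",
              nrow(x$monthly), ncol(x$monthly)))
  if (nrow(x$monthly) %% 12 == 0) {
    y <- yearly_fte(x)
    print(utils::head(stats::reshape(
      y[, c("year", "provider", "fte")], idvar = "year",
      timevar = "provider", direction = "wide"
    ), 10))
  }
  invisible(x)
}

# set a value at a dotted path inside a nested list, erroring on unknown path
set_config_path <- function(cfg, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  ref <- cfg
  for (k in keys) {
    if (!is.list(ref) || !k %in% names(ref)) {
      stop("unresolvable parameter path '", path, "'")
    }
    ref <- ref[[k]]
  }
  cfg[[keys]] <- value
  cfg
}

#' Sensitivity sweep over scenario parameters
#'
#' Runs the full pipeline once per point of a full-factorial grid of
#' parameter values, each addressed by a dotted path into the scenario
#' configuration (e.g. `"capacity.nurse.minutes_per_encounter"`), and
#' returns the yearly FTE table per run plus a min/median/max summary per
#' provider-year.
#'
#' @param cfg a scenario configuration (see [load_config()])
#' @param grid named list: dotted parameter path -> vector of values
#' @param max_runs guard on the grid size (default 10000)
#' @return a list with `runs` (long data.frame: one row per grid point x
#'   provider x year, with one column per swept parameter) and `summary`
#'   (per provider-year min/median/max FTE)
#' @export
sensitivity_sweep <- function(cfg, grid = list(), max_runs = 10000L) {
  cfg <- validate_config(cfg)
  if (length(grid) == 0L) {
    res <- run_scenario(cfg)
    return(list(runs = res$yearly, summary = stats::aggregate(
      fte ~ provider + year, res$yearly,
      function(v) c(min = min(v), median = stats::median(v), max = max(v))
    )))
  }
  points <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (nrow(points) > max_runs) {
    stop("sensitivity grid has ", nrow(points), " points; max_runs = ", max_runs)
  }
  # probe every path once up front so a typo fails before any runs
  for (path in names(grid)) set_config_path(cfg, path, grid[[path]][[1L]])

  runs <- vector("list", nrow(points))
  for (i in seq_len(nrow(points))) {
    cfg_i <- cfg
    for (path in names(grid)) {
      cfg_i <- set_config_path(cfg_i, path, points[i, path])
    }
    y <- run_scenario(cfg_i)$yearly
    for (path in names(grid)) y[[path]] <- points[i, path]
    runs[[i]] <- y
  }
  runs <- do.call(rbind, runs)
  summ <- stats::aggregate(fte ~ provider + year, runs, function(v) {
    c(min = min(v), median = stats::median(v), max = max(v))
  })
  summ <- cbind(summ[c("provider", "year")], as.data.frame(summ$fte))
  list(runs = runs, summary = summ)
}
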