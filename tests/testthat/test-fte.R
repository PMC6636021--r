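test_that("FTE is demand over capacity, cell by cell", {
  p <- default_protocol()
  d <- aggregate_demand(p, constant_enrollment(100, 12, default_pi()))
  cm <- default_capacity()
  r <- fte_series(d, cm)
  E <- capacity_per_fte(cm)
  for (j in colnames(d$encounters)) {
    expect_equal(r$monthly[, j], d$encounters[, j] / E[[j]], tolerance = 1e-12)
  }
  expect_true(all(r$monthly >= 0))
  expect_true(all(r$monthly[d$encounters == 0] == 0))
  # identity check: demand equal to one capacity-month is exactly 1 FTE
  expect_equal(unname(d$encounters[1, "nurse"] / E[["nurse"]]),
               unname(r$monthly[1, "nurse"]), tolerance = 1e-12)
})

test_that("zero demand gives a zero report; zero capacity with demand is infeasible", {
  p <- default_protocol()
  dz <- aggregate_demand(p, constant_enrollment(0, 12, default_pi()))
  rz <- fte_series(dz, default_capacity())
  expect_true(all(rz$monthly == 0))

  d <- aggregate_demand(p, constant_enrollment(10, 12, default_pi()))
  cm <- default_capacity()
  cm[["pharmacist"]]$contact_minutes_per_month <- 0
  expect_error(fte_series(d, cm), "pharmacist",
               class = "infeasible_capacity_error")
})

test_that("yearly aggregation: year_average is the within-year mean, year_end the December value", {
  p <- default_protocol()
  d <- aggregate_demand(p, constant_enrollment(100, 24, default_pi()))
  r <- fte_series(d, default_capacity())
  ya <- yearly_fte(r, "year_average")
  ye <- yearly_fte(r, "year_end")
  for (y in 1:2) {
    rows <- (12 * y - 11):(12 * y)
    expect_equal(ya$fte[ya$year == y & ya$provider == "nurse"],
                 mean(r$monthly[rows, "nurse"]))
    expect_equal(ye$fte[ye$year == y & ye$provider == "nurse"],
                 unname(r$monthly[12 * y, "nurse"]))
    # year_average equals total yearly encounters / (12 E_j)
    expect_equal(ya$fte[ya$year == y & ya$provider == "nurse"],
                 sum(d$encounters[rows, "nurse"]) / (12 * r$capacity[["nurse"]]),
                 tolerance = 1e-12)
  }
  expect_true(all(ya$fte_ceiling >= ya$fte - 1e-9))
  expect_true(all(ya$fte_ceiling == ceiling(ya$fte - 1e-9)))

  # constant monthly FTE: both rules coincide
  pc <- one_combo_protocol(1L)
  # 120-patient standing pool via one enrollment month and a 12-month horizon
  dcon <- aggregate_demand(pc, enrollment_stream(c(120, rep(0, 11)),
                                                 point_mass("Nq1")))
  rcon <- fte_series(dcon, capacity_model(
    provider_capacity("nurse", 2, 6, 8.9),
    provider_capacity("pharmacist", 2, 6, 3),
    provider_capacity("triage", 2, 6, 3)
  ))
  expect_equal(yearly_fte(rcon, "year_average")$fte,
               yearly_fte(rcon, "year_end")$fte, tolerance = 1e-12)

  # partial years are refused
  d18 <- aggregate_demand(p, constant_enrollment(100, 18, default_pi()))
  expect_error(yearly_fte(fte_series(d18, default_capacity())), "whole years")
})

test_that("FTE is homogeneous: degree 1 in enrollment, degree -1 in capacity", {
  p <- default_protocol()
  pi <- default_pi()
  d1 <- aggregate_demand(p, constant_enrollment(50, 24, pi))
  d2 <- aggregate_demand(p, constant_enrollment(100, 24, pi))
  cm <- default_capacity()
  r1 <- fte_series(d1, cm)
  r2 <- fte_series(d2, cm)
  expect_equal(r2$monthly, 2 * r1$monthly, tolerance = 1e-12)

  cm_half <- default_capacity()
  for (j in names(cm_half)) cm_half[[j]]$minutes_per_encounter <-
    cm_half[[j]]$minutes_per_encounter * 2  # halves E_j
  r_half <- fte_series(d1, cm_half)
  expect_equal(r_half$monthly, 2 * r1$monthly, tolerance = 1e-12)
})

test_that("total FTE under steady enrollment without attrition never decreases", {
  p <- default_protocol()
  d <- aggregate_demand(p, constant_enrollment(100, 36, default_pi()))
  r <- fte_series(d, default_capacity())
  total <- rowSums(r$monthly)
  expect_true(all(diff(total) >= -1e-9))
})

test_that("sensitivity sweep: empty grid is a single base run, FTE increases with encounter time", {
  cfg <- load_config(example_config("steady.yaml"))
  cfg$horizon_months <- 12L
  base <- sensitivity_sweep(cfg)
  expect_equal(nrow(base$runs), 12 / 12 * 5)  # 1 year x 5 providers

  sw <- sensitivity_sweep(cfg, list(
    "capacity.nurse.minutes_per_encounter" = c(3.5, 8.9, 20.2)
  ))
  nurse <- sw$runs[sw$runs$provider == "nurse" & sw$runs$year == 1, ]
  nurse <- nurse[order(nurse$capacity.nurse.minutes_per_encounter), ]
  expect_equal(nrow(nurse), 3L)
  expect_true(all(diff(nurse$fte) > 0))
  # other providers unaffected by the nurse parameter
  ph <- sw$runs[sw$runs$provider == "pharmacist" & sw$runs$year == 1, ]
  expect_equal(length(unique(round(ph$fte, 10))), 1L)

  expect_error(sensitivity_sweep(cfg, list("capacity.nurse.not_a_key" = 1:2)),
               "unresolvable")
  expect_error(
    sensitivity_sweep(cfg, list(
      "capacity.nurse.minutes_per_encounter" = 1:200,
      "scenario.monthly_rate" = 1:200
    ), max_runs = 100),
    "max_runs"
  )

  # doubling enrollment doubles every FTE (linearity through the pipeline)
  sw2 <- sensitivity_sweep(cfg, list("scenario.monthly_rate" = c(100, 200)))
  lo <- sw2$runs[sw2$runs$scenario.monthly_rate == 100, ]
  hi <- sw2$runs[sw2$runs$scenario.monthly_rate == 200, ]
  key <- order(lo$provider, lo$year)
  expect_equal(hi$fte[order(hi$provider, hi$year)], 2 * lo$fte[key],
               tolerance = 1e-12)
})
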