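test_that("enrollment streams: constant rate and year targets", {
  pi <- default_pi()
  e <- constant_enrollment(100, 36, pi)
  expect_length(e$new_patients, 36L)
  expect_true(all(e$new_patients == 100))
  expect_equal(cumulative_enrollment(e)[12], 1200)
  expect_equal(cumulative_enrollment(e)[36], 3600)
  expect_true(all(constant_enrollment(0, 12, pi)$new_patients == 0))
  expect_error(constant_enrollment(-5, 12, pi), "rate")

  r <- enrollment_from_year_targets(c(1000, 3000, 7000), pi)
  expect_equal(r$new_patients[1], 1000 / 12)
  expect_equal(r$new_patients[13], 2000 / 12)
  expect_equal(r$new_patients[25], 4000 / 12)
  expect_equal(cumulative_enrollment(r)[c(12, 24, 36)], c(1000, 3000, 7000))
  expect_equal(enrollment_from_year_targets(1200, pi)$new_patients,
               rep(100, 12))
  expect_error(enrollment_from_year_targets(c(500, 400), pi), "non-decreasing")
  expect_error(enrollment_stream(rep(1, 12), c(Nq1 = 0.7, Nq2 = 0.2)),
               "sum to 1")
})

test_that("a unit monthly-visit cohort generates one trip per month for every scheduled provider", {
  p <- one_combo_protocol(1L)
  u <- project_unit_cohort(p, 1, 6, pi = point_mass("Nq1"))
  for (j in c("nurse", "pharmacist", "triage")) {
    expect_equal(unname(u$encounters[, j]), rep(1, 6))
  }
  expect_equal(unname(rowSums(u$occupancy)), rep(1, 6))
})

test_that("2-monthly cohort: phase trips at months 1,3,5; smoothed spreads 0.5/month; totals agree", {
  p <- one_combo_protocol(2L)
  ph <- project_unit_cohort(p, 1, 6, pi = point_mass("Nq2"), mode = "phase")
  expect_equal(unname(ph$encounters[, "nurse"]), c(1, 0, 1, 0, 1, 0))
  sm <- project_unit_cohort(p, 1, 6, pi = point_mass("Nq2"), mode = "smoothed")
  expect_equal(unname(sm$encounters[, "nurse"]), rep(0.5, 6))
  expect_equal(sum(ph$encounters[, "nurse"]), sum(sm$encounters[, "nurse"]))
})

test_that("first re-assessment of an Nq1 cohort splits nurse demand 2/3 and clinical officer 1/3", {
  # hand enumeration of the three-outcome tree at month 7: 1/3 stays Nq1
  # (trips), 1/3 improves to Nq2 (re-assessment visit at month 7), 1/3
  # worsens to Cq1 (trips)
  p <- default_protocol()
  u <- project_unit_cohort(p, 1, 7, pi = c(Nq1 = 1))
  expect_equal(unname(u$encounters[7, "nurse"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(u$encounters[7, "clinical_officer"]), 1 / 3,
               tolerance = 1e-12)
  expect_equal(unname(u$occupancy[7, c("Nq1", "Nq2", "Cq1")]),
               rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("occupancy decays with the monthly survival curve under attrition", {
  p <- default_protocol()
  rho <- 0.05
  u <- project_unit_cohort(p, 3, 24, attrition_rate = rho, pi = default_pi())
  for (t in 3:24) {
    expect_equal(sum(u$occupancy[t, ]), (1 - rho)^(t - 3), tolerance = 1e-9)
  }
  expect_true(all(u$encounters[1:2, ] == 0))
  expect_true(all(u$occupancy[1:2, ] == 0))
})

test_that("aggregate demand reproduces hand-enumerated early months of the steady scenario", {
  p <- default_protocol()
  e <- constant_enrollment(100, 12, default_pi())
  d <- aggregate_demand(p, e)
  # month 1: every combo's first trip is in the enrollment month
  expect_equal(unname(d$encounters[1, "nurse"]), 100)
  expect_equal(unname(d$encounters[1, "pharmacist"]), 100)
  # month 2: 60 Nq1 returnees + 100 newly enrolled
  expect_equal(unname(d$encounters[2, "nurse"]), 160)
  # month 3: 60+32 returnees from month-1 cohort, 60 from month-2, 100 new
  expect_equal(unname(d$encounters[3, "nurse"]), 252)
})

test_that("patient mass is conserved: cumulative enrollment with rho = 0, attrition-discounted otherwise", {
  p <- default_protocol()
  e <- enrollment_from_year_targets(c(1000, 3000), default_pi())
  d0 <- aggregate_demand(p, e)
  expect_equal(unname(rowSums(d0$occupancy)), cumulative_enrollment(e),
               tolerance = 1e-6)
  rho <- 0.03
  dr <- aggregate_demand(p, e, attrition_rate = rho)
  expected <- vapply(seq_len(24), function(t) {
    sum(e$new_patients[1:t] * (1 - rho)^(t - (1:t)))
  }, 0)
  expect_equal(unname(rowSums(dr$occupancy)), expected, tolerance = 1e-9)
})

test_that("demand is linear and superposable in the enrollment stream", {
  p <- default_protocol()
  pi <- default_pi()
  set.seed(7)
  a <- enrollment_stream(round(runif(24, 0, 50)), pi)
  b <- enrollment_stream(round(runif(24, 0, 50)), pi)
  da <- aggregate_demand(p, a)
  db <- aggregate_demand(p, b)
  dsum <- aggregate_demand(p, enrollment_stream(a$new_patients + b$new_patients, pi))
  expect_equal(dsum$encounters, da$encounters + db$encounters, tolerance = 1e-10)
  d3a <- aggregate_demand(p, enrollment_stream(3 * a$new_patients, pi))
  expect_equal(d3a$encounters, 3 * da$encounters, tolerance = 1e-10)
})

test_that("phase and smoothed modes agree on every full re-assessment block", {
  p <- default_protocol()
  # per enrollment cohort: totals over every complete 6-month block coincide
  for (s in c(1, 4, 7, 13)) {
    uph <- project_unit_cohort(p, s, 24, mode = "phase")
    usm <- project_unit_cohort(p, s, 24, mode = "smoothed")
    blocks <- seq(s, 24, by = 6)
    for (b0 in blocks[-length(blocks)]) {
      rows <- b0:(b0 + 5)
      expect_equal(colSums(uph$encounters[rows, , drop = FALSE]),
                   colSums(usm$encounters[rows, , drop = FALSE]),
                   tolerance = 1e-10)
    }
  }
  # block-aligned enrollment (new cohorts only at months 1, 7, 13, 19):
  # yearly aggregate totals then consist of complete blocks and coincide too
  np <- rep(0, 24)
  np[c(1, 7, 13, 19)] <- 150
  e <- enrollment_stream(np, default_pi())
  ph <- aggregate_demand(p, e, mode = "phase")
  sm <- aggregate_demand(p, e, mode = "smoothed")
  for (y in 1:2) {
    rows <- (12 * y - 11):(12 * y)
    expect_equal(colSums(ph$encounters[rows, ]), colSums(sm$encounters[rows, ]),
                 tolerance = 1e-8)
  }
  # with mid-year enrollment the two modes split partially elapsed blocks
  # differently, so monthly series differ while block totals do not
  e2 <- constant_enrollment(50, 12, default_pi())
  ph2 <- aggregate_demand(p, e2, mode = "phase")
  sm2 <- aggregate_demand(p, e2, mode = "smoothed")
  expect_false(isTRUE(all.equal(ph2$encounters, sm2$encounters)))
})

test_that("demand is monotone in the enrollment stream and zero for zero enrollment", {
  p <- default_protocol()
  pi <- default_pi()
  base <- constant_enrollment(10, 18, pi)
  d0 <- aggregate_demand(p, base)
  bumped <- base$new_patients
  bumped[5] <- bumped[5] + 7
  d1 <- aggregate_demand(p, enrollment_stream(bumped, pi))
  expect_true(all(d1$encounters >= d0$encounters - 1e-12))
  dz <- aggregate_demand(p, constant_enrollment(0, 18, pi))
  expect_true(all(dz$encounters == 0))
  expect_true(all(dz$occupancy == 0))
})

test_that("tidy and wide exports carry the grid faithfully", {
  p <- default_protocol()
  d <- aggregate_demand(p, constant_enrollment(10, 12, default_pi()))
  td <- demand_tidy(d)
  expect_equal(nrow(td), 12 * 5)
  expect_equal(sum(td$expected_encounters), sum(d$encounters))
  expect_equal(
    td$expected_encounters[td$provider == "nurse" & td$month == 2],
    unname(d$encounters[2, "nurse"])
  )
  wd <- demand_wide(d)
  expect_identical(names(wd)[1], "provider")
  expect_identical(names(wd)[-1], paste0("M", 1:12))
  expect_equal(wd[wd$provider == "nurse", "M2"],
               unname(d$encounters[2, "nurse"]))
  ocw <- demand_wide(d, "occupancy")
  expect_identical(names(ocw)[1], "combo")
  expect_equal(sum(ocw[, -1]), sum(d$occupancy))
})
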