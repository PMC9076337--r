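test_that("discount factors follow the closed form", {
  expect_equal(discount_factor(0.025, 3), 1.025^-2)
  expect_equal(discount_factor(0.025, 3), 0.951814, tolerance = 1e-6)
  expect_equal(discount_factor(0.025, 1), 1)
  expect_equal(discount_factor(0, 1:10), rep(1, 10))
  expect_equal(discount_factor(0.025, 1, offset = 1L), 1 / 1.025)
})

test_that("annual medication cost scales per-diem by therapy days and adherence", {
  expect_equal(annual_medication_cost(0.30, 1.0), 0.30 * 365.25)
  expect_equal(annual_medication_cost(0.30, 1.0), 109.575)
  expect_equal(annual_medication_cost(0.24, 0), 0)
  expect_equal(annual_medication_cost(0.24, 0.653), 0.24 * 365.25 * 0.653)
  expect_error(annual_medication_cost(0.24, 1.2), "adherence")
})

test_that("stage costs aggregate items per category", {
  items <- list(
    resource_item("visit", "addon_followup", 25.32, 2),
    resource_item("slit", "addon_followup", 28.29, 1),
    resource_item("tono", "addon_followup", 41.66, 1),
    resource_item("lub", "osd_management", 0.27, 0.5,
                  type = "probability", days_per_year = 365.25),
    resource_item("workup", "diagnosis", 100, 1))
  cs <- stage_annual_cost(items, "A")
  expect_equal(unname(cs["addon_followup", "stage0"]), 25.32 * 2 + 28.29 + 41.66)
  expect_equal(unname(cs["osd_management", "stage0"]), 0.27 * 0.5 * 365.25)
  expect_equal(unname(cs["diagnosis", ]), rep(0, 6))  # one-time excluded here
  expect_equal(unname(stage_annual_cost(list(), "A")), matrix(0, 4, 6),
               ignore_attr = TRUE)
  cs2 <- stage_annual_cost(items[1:2], "A")
  expect_equal(sum(cs2[, "stage0"]), 25.32 * 2 + 28.29)
})

test_that("effective utility applies expected OSD disutility with a floor", {
  expect_equal(effective_utility(0.900, 0.762, -0.120), 0.80856)
  expect_equal(effective_utility(0.9, 0, -0.12), 0.9)
  expect_equal(effective_utility(0.9, 0.8, 0), 0.9)
  expect_equal(effective_utility(0.05, 1, -0.12), 0)
})

test_that("accrual reproduces geometric closed forms under static disease", {
  ps <- static_parameterset(flat_q = 0, horizon = 2L)
  # single effective utility, flat yearly cost 100, r = 0.025
  ps$utilities$u["A", ] <- 0.8
  ps$osd[["A"]] <- 0
  ps$resources <- list(resource_item("flat", "addon_followup", 100, 1))
  names(ps$resources) <- "flat"
  ps$adherence$A[] <- 0
  led <- accrue(person_time(run_trace(ps, "A"), TRUE), ps, "A")
  expect_equal(sum(led$cost_disc[, "addon_followup"]), 100 + 100 / 1.025,
               tolerance = 1e-9)
  expect_equal(sum(led$cost_disc), 197.56, tolerance = 0.01)
  expect_equal(sum(led$qaly), 1.6, tolerance = 1e-12)
  expect_equal(led$qaly[1], 0.8, tolerance = 1e-12)
  expect_equal(sum(led$cost[, "medication"]), 0)
})

test_that("increments, dominance labels and NMB follow their definitions", {
  mk <- function(dC, dE) {
    la <- structure(list(cost_disc = matrix(1000 + dC, 1, 4,
                                            dimnames = list(NULL, c("diagnosis",
                                              "medication", "addon_followup",
                                              "osd_management"))) / 4,
                         ly_disc = 4, qaly_disc = 2 + dE,
                         cost = matrix(0, 1, 4), ly = 4, qaly = 2 + dE),
                    class = "accrual_ledger")
    lb <- structure(list(cost_disc = matrix(1000, 1, 4,
                                            dimnames = list(NULL, c("diagnosis",
                                              "medication", "addon_followup",
                                              "osd_management"))) / 4,
                         ly_disc = 4, qaly_disc = 2,
                         cost = matrix(0, 1, 4), ly = 4, qaly = 2),
                    class = "accrual_ledger")
    cua_compare(la, lb, wtp_grid = c(30000))
  }
  r <- mk(7.39, 0.348)
  expect_equal(r$label, "icur")
  expect_equal(r$icur, 7.39 / 0.348, tolerance = 1e-9)
  expect_equal(r$icur, 21.24, tolerance = 0.01)
  expect_equal(r$nmb, 30000 * 0.348 - 7.39, tolerance = 1e-9)
  expect_equal(r$nmb, 10432.61, tolerance = 0.01)

  expect_equal(mk(-5, 0.1)$label, "strongly-dominant")
  expect_equal(mk(5, -0.1)$label, "dominated")
  expect_equal(mk(-5, -0.1)$label, "icur")
  expect_equal(mk(0, 0)$label, "equivalent")
  expect_equal(mk(-3, 0)$label, "strongly-dominant")
})

test_that("category shares are percentages of the overall cost", {
  sh <- category_shares(c(diagnosis = 191.60, medication = 341.28,
                          addon_followup = 1337.59, osd_management = 477.27))
  expect_equal(unname(sh["addon_followup"]), 56.97, tolerance = 0.005)
  expect_equal(unname(sh["medication"]), 14.54, tolerance = 0.005)
  expect_equal(sum(sh), 100, tolerance = 1e-9)
  expect_equal(unname(category_shares(c(a = 7))), 100)
  expect_error(category_shares(c(a = 0)), "positive")
})

test_that("the ICUR is invariant to cohort size", {
  ps1 <- generate_parameterset(synth_config(seed = 4, cohort_size = 1000))
  ps2 <- generate_parameterset(synth_config(seed = 4, cohort_size = 250))
  r1 <- run_cua(ps1)$result
  r2 <- run_cua(ps2)$result
  expect_equal(r1$delta_cost, r2$delta_cost, tolerance = 1e-9)
  expect_equal(r1$delta_qaly, r2$delta_qaly, tolerance = 1e-9)
})

test_that("identical arms produce exactly zero increments", {
  ps <- generate_parameterset(synth_config(seed = 8, preset = "null"))
  r <- run_cua(ps)$result
  expect_identical(r$delta_cost, 0)
  expect_identical(r$delta_qaly, 0)
  expect_equal(r$label, "equivalent")
})

test_that("discounting is monotone and QALYs never exceed life-years", {
  ps <- generate_parameterset(synth_config(seed = 13))
  totals <- sapply(c(0, 0.025, 0.045), function(r) {
    ps$econ$discount_rate <- r
    led <- accrue(person_time(run_trace(ps, "A"), TRUE), ps, "A")
    c(cost = sum(led$cost_disc), ly = sum(led$ly_disc),
      qaly = sum(led$qaly_disc), cost_u = sum(led$cost),
      ly_u = sum(led$ly), qaly_u = sum(led$qaly))
  })
  expect_true(all(diff(totals["cost", ]) < 0))
  expect_true(all(diff(totals["ly", ]) < 0))
  expect_true(all(diff(totals["qaly", ]) < 0))
  expect_true(all(totals["cost", ] <= totals["cost_u", ] + 1e-9))
  expect_true(all(totals["qaly", ] <= totals["ly", ]))

  # with r = 0 and no deaths, per-person life-years equal the horizon
  ps0 <- static_parameterset(flat_q = 0)
  ps0$econ$discount_rate <- 0
  led0 <- accrue(person_time(run_trace(ps0, "A"), TRUE), ps0, "A")
  expect_equal(sum(led0$ly_disc), 5, tolerance = 1e-12)
})
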