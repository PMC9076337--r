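test_that("stay-probability calibration solves the retention equation", {
  expect_equal(calibrate_stay_probability(0.65, 5, 0), 0.65^(1 / 5))
  expect_equal(calibrate_stay_probability(0.65, 5, 0), 0.9174, tolerance = 1e-4)
  expect_equal(calibrate_stay_probability(1, 5, 0), 1)
  expect_equal(calibrate_stay_probability(0.65, 5, 0.01), 0.65^(1 / 5) / 0.99)
  expect_equal(calibrate_stay_probability(0.65, 5, 0.01), 0.9267, tolerance = 1e-4)
  # the closed form inverts the retention identity
  for (tgt in c(0.5, 0.65, 0.8)) for (q in c(0, 0.01, 0.024)) {
    p <- calibrate_stay_probability(tgt, 5, q)
    expect_equal(((1 - q) * p)^5, tgt, tolerance = 1e-12)
  }
  expect_error(calibrate_stay_probability(0.9, 5, 0.1), "infeasible")
  expect_error(calibrate_stay_probability(0, 5, 0.01), "target")
})

test_that("generated life tables meet the mortality-table invariants", {
  lt <- generate_life_table(flat_q = 0.01)
  expect_true(all(lt$qx == 0.01))
  expect_setequal(unique(lt$sex), c("f", "m"))
  for (s in c("f", "m")) expect_equal(diff(sort(lt$age[lt$sex == s])),
                                      rep(1, sum(lt$sex == s) - 1))
  lt2 <- generate_life_table(base_q = 0.002, base_age = 47, doubling_years = 10)
  expect_equal(lt2$qx[lt2$sex == "f" & lt2$age == 57],
               2 * lt2$qx[lt2$sex == "f" & lt2$age == 47])
  expect_equal(lt2$qx[lt2$sex == "f" & lt2$age == 47], 0.002)
})

test_that("generation is seed-deterministic and always valid", {
  g1 <- generate_parameterset(synth_config(seed = 7))
  g2 <- generate_parameterset(synth_config(seed = 7))
  expect_identical(g1, g2)
  g3 <- generate_parameterset(synth_config(seed = 8))
  expect_false(identical(g1$adherence, g3$adherence))
  for (seed in c(1, 2, 3, 10, 99))
    expect_length(validate_parameters(generate_parameterset(synth_config(seed = seed))), 0L)
})

test_that("generated sets encode the configured arm contrasts", {
  ps <- generate_parameterset(synth_config(seed = 10))
  lub <- ps$resources[["osd_lubricant"]]$value
  expect_true(all(lub["B", ] - lub["A", ] >= 0.0588 - 1e-12))
  expect_true(all(lub["B", ] - lub["A", ] <= 0.1134 + 1e-12))
  cic <- ps$resources[["osd_ciclosporin"]]$value
  expect_true(all(cic["B", ] - cic["A", ] >= 0.0431 - 1e-12 &
                  cic["B", ] - cic["A", ] <= 0.0539 + 1e-12))
  sch <- ps$resources[["osd_schirmer"]]$value
  expect_true(all(sch["B", ] - sch["A", ] >= 0.0729 - 1e-12 &
                  sch["B", ] - sch["A", ] <= 0.0957 + 1e-12))

  # adherence advantage in stages 0-3, equality in stages 4-5
  adv <- ps$adherence$A - ps$adherence$B
  expect_true(all(adv[1:4, ] >= 0.047 - 1e-12 & adv[1:4, ] <= 0.098 + 1e-12))
  expect_true(all(adv[5:6, ] == 0))

  # utilities monotone decreasing with the configured arm gap
  expect_true(all(diff(ps$utilities$u["A", ]) < 0))
  expect_true(all(diff(ps$utilities$u["B", ]) < 0))
  expect_equal(unname(ps$utilities$u["A", ] - ps$utilities$u["B", ]),
               c(0, 0.007, 0.013, 0.013, 0.017, 0))
  expect_equal(unname(ps$utilities$u["A", c(1, 6)]), c(0.900, 0.790))
})

test_that("arm-A advantages always translate into non-negative QALY gains", {
  for (seed in 1:15) {
    ps <- generate_parameterset(synth_config(seed = seed))
    r <- run_cua(ps)$result
    expect_gte(r$delta_qaly, 0)
  }
})

test_that("the null preset produces exactly identical arms", {
  ps <- generate_parameterset(synth_config(seed = 5, preset = "null"))
  expect_identical(ps$transitions$A, ps$transitions$B)
  expect_identical(ps$adherence$A, ps$adherence$B)
  expect_equal(unname(ps$utilities$u["A", ] - ps$utilities$u["B", ]), rep(0, 6))
  r <- run_cua(ps)$result
  expect_identical(r$delta_cost, 0)
  expect_identical(r$delta_qaly, 0)
})

test_that("generated sets hit their trace calibration targets", {
  for (seed in c(1, 4, 9)) {
    ps <- generate_parameterset(synth_config(seed = seed))
    trA <- run_trace(ps, "A"); trB <- run_trace(ps, "B")
    expect_lt(abs(trA$occupancy[6, 1] / 1000 - 0.65), 0.02)
    expect_lt(abs(trB$occupancy[6, 1] / 1000 - 0.65), 0.02)
    expect_equal(trA$occupancy[6, 6], 5.5, tolerance = 0.01)  # stage-5 target
    expect_equal(trA$occupancy[6, 7] / 1000, 0.115, tolerance = 0.001)
  }
})

test_that("generated configurations round-trip through the config format", {
  ps <- generate_parameterset(synth_config(seed = 12))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(ps, f)
  ps2 <- load_parameters(f)
  expect_equal(ps2$transitions, ps$transitions, tolerance = 1e-12)
  expect_equal(ps2$adherence, ps$adherence, tolerance = 1e-12)
  expect_length(validate_parameters(ps2), 0L)
})
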