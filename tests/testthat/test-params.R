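test_that("base-case parameter set carries the published values exactly", {
  ps <- base_case_parameters()
  expect_equal(ps$econ$discount_rate, 0.025)
  expect_equal(ps$econ$cohort_size, 1000)
  expect_equal(ps$econ$horizon_cycles, 5L)
  expect_equal(ps$econ$entry_age, 47.31)

  pd <- vapply(ps$drugs, function(d) d$per_diem, 0)
  names(pd) <- vapply(ps$drugs, `[[`, "", "name")
  expect_equal(unname(pd["STN1013001"]), 0.30)
  expect_equal(unname(pd["latanoprost"]), 0.24)
  expect_equal(ps$resources[["addon_timolol"]]$unit_cost, 0.18)
  expect_equal(ps$resources[["addon_dorzolamide"]]$unit_cost, 0.14)
  expect_equal(ps$resources[["osd_ciclosporin"]]$unit_cost, 3.67)
  expect_equal(ps$resources[["osd_lubricant"]]$unit_cost, 0.27)

  expect_equal(ps$resources[["fu_slit_lamp"]]$unit_cost, 28.29)
  expect_equal(ps$resources[["fu_tonometry"]]$unit_cost, 41.66)
  expect_equal(ps$resources[["fu_visual_field"]]$unit_cost, 39.43)
  expect_equal(ps$resources[["diag_ophthalmologist_visit"]]$unit_cost, 25.32)
  expect_equal(ps$resources[["osd_schirmer"]]$unit_cost, 19.20)
  expect_equal(ps$resources[["diag_gonioscopy"]]$unit_cost, 17.28)
  expect_equal(ps$resources[["diag_oct_rnfl"]]$unit_cost, 56.54)
  expect_equal(ps$resources[["fu_retinal_fiber"]]$unit_cost, 26.78)
  expect_equal(ps$resources[["fu_diurnal_iop"]]$unit_cost, 41.66)

  expect_equal(unname(ps$utilities$u["A", ]),
               c(0.900, 0.897, 0.879, 0.862, 0.825, 0.790))
  expect_equal(unname(ps$utilities$u["B", ]),
               c(0.900, 0.890, 0.866, 0.849, 0.808, 0.790))
  expect_equal(ps$utilities$d_osd, -0.120)
  expect_equal(unname(ps$osd[["A"]]), 0.762)
  expect_equal(unname(ps$osd[["B"]]), 0.837)

  # synthetic completion is flagged as such
  expect_identical(unname(ps$provenance["transitions"]), "synthetic")
  expect_identical(unname(ps$provenance["utility"]), "published")
  expect_length(validate_parameters(ps), 0L)
})

test_that("configuration round-trips through YAML field by field", {
  ps <- base_case_parameters()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(ps, f)
  ps2 <- load_parameters(f)
  expect_equal(ps2$econ, ps$econ, tolerance = 1e-12)
  expect_equal(ps2$transitions, ps$transitions, tolerance = 1e-12)
  expect_equal(ps2$utilities, ps$utilities, tolerance = 1e-12)
  expect_equal(ps2$osd, ps$osd, tolerance = 1e-12)
  expect_equal(ps2$adherence, ps$adherence, tolerance = 1e-12)
  expect_equal(ps2$life_table, ps$life_table, tolerance = 1e-12)
  expect_equal(lapply(ps2$resources, `[`, c("unit_cost", "value", "category")),
               lapply(ps$resources, `[`, c("unit_cost", "value", "category")),
               tolerance = 1e-12)
  expect_equal(length(ps2$uncertainty), length(ps$uncertainty))
  expect_equal(vapply(ps2$uncertainty, `[[`, 0, "mean"),
               vapply(ps$uncertainty, `[[`, 0, "mean"), tolerance = 1e-12)
})

test_that("malformed configurations are rejected with named violations", {
  ps <- base_case_parameters()
  f <- withr::local_tempfile(fileext = ".yaml")

  bad <- ps
  bad$transitions$A[1, 1] <- bad$transitions$A[1, 1] - 0.02  # row sums to 0.98
  rep1 <- validate_parameters(bad)
  expect_true(any(grepl("transitions.A.stage0", rep1, fixed = TRUE)))
  write_parameters(bad, f)
  expect_error(load_parameters(f), "transitions.A.stage0")

  bad <- ps
  bad$resources[["fu_tonometry"]]$unit_cost <- -1
  expect_true(any(grepl("fu_tonometry", validate_parameters(bad))))

  bad <- ps
  bad$utilities$u["B", "stage2"] <- 1.2
  rep3 <- validate_parameters(bad)
  expect_length(rep3, 1L)
  expect_match(rep3, "utilities.u.B.stage2")

  bad <- ps
  bad$adherence$B["stage3", 5] <- NA
  rep4 <- validate_parameters(bad)
  expect_length(rep4, 1L)
  expect_match(rep4, "adherence.B.stage3.year5")

  writeLines("schema_version: '1.0'\nbogus_key: 1", f)
  expect_error(load_parameters(f), "unknown top-level key")
  writeLines("econ: [unbalanced", f)
  expect_error(load_parameters(f), "parse failure")
})

test_that("valid sets produce an empty validation report", {
  expect_length(validate_parameters(base_case_parameters()), 0L)
  expect_length(validate_parameters(generate_parameterset(synth_config(seed = 9))), 0L)
})

test_that("standard errors from coefficients of variation multiply out", {
  expect_equal(se_from_cv(1.18, 0.2), 0.236)
  expect_equal(se_from_cv(10, 0), 0)
  expect_equal(se_from_cv(0, 3), 0)
  expect_error(se_from_cv(-1, 0.1), "non-negative")
})

test_that("per-diem from pack price and duration divides out", {
  expect_equal(per_diem_from_pack(9.00, 30), 0.30)
  expect_equal(per_diem_from_pack(0, 30), 0)
  expect_equal(per_diem_from_pack(7.1352, 29.73), 0.24)
  expect_error(per_diem_from_pack(5, 0), "positive")
})
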