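test_that("tornado entries recover the baseline at degenerate bounds", {
  ps <- base_case_parameters()
  ids <- vapply(ps$uncertainty, `[[`, "", "id")
  k <- which(ids == "utility_A_stage1")
  ps$uncertainty <- ps$uncertainty[k]
  ps$uncertainty[[1]]$lo <- ps$uncertainty[[1]]$mean
  ps$uncertainty[[1]]$hi <- ps$uncertainty[[1]]$mean
  tor <- run_owsa(ps)
  expect_equal(nrow(tor), 1L)
  base <- attr(tor, "baseline")
  if (base$label == "icur") {
    expect_equal(tor$icur_lo, base$icur, tolerance = 1e-9)
    expect_equal(tor$pct_lo, 0, tolerance = 1e-9)
    expect_equal(tor$pct_hi, 0, tolerance = 1e-9)
    expect_equal(tor$width, 0, tolerance = 1e-9)
  } else {
    expect_identical(tor$label_lo, base$label)
  }
})

test_that("tornado ordering matches brute-force recomputation on a toy model", {
  ps <- base_case_parameters()
  # widen the medication cost gap so every bound stays in the NE quadrant and
  # the tornado is a pure ICUR ordering problem
  ps$drugs[[1]]$per_diem <- 0.60
  ids <- vapply(ps$uncertainty, `[[`, "", "id")
  keep <- c("utility_A_stage1", "osd_prob_A",
            "unit_cost_fu_tonometry", "osd_disutility")
  ps$uncertainty <- ps$uncertainty[ids %in% keep]
  tor <- run_owsa(ps)
  expect_true(all(diff(tor$width) <= 1e-12))
  # brute force: recompute each bound ICUR independently of run_owsa
  brute <- sapply(ps$uncertainty, function(us) {
    icur_at <- function(v) {
      ps2 <- glaucua:::set_param(ps, us$target, v)
      f <- run_cua(ps2)$result
      f$delta_cost / f$delta_qaly
    }
    abs(icur_at(us$hi) - icur_at(us$lo))
  })
  ord <- vapply(ps$uncertainty, `[[`, "", "id")[order(-brute)]
  expect_identical(tor$param, ord)
})

test_that("the discount rate enters the one-way analysis with its 0-4.5% range", {
  ps <- base_case_parameters()
  ids <- vapply(ps$uncertainty, `[[`, "", "id")
  k <- which(ids == "discount_rate")
  expect_equal(ps$uncertainty[[k]]$lo, 0)
  expect_equal(ps$uncertainty[[k]]$hi, 0.045)
  expect_true(ps$uncertainty[[k]]$fixed_in_psa)
  tor <- run_owsa(ps)
  expect_true("discount_rate" %in% tor$param)
})

test_that("parameter sampling is seed-deterministic and respects fixed flags", {
  ps <- base_case_parameters()
  set.seed(99); d1 <- sample_parameterset(ps)
  set.seed(99); d2 <- sample_parameterset(ps)
  expect_identical(d1, d2)
  set.seed(100); d3 <- sample_parameterset(ps)
  expect_false(identical(d3$utilities$u, ps$utilities$u))

  set.seed(1)
  for (i in 1:25) {
    d <- sample_parameterset(ps)
    expect_identical(d$drugs, ps$drugs)                      # posology & cost fixed
    expect_identical(d$econ$discount_rate, ps$econ$discount_rate)
    # draws stay on their supports
    expect_true(all(d$utilities$u >= 0 & d$utilities$u <= 1))
    expect_true(d$utilities$d_osd <= 0)
    expect_true(all(vapply(d$resources, function(it) all(it$value >= 0), TRUE)))
    for (a in c("A", "B")) {
      expect_equal(unname(rowSums(d$transitions[[a]])), rep(1, 6), tolerance = 1e-12)
      expect_true(all(d$transitions[[a]][lower.tri(d$transitions[[a]])] == 0))
      expect_true(all(d$adherence[[a]] >= 0 & d$adherence[[a]] <= 1))
    }
  }

  ps_fixed <- ps
  for (i in seq_along(ps_fixed$uncertainty)) ps_fixed$uncertainty[[i]]$fixed_in_psa <- TRUE
  set.seed(5)
  expect_identical(sample_parameterset(ps_fixed), ps_fixed)
})

test_that("a fully fixed PSA collapses to the deterministic result", {
  ps <- toy_psa_parameterset(seed = 6)
  for (i in seq_along(ps$uncertainty)) ps$uncertainty[[i]]$fixed_in_psa <- TRUE
  psa <- run_psa(ps, n_iter = 1L, seed = 3, trace_summaries = FALSE)
  det <- run_cua(ps)$result
  expect_equal(psa$draws$dC, det$delta_cost, tolerance = 1e-9)
  expect_equal(psa$draws$dE, det$delta_qaly, tolerance = 1e-9)
})

test_that("PSA draws are reproducible and centred on the deterministic value", {
  ps <- toy_psa_parameterset(seed = 6)
  p1 <- run_psa(ps, n_iter = 40L, seed = 17, trace_summaries = FALSE)
  p2 <- run_psa(ps, n_iter = 40L, seed = 17, trace_summaries = FALSE)
  expect_identical(p1$draws, p2$draws)

  p3 <- run_psa(ps, n_iter = 400L, seed = 31, trace_summaries = FALSE)
  det <- run_cua(ps)$result
  mcse <- stats::sd(p3$draws$dE) / sqrt(400)
  expect_lt(abs(mean(p3$draws$dE) - det$delta_qaly), 3 * mcse)
})

test_that("quadrant classification partitions the draws", {
  one <- data.frame(dC = -1, dE = 0.2)
  expect_equal(unname(cep_classify(one)), c(0, 1, 0, 0))
  set.seed(8)
  d <- data.frame(dC = rnorm(500), dE = rnorm(500))
  q <- cep_classify(d)
  expect_equal(sum(q), 500)
  expect_message(cep_classify(data.frame(dC = 0, dE = 0)), "boundary")
})

test_that("acceptability curves follow their definition", {
  d <- data.frame(dC = c(10, -5), dE = c(0.001, 0.002),
                  cost_A = c(10, 0), cost_B = c(0, 5),
                  qaly_A = c(1.001, 1.002), qaly_B = c(1, 1))
  cc <- ceac(d, lambda = 1000)
  expect_equal(cc$p_A, 0.5)
  expect_equal(cc$p_B, 0.5)

  dom <- data.frame(dC = -abs(rnorm(100)), dE = abs(rnorm(100)))
  expect_true(all(ceac(dom, lambda = c(0, 1e4, 5e4))$p_A == 1))

  set.seed(12)
  for (i in 1:20) {
    dd <- data.frame(dC = rnorm(200), dE = abs(rnorm(200)) + 1e-6)
    cc <- ceac(dd, lambda = seq(0, 5e4, length.out = 50))
    expect_true(all(diff(cc$p_A) >= -1e-12))              # monotone when dE > 0
    expect_equal(cc$p_A + cc$p_B, rep(1, 50), tolerance = 1e-12)  # complement
  }
})

test_that("the frontier switches arm at the mean cost-effectiveness ratio", {
  set.seed(21)
  n <- 400
  d <- data.frame(dE = rep(0.5, n), dC = 1000 + rnorm(n, sd = 50))
  d$cost_A <- 2000 + d$dC; d$cost_B <- 2000
  d$qaly_A <- 3 + d$dE; d$qaly_B <- 3
  lstar <- mean(d$dC) / mean(d$dE)
  cf <- ceaf(d, lambda = c(0, lstar * 0.999, lstar * 1.001, 5e4))
  expect_identical(cf$optimal_arm, c("B", "B", "A", "A"))
  expect_equal(cf$frontier_p, ifelse(cf$optimal_arm == "A", cf$p_A, cf$p_B))

  # arm A dominant in every draw: frontier is A with probability 1 everywhere
  dom <- data.frame(dC = -(1:50), dE = (1:50) / 100,
                    cost_A = 100 - (1:50), cost_B = 100,
                    qaly_A = 2 + (1:50) / 100, qaly_B = 2)
  cf2 <- ceaf(dom, lambda = c(0, 1e4, 5e4))
  expect_true(all(cf2$optimal_arm == "A"))
  expect_true(all(cf2$frontier_p == 1))

  # at lambda = 0 the cheaper arm is optimal
  expect_identical(ceaf(d, lambda = 0)$optimal_arm, "B")
})
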