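# Probabilistic sensitivity analysis: joint Monte Carlo sampling of all
# uncertain parameters, propagation through the cohort engine, and
# cost-effectiveness plane / acceptability curve / frontier construction.

#' Draw one realised parameter set
#'
#' Replaces every non-fixed parameter by one draw from its method-of-moments
#' distribution: beta for probabilities and utilities, gamma for volumes (and
#' the OSD disutility, sampled on magnitude then negated), normal truncated
#' at 0 by resampling for unit costs, Dirichlet for transition rows
#' (renormalised exactly to the simplex). Parameters flagged
#' \code{fixed_in_psa} (drug posology and cost, discount rate) are left
#' untouched. Draws are taken in parameter order from R's seeded generator,
#' so a given seed reproduces the realised set exactly.
#'
#' @param ps a valid \code{cua_parameters} object.
#' @return a realised \code{cua_parameters} object.
#' @export
sample_parameterset <- function(ps) {
  for (us in ps$uncertainty) {
    if (us$fixed_in_psa || us$dist == "fixed") next
    value <- switch(us$dist,
      beta = {
        ab <- fit_beta(us$mean, us$se)
        stats::rbeta(1L, ab[["alpha"]], ab[["beta"]])
      },
      gamma = {
        m <- abs(us$mean)
        sh <- fit_gamma(m, us$se)
        d <- stats::rgamma(1L, shape = sh[["shape"]], scale = sh[["scale"]])
        if (us$mean < 0) -d else d
      },
      normal = rnorm_pos(us$mean, us$se),
      dirichlet = {
        row <- get_param(ps, us$target)
        rdirichlet_row(fit_dirichlet(row, if (is.na(us$ess)) 100 else us$ess))
      },
      stop("sample_parameterset: unsupported family ", us$dist))
    ps <- set_param(ps, us$target, value)
  }
  ps
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of joint parameter uncertainty: at each iteration
#' a realised parameter set is drawn with [sample_parameterset()] and both
#' arms are run through the cohort engine and accrual, recording per-arm
#' discounted (cost, QALY) pairs and the increments. Per-state occupancy mean
#' and SD across iterations are accumulated as trace summaries. Fully
#' reproducible for a given seed.
#'
#' @param ps a valid \code{cua_parameters} object.
#' @param n_iter number of Monte Carlo iterations (the base analysis uses
#'   10000).
#' @param seed integer seed.
#' @param trace_summaries accumulate occupancy mean/SD across iterations
#'   (default TRUE; disable for speed in tight loops).
#' @return an object of class \code{cua_psa}: draws data.frame (iter, cost_A,
#'   qaly_A, cost_B, qaly_B, dC, dE), seed, lambda grid, and per-arm trace
#'   summary arrays.
#' @export
run_psa <- function(ps, n_iter = 10000L, seed = 1L, trace_summaries = TRUE) {
  bad <- validate_parameters(ps)
  if (length(bad)) stop("run_psa: invalid parameter set")
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("run_psa: n_iter must be >= 1")
  set.seed(seed)
  hc <- ps$econ$half_cycle
  H <- ps$econ$horizon_cycles
  cost <- qaly <- matrix(0, n_iter, 2L, dimnames = list(NULL, ARMS))
  tsum <- tsumsq <- if (trace_summaries)
    lapply(stats::setNames(ARMS, ARMS), function(a) matrix(0, H + 1L, 7L)) else NULL
  for (i in seq_len(n_iter)) {
    psi <- sample_parameterset(ps)
    for (a in ARMS) {
      tr <- run_trace(psi, a)
      led <- accrue(person_time(tr, hc), psi, a)
      tt <- ledger_totals(led)
      cost[i, a] <- tt$cost
      qaly[i, a] <- tt$qaly
      if (trace_summaries) {
        tsum[[a]] <- tsum[[a]] + tr$occupancy
        tsumsq[[a]] <- tsumsq[[a]] + tr$occupancy^2
      }
    }
  }
  draws <- data.frame(iter = seq_len(n_iter),
                      cost_A = cost[, "A"], qaly_A = qaly[, "A"],
                      cost_B = cost[, "B"], qaly_B = qaly[, "B"])
  draws$dC <- draws$cost_A - draws$cost_B
  draws$dE <- draws$qaly_A - draws$qaly_B
  trace_stats <- NULL
  if (trace_summaries) {
    trace_stats <- lapply(stats::setNames(ARMS, ARMS), function(a) {
      m <- tsum[[a]] / n_iter
      v <- tsumsq[[a]] / n_iter - m^2
      v[v < 0] <- 0
      sd <- if (n_iter > 1L) sqrt(v * n_iter / (n_iter - 1L)) else 0 * m
      dimnames(m) <- dimnames(sd) <- list(0:H, cua_stages(TRUE))
      list(mean = m, sd = sd)
    })
  }
  structure(list(draws = draws, n_iter = n_iter, seed = seed,
                 wtp_grid = ps$econ$wtp_grid, trace_stats = trace_stats),
            class = "cua_psa")
}

#' Classify Monte Carlo draws on the cost-effectiveness plane
#'
#' Counts iterations per quadrant of the (deltaE, deltaC) plane: NE (more
#' effective, more costly), SE (more effective, less costly = strong
#' dominance), SW, NW. Boundary draws (exact zeros) are assigned to the
#' positive side and reported via a message.
#'
#' @param draws a \code{cua_psa} object or its draws data.frame.
#' @return named integer vector c(NE, SE, SW, NW) partitioning the draws.
#' @export
cep_classify <- function(draws) {
  d <- if (inherits(draws, "cua_psa")) draws$draws else draws
  nz <- sum(d$dE == 0) + sum(d$dC == 0)
  if (nz > 0) message("cep_classify: ", nz,
                      " boundary draw(s) assigned to the positive side")
  eff <- d$dE >= 0
  costly <- d$dC >= 0
  c(NE = sum(eff & costly), SE = sum(eff & !costly),
    SW = sum(!eff & !costly), NW = sum(!eff & costly))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold lambda, the probability that each
#' arm is cost-effective: for arm A the fraction of iterations with
#' lambda x deltaE - deltaC > 0, for arm B the fraction with the reverse
#' strict inequality.
#'
#' @param draws a \code{cua_psa} object or its draws data.frame.
#' @param lambda threshold grid (default 1000 thresholds over [0, 50000]).
#' @return data.frame with columns lambda, p_A, p_B.
#' @export
ceac <- function(draws, lambda = seq(0, 50000, length.out = 1000)) {
  d <- if (inherits(draws, "cua_psa")) draws$draws else draws
  p_A <- vapply(lambda, function(l) mean(l * d$dE - d$dC > 0), 0)
  p_B <- vapply(lambda, function(l) mean(l * d$dE - d$dC < 0), 0)
  data.frame(lambda = lambda, p_A = p_A, p_B = p_B)
}

#' Cost-effectiveness acceptability frontier
#'
#' At each threshold the optimal arm is the one with the highest expected net
#' monetary benefit lambda x mean(E) - mean(C) (ties broken toward the lower
#' mean cost); the frontier value is that arm's probability of having the
#' highest NMB across iterations.
#'
#' @inheritParams ceac
#' @return data.frame with columns lambda, optimal_arm, frontier_p, p_A, p_B.
#' @export
ceaf <- function(draws, lambda = seq(0, 50000, length.out = 1000)) {
  d <- if (inherits(draws, "cua_psa")) draws$draws else draws
  cc <- ceac(d, lambda)
  mE <- c(A = mean(d$qaly_A), B = mean(d$qaly_B))
  mC <- c(A = mean(d$cost_A), B = mean(d$cost_B))
  opt <- vapply(lambda, function(l) {
    nmb <- l * mE - mC
    if (nmb[["A"]] == nmb[["B"]]) names(which.min(mC)) else names(which.max(nmb))
  }, "")
  cc$optimal_arm <- opt
  cc$frontier_p <- ifelse(opt == "A", cc$p_A, cc$p_B)
  cc
}

#' Probabilistic sensitivity analysis of a fitted base case
#'
#' \code{simulate} on a \code{cua} object runs [run_psa()] on its parameter
#' set.
#'
#' @param object a \code{cua} object from [run_cua()].
#' @param nsim number of Monte Carlo iterations.
#' @param seed integer seed.
#' @param ... passed to [run_psa()].
#' @return a \code{cua_psa} object.
#' @export
simulate.cua <- function(object, nsim = 10000L, seed = 1L, ...) {
  run_psa(object$parameters, n_iter = nsim, seed = seed, ...)
}

#' @export
print.cua_psa <- function(x, ...) {
  d <- x$draws
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations (seed %d)\n",
              x$n_iter, x$seed))
  ciC <- percentile_ci(d$dC); ciE <- percentile_ci(d$dE)
  cat(sprintf("  deltaC mean %.2f (95%% CI %.2f; %.2f)\n", mean(d$dC), ciC[1], ciC[2]))
  cat(sprintf("  deltaE mean %.3f (95%% CI %.3f; %.3f) QALYs\n", mean(d$dE), ciE[1], ciE[2]))
  q <- suppressMessages(cep_classify(d))
  cat("  cost-effectiveness plane: ",
      paste(sprintf("%s %.2f%%", names(q), 100 * q / x$n_iter), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cua_psa <- function(object, wtp = 30000, ...) {
  d <- object$draws
  q <- suppressMessages(cep_classify(d))
  cc <- ceac(d, lambda = wtp)
  out <- list(n_iter = object$n_iter, seed = object$seed,
              mean_dC = mean(d$dC), mean_dE = mean(d$dE),
              ci_dC = percentile_ci(d$dC), ci_dE = percentile_ci(d$dE),
              ci_cost_A = percentile_ci(d$cost_A), ci_cost_B = percentile_ci(d$cost_B),
              ci_qaly_A = percentile_ci(d$qaly_A), ci_qaly_B = percentile_ci(d$qaly_B),
              quadrants = q, p_ce_at_wtp = cc$p_A, wtp = wtp)
  class(out) <- "summary.cua_psa"
  out
}

#' @export
print.summary.cua_psa <- function(x, ...) {
  cat(sprintf("PSA summary (%d iterations)\n", x$n_iter))
  cat(sprintf("  deltaC %.2f (%.2f; %.2f)  deltaE %.3f (%.3f; %.3f)\n",
              x$mean_dC, x$ci_dC[1], x$ci_dC[2], x$mean_dE, x$ci_dE[1], x$ci_dE[2]))
  cat(sprintf("  P(cost-effective at %.0f/QALY) = %.4f\n", x$wtp, x$p_ce_at_wtp))
  cat("  quadrants:", paste(sprintf("%s=%d", names(x$quadrants), x$quadrants),
                            collapse = " "), "\n")
  invisible(x)
}

#' Plot PSA results
#'
#' \code{type = "cep"} draws the cost-effectiveness plane of (deltaE, deltaC)
#' draws; \code{"ceac"} the acceptability curves of both arms; \code{"ceaf"}
#' the acceptability frontier.
#'
#' @param x a \code{cua_psa} object.
#' @param type one of "cep", "ceac", "ceaf".
#' @param lambda threshold grid for the curves.
#' @param ... passed to the underlying base-graphics call.
#' @return \code{x}, invisibly.
#' @export
plot.cua_psa <- function(x, type = c("cep", "ceac", "ceaf"),
                         lambda = x$wtp_grid, ...) {
  type <- match.arg(type)
  d <- x$draws
  if (type == "cep") {
    graphics::plot(d$dE, d$dC, pch = ".", xlab = "Incremental QALYs",
                   ylab = "Incremental cost", main = "Cost-effectiveness plane", ...)
    graphics::abline(h = 0, v = 0, col = "grey60")
  } else if (type == "ceac") {
    cc <- ceac(d, lambda)
    graphics::plot(cc$lambda, cc$p_A, type = "l", ylim = c(0, 1),
                   xlab = "Willingness to pay (per QALY)",
                   ylab = "P(cost-effective)", main = "CEAC", ...)
    graphics::lines(cc$lambda, cc$p_B, lty = 2)
    graphics::legend("right", legend = c("A", "B"), lty = 1:2, bty = "n")
  } else {
    cf <- ceaf(d, lambda)
    graphics::plot(cf$lambda, cf$frontier_p, type = "l", ylim = c(0, 1),
                   xlab = "Willingness to pay (per QALY)",
                   ylab = "P(optimal arm)", main = "CEAF", ...)
  }
  invisible(x)
}
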