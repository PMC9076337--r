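# Report generation: deterministic base-case tables, tornado tables and PSA
# outputs as CSV + JSON files with a run manifest. These functions are the
# package's orchestration layer; inst/cli/glaucua.R is a thin command-line
# wrapper over them.

write_manifest <- function(out_dir, command, files, config_path = NULL,
                           seed = NA_integer_, n_iter = NA_integer_) {
  man <- list(command = command,
              config = config_path,
              config_md5 = if (!is.null(config_path))
                unname(tools::md5sum(config_path)) else NULL,
              seed = seed, n_iter = n_iter, schema_version = "1.0",
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              outputs = files)
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  stopifnot(all(file.exists(file.path(out_dir, files))))
  invisible(path)
}

#' Write the deterministic base-case report
#'
#' Runs the cohort model on both arms and writes the per-arm cohort traces
#' (CSV, one row per cycle, cycle 0 = entry), the per-cycle accrual ledgers,
#' and a JSON summary in the standard cost-utility layout (category costs
#' with shares, overall, life-years, QALYs, increments, ICUR or dominance
#' label).
#'
#' @param ps a valid \code{cua_parameters} object.
#' @param out_dir output directory (created if absent).
#' @param config_path optional path of the source configuration, recorded
#'   (with its hash) in the run manifest.
#' @return the \code{cua} object, invisibly.
#' @export
report_base_case <- function(ps, out_dir, config_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- run_cua(ps)
  files <- character()
  for (a in ARMS) {
    f <- sprintf("trace_%s.csv", a)
    utils::write.csv(as.data.frame(fit$traces[[a]]),
                     file.path(out_dir, f), row.names = FALSE)
    files <- c(files, f)
    led <- fit$ledgers[[a]]
    ldf <- data.frame(cycle = seq_along(led$ly))
    for (cat in COST_CATEGORIES) {
      ldf[[paste0(cat, "_undiscounted")]] <- led$cost[, cat]
      ldf[[paste0(cat, "_discounted")]] <- led$cost_disc[, cat]
    }
    ldf$ly <- led$ly; ldf$ly_discounted <- led$ly_disc
    ldf$qaly <- led$qaly; ldf$qaly_discounted <- led$qaly_disc
    f <- sprintf("ledger_%s.csv", a)
    utils::write.csv(ldf, file.path(out_dir, f), row.names = FALSE)
    files <- c(files, f)
  }
  s <- summary(fit)
  jsonlite::write_json(
    list(table = s$table, icur = s$icur, label = s$label,
         delta_cost = s$delta_cost, delta_qaly = s$delta_qaly,
         delta_ly = s$delta_ly),
    file.path(out_dir, "base_case.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA, na = "null")
  files <- c(files, "base_case.json")
  write_manifest(out_dir, "run", files, config_path)
  invisible(fit)
}

#' Write the one-way sensitivity (tornado) report
#'
#' Full tornado table plus a top-10 summary sorted by bar width.
#'
#' @inheritParams report_base_case
#' @return the \code{cua_owsa} table, invisibly.
#' @export
report_owsa <- function(ps, out_dir, config_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tor <- run_owsa(ps)
  utils::write.csv(as.data.frame(tor), file.path(out_dir, "tornado.csv"),
                   row.names = FALSE)
  utils::write.csv(utils::head(as.data.frame(tor), 10L),
                   file.path(out_dir, "tornado_top10.csv"), row.names = FALSE)
  write_manifest(out_dir, "owsa", c("tornado.csv", "tornado_top10.csv"),
                 config_path)
  invisible(tor)
}

#' Write the probabilistic sensitivity analysis report
#'
#' Writes the draw table (iter, per-arm cost and QALY, increments),
#' cost-effectiveness-plane quadrant counts, acceptability curve and frontier
#' over the willingness-to-pay grid, percentile CIs for the increments and
#' per-arm totals, and the across-iteration occupancy mean/SD tables.
#'
#' @inheritParams report_base_case
#' @param n_iter Monte Carlo iterations.
#' @param seed integer seed.
#' @return the \code{cua_psa} object, invisibly.
#' @export
report_psa <- function(ps, out_dir, n_iter = 10000L, seed = 1L,
                       config_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  psa <- run_psa(ps, n_iter = n_iter, seed = seed)
  utils::write.csv(psa$draws, file.path(out_dir, "psa_draws.csv"),
                   row.names = FALSE)
  cf <- ceaf(psa, ps$econ$wtp_grid)
  utils::write.csv(cf[, c("lambda", "p_A", "p_B", "optimal_arm", "frontier_p")],
                   file.path(out_dir, "ceac_ceaf.csv"), row.names = FALSE)
  files <- c("psa_draws.csv", "ceac_ceaf.csv")
  for (a in ARMS) {
    f <- sprintf("trace_summary_%s.csv", a)
    ts <- psa$trace_stats[[a]]
    df <- data.frame(cycle = as.integer(rownames(ts$mean)))
    for (s in colnames(ts$mean)) {
      df[[paste0(s, "_mean")]] <- ts$mean[, s]
      df[[paste0(s, "_sd")]] <- ts$sd[, s]
    }
    utils::write.csv(df, file.path(out_dir, f), row.names = FALSE)
    files <- c(files, f)
  }
  d <- psa$draws
  q <- suppressMessages(cep_classify(d))
  jsonlite::write_json(
    list(n_iter = psa$n_iter, seed = psa$seed,
         quadrants = as.list(q),
         ci = list(delta_cost = as.list(percentile_ci(d$dC)),
                   delta_qaly = as.list(percentile_ci(d$dE)),
                   cost_A = as.list(percentile_ci(d$cost_A)),
                   cost_B = as.list(percentile_ci(d$cost_B)),
                   qaly_A = as.list(percentile_ci(d$qaly_A)),
                   qaly_B = as.list(percentile_ci(d$qaly_B)))),
    file.path(out_dir, "psa_summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  files <- c(files, "psa_summary.json")
  write_manifest(out_dir, "psa", files, config_path, seed = seed,
                 n_iter = as.integer(n_iter))
  invisible(psa)
}
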