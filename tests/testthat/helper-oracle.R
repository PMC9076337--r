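# Independent oracles and toy fixtures, built in code.

# Exhaustive path-enumeration oracle for the cohort trace: enumerates every
# state sequence over the horizon, weights it by the product of single-cycle
# transition probabilities (built here from first principles, not via the
# package's matrix constructor), and accumulates probability-weighted
# occupancy. Feasible only for short horizons.
enum_trace_oracle <- function(ps, arm) {
  H <- ps$econ$horizon_cycles
  N <- ps$econ$cohort_size
  qs <- vapply(seq_len(H), function(t)
    mortality_q(ps$life_table, ps$econ$female_fraction,
                ps$econ$entry_age + t - 1), 0)
  tr <- ps$transitions[[arm]]
  Ps <- lapply(qs, function(q) {
    P <- matrix(0, 7, 7)
    P[1:6, 1:6] <- (1 - q) * tr
    P[1:6, 7] <- q
    P[7, 7] <- 1
    P
  })
  occ <- matrix(0, H + 1L, 7L)
  occ[1L, 1L] <- N
  for (tt in seq_len(H)) {
    paths <- as.matrix(expand.grid(rep(list(1:7), tt)))
    for (k in seq_len(nrow(paths))) {
      pr <- 1
      s <- 1L
      for (t in seq_len(tt)) {
        s2 <- paths[k, t]
        pr <- pr * Ps[[t]][s, s2]
        if (pr == 0) break
        s <- s2
      }
      occ[tt + 1L, s] <- occ[tt + 1L, s] + N * pr
    }
  }
  occ
}

# Parameter set with flat mortality and identity disease rows (nobody
# progresses), handy for closed-form checks.
static_parameterset <- function(flat_q = 0, horizon = 5L, cohort = 1000) {
  cfg <- synth_config(seed = 42L, cohort_size = cohort)
  ps <- generate_parameterset(cfg)
  ps$econ$horizon_cycles <- as.integer(horizon)  # shorten after generation
  ps$life_table$qx[] <- flat_q
  for (a in c("A", "B")) {
    ps$transitions[[a]] <- diag(6)
    dimnames(ps$transitions[[a]]) <- list(cua_stages(), cua_stages())
  }
  ps
}

# Small well-specified model for PSA coverage runs: few uncertain parameters,
# all centred on their deterministic values with modest dispersion.
toy_psa_parameterset <- function(seed = 1L) {
  ps <- generate_parameterset(synth_config(seed = seed))
  keep <- c("utility_A_stage0", "utility_B_stage0", "utility_A_stage1",
            "utility_B_stage1", "osd_prob_A", "osd_prob_B", "osd_disutility",
            "volume_fu_tonometry_A_stage0", "volume_fu_tonometry_B_stage0")
  ids <- vapply(ps$uncertainty, `[[`, "", "id")
  ps$uncertainty <- ps$uncertainty[ids %in% keep]
  ps
}
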