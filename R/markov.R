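# Cohort state-transition engine: annual cycles over 6 living stages plus an
# absorbing death state, age/sex all-cause mortality applied first and disease
# progression conditional on surviving the cycle.

#' Sex-mixed, age-interpolated annual death probability
#'
#' Looks up the annual all-cause death probability at a (possibly fractional)
#' age, interpolating linearly between adjacent integer ages within each sex
#' and mixing sexes by the cohort's female fraction.
#'
#' @param life_table data.frame with columns sex ("f"/"m"), age, qx.
#' @param female_fraction fraction of the cohort that is female.
#' @param age age in years; must lie within the table's age range.
#' @return a death probability in [0, 1].
#' @export
mortality_q <- function(life_table, female_fraction, age) {
  amin <- min(life_table$age); amax <- max(life_table$age)
  if (age < amin || age > amax)
    stop(sprintf("mortality_q: age %.2f outside life table range [%d, %d]",
                 age, amin, amax))
  one_sex <- function(s) {
    sub <- life_table[life_table$sex == s, ]
    sub <- sub[order(sub$age), ]
    stats::approx(sub$age, sub$qx, xout = age, method = "linear")$y
  }
  qf <- one_sex("f"); qm <- one_sex("m")
  female_fraction * qf + (1 - female_fraction) * qm
}

# Vectorised internal version: one table split, all cycle ages at once.
mortality_q_vec <- function(life_table, female_fraction, ages) {
  if (min(ages) < min(life_table$age) || max(ages) > max(life_table$age))
    stop("mortality_q_vec: age outside life table range")
  f <- life_table$sex == "f"
  of <- order(life_table$age[f]); om <- order(life_table$age[!f])
  qf <- stats::approx(life_table$age[f][of], life_table$qx[f][of], xout = ages)$y
  qm <- stats::approx(life_table$age[!f][om], life_table$qx[!f][om], xout = ages)$y
  female_fraction * qf + (1 - female_fraction) * qm
}

#' Full-cycle transition matrix over stages and death
#'
#' Combines elicited disease-transition rows (conditional on survival) with an
#' annual death probability q as competing risks: mortality strikes first,
#' disease progression applies to survivors. For each living stage s,
#' P(s -> death) = q and P(s -> s') = (1 - q) x t[s, s']; death is absorbing.
#' Rows remain stochastic for any q and backward flow stays structurally zero.
#'
#' @param trans 6 x 6 upper-triangular row-stochastic disease transition
#'   matrix.
#' @param q annual death probability in [0, 1].
#' @return a 7 x 7 row-stochastic matrix (states = stages 0-5, death).
#' @export
build_cycle_matrix <- function(trans, q) {
  if (q < 0 || q > 1) stop("build_cycle_matrix: q outside [0,1]")
  rs <- rowSums(trans)
  if (any(abs(rs - 1) > 1e-9))
    stop("build_cycle_matrix: disease transition rows must sum to 1")
  P <- matrix(0, 7L, 7L, dimnames = list(cua_stages(TRUE), cua_stages(TRUE)))
  P[1:6, 1:6] <- (1 - q) * trans
  P[1:6, 7L] <- q
  P[7L, 7L] <- 1
  P
}

#' Advance the cohort one cycle
#'
#' @param occupancy length-7 state occupancy vector (persons).
#' @param P 7 x 7 row-stochastic cycle matrix.
#' @return the next occupancy vector; total persons are conserved.
#' @export
step_cohort <- function(occupancy, P) {
  if (length(occupancy) != 7L || !all(dim(P) == c(7L, 7L)))
    stop("step_cohort: need a length-7 vector and 7x7 matrix")
  out <- as.numeric(occupancy %*% P)
  if (abs(sum(out) - sum(occupancy)) > 1e-9 * max(1, sum(occupancy)))
    stop("step_cohort: persons not conserved")
  names(out) <- colnames(P)
  out
}

#' Run the cohort trace for one arm
#'
#' Places the whole cohort in stage 0 at entry and applies the cycle matrix
#' for each annual cycle, advancing age by one year per cycle from the
#' (fractional) entry age and interpolating the mortality table at each age.
#'
#' @param ps a valid \code{cua_parameters} object.
#' @param arm "A" or "B".
#' @return an object of class \code{cohort_trace}: occupancy matrix
#'   (cycles 0..H x 7 states), new deaths per cycle, and the per-cycle death
#'   probabilities used.
#' @export
run_trace <- function(ps, arm = c("A", "B")) {
  arm <- match.arg(arm)
  e <- ps$econ
  H <- e$horizon_cycles
  states <- cua_stages(TRUE)
  occ <- matrix(0, H + 1L, 7L, dimnames = list(0:H, states))
  occ[1L, 1L] <- e$cohort_size
  tr <- ps$transitions[[arm]]
  qs <- mortality_q_vec(ps$life_table, e$female_fraction,
                        e$entry_age + seq_len(H) - 1)
  v <- occ[1L, ]
  for (t in seq_len(H)) {
    v <- step_cohort(v, build_cycle_matrix(tr, qs[t]))
    occ[t + 1L, ] <- v
  }
  structure(list(occupancy = occ, new_deaths = diff(occ[, 7L]), qs = qs,
                 arm = arm, cohort_size = e$cohort_size), class = "cohort_trace")
}

#' Person-time weights per cycle and stage
#'
#' Attributes person-years to the stage occupied at cycle start. Patients who
#' survive the cycle contribute a full year; with the half-cycle correction on,
#' patients who die within the cycle contribute half a year in their starting
#' stage (and nothing once dead); with it off, decedents contribute nothing.
#'
#' @param trace a \code{cohort_trace}.
#' @param half_cycle logical; apply the half-cycle correction for decedents.
#' @return matrix w (cycles 1..H x stages 0-5) of person-years.
#' @export
person_time <- function(trace, half_cycle = TRUE) {
  H <- length(trace$qs)
  w <- matrix(0, H, 6L, dimnames = list(seq_len(H), cua_stages()))
  for (t in seq_len(H)) {
    start <- trace$occupancy[t, 1:6]
    q <- trace$qs[t]
    frac <- if (half_cycle) 1 - 0.5 * q else 1 - q
    w[t, ] <- start * frac
  }
  w
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("Cohort trace, arm %s: %g patients, %d cycles\n",
              x$arm, x$cohort_size, length(x$qs)))
  print(round(x$occupancy, 1))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  df <- as.data.frame(x$occupancy)
  df <- cbind(cycle = as.integer(rownames(x$occupancy)), df)
  df$new_deaths <- c(0, x$new_deaths)
  rownames(df) <- NULL
  df
}
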