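# Accrual of discounted costs, life-years and QALYs from person-time, and the
# incremental cost-utility comparison.

#' Discount factor for a cycle
#'
#' Present-value factor (1+r)^-(t-1+offset) for cycle t (1-based). With the
#' default offset 0 the first year's flows are undiscounted; offset 1
#' discounts from the first cycle onward.
#'
#' @param r annual discount rate (> -1).
#' @param t cycle index, 1-based (vectorised).
#' @param offset exponent shift (0 or 1).
#' @return discount factor(s).
#' @export
discount_factor <- function(r, t, offset = 0L) {
  if (any(r <= -1)) stop("discount_factor: rate must exceed -1")
  (1 + r)^(-(t - 1 + offset))
}

#' Annual monotherapy drug cost
#'
#' Per-diem cost times days of therapy per year, scaled by the probability of
#' being treatment-adherent in that stage and year.
#'
#' @param per_diem drug cost per day.
#' @param adherence adherence probability in [0, 1].
#' @param therapy_days days of therapy per year (default 365.25).
#' @return expected annual drug cost per person.
#' @export
annual_medication_cost <- function(per_diem, adherence, therapy_days = 365.25) {
  if (any(per_diem < 0) || any(therapy_days < 0)) stop("annual_medication_cost: negative input")
  if (any(adherence < 0 | adherence > 1)) stop("annual_medication_cost: adherence outside [0,1]")
  per_diem * therapy_days * adherence
}

#' Annual per-person resource cost by category and stage
#'
#' For each recurring (non-one-time) resource item, annual cost is unit cost
#' x annual volume (tests, visits) or unit cost x probability x days of
#' therapy (prescription-probability drug items). Returns the category x stage
#' cost table for one arm.
#'
#' @param items list of [resource_item()]s.
#' @param arm "A" or "B".
#' @return 4 x 6 matrix (categories x stages) of annual per-person costs.
#' @export
stage_annual_cost <- function(items, arm) {
  out <- matrix(0, length(COST_CATEGORIES), 6L,
                dimnames = list(COST_CATEGORIES, STAGES))
  for (it in items) {
    if (it$one_time) next
    ann <- it$unit_cost * it$value[arm, ] * (it$days_per_year %||% 1)
    out[it$category, ] <- out[it$category, ] + ann
  }
  out
}

one_time_cost <- function(items, arm, stage = "stage0") {
  tot <- stats::setNames(numeric(length(COST_CATEGORIES)), COST_CATEGORIES)
  for (it in items) {
    if (!it$one_time) next
    tot[it$category] <- tot[it$category] +
      it$unit_cost * it$value[arm, stage] * (it$days_per_year %||% 1)
  }
  tot
}

#' Stage utility net of expected ocular-surface-disease disutility
#'
#' The stage utility is reduced by the expected OSD decrement
#' p_osd x d_osd (an arm-level annual OSD probability times a common
#' disutility), floored at 0.
#'
#' @param u stage utility in [0, 1].
#' @param p_osd annual probability of OSD in the arm.
#' @param d_osd non-positive OSD disutility.
#' @return effective utility in [0, 1].
#' @export
effective_utility <- function(u, p_osd, d_osd) {
  pmax(0, u + p_osd * d_osd)
}

#' Accrue discounted costs, life-years and QALYs for one arm
#'
#' Converts person-time weights into per-cycle, per-person streams: life-years
#' as person-years / cohort size; QALYs weighted by effective stage utility;
#' medication cost from the arm's monotherapy per-diem, therapy days and the
#' stage/year adherence table; recurring resource costs from
#' [stage_annual_cost()]; one-time diagnosis items added at cycle 1,
#' undiscounted. Every stream is stored undiscounted and discounted.
#'
#' @param weights person-time matrix from [person_time()] (cycles x stages).
#' @param ps a valid \code{cua_parameters} object.
#' @param arm "A" or "B".
#' @return an object of class \code{accrual_ledger}.
#' @export
accrue <- function(weights, ps, arm = c("A", "B")) {
  arm <- match.arg(arm)
  e <- ps$econ
  H <- nrow(weights)
  N <- e$cohort_size
  dfs <- discount_factor(e$discount_rate, seq_len(H), e$discount_offset)

  u_eff <- effective_utility(ps$utilities$u[arm, ], ps$osd[[arm]],
                             ps$utilities$d_osd)
  drug <- ps$drugs[[which(vapply(ps$drugs, `[[`, "", "name") == ps$medication[[arm]])]]
  pd <- drug_per_diem(drug)
  tdays <- drug$therapy_days_per_year %||% 365.25
  csm <- stage_annual_cost(ps$resources, arm)  # categories x stages

  ncat <- length(COST_CATEGORIES)
  cost <- matrix(0, H, ncat, dimnames = list(NULL, COST_CATEGORIES))
  ly <- qaly <- numeric(H)
  adh <- ps$adherence[[arm]]
  for (t in seq_len(H)) {
    w <- weights[t, ]
    ly[t] <- sum(w) / N
    qaly[t] <- sum(w * u_eff) / N
    med <- annual_medication_cost(pd, adh[, t], tdays)
    cost[t, "medication"] <- sum(w * med) / N
    for (cat in COST_CATEGORIES)
      cost[t, cat] <- cost[t, cat] + sum(w * csm[cat, ]) / N
  }
  cost_disc <- cost * dfs
  entry <- one_time_cost(ps$resources, arm)
  cost[1L, ] <- cost[1L, ] + entry
  cost_disc[1L, ] <- cost_disc[1L, ] + entry  # one-time items undiscounted

  structure(list(arm = arm,
                 cost = cost, cost_disc = cost_disc,
                 ly = ly, ly_disc = ly * dfs,
                 qaly = qaly, qaly_disc = qaly * dfs,
                 discount_factors = dfs),
            class = "accrual_ledger")
}

ledger_totals <- function(led, discounted = TRUE) {
  if (discounted)
    list(cost_by_cat = colSums(led$cost_disc), cost = sum(led$cost_disc),
         ly = sum(led$ly_disc), qaly = sum(led$qaly_disc))
  else
    list(cost_by_cat = colSums(led$cost), cost = sum(led$cost),
         ly = sum(led$ly), qaly = sum(led$qaly))
}

# Shared labelling of the (deltaC, deltaE) pair: a ratio only when one is
# meaningful, dominance labels otherwise.
cua_label <- function(dC, dE) {
  if (dE == 0 && dC == 0) list(label = "equivalent", icur = NA_real_)
  else if (dE == 0) list(label = if (dC < 0) "strongly-dominant" else "dominated",
                         icur = NA_real_)
  else if (dC < 0 && dE > 0) list(label = "strongly-dominant", icur = NA_real_)
  else if (dC > 0 && dE < 0) list(label = "dominated", icur = NA_real_)
  else list(label = "icur", icur = dC / dE)
}

#' Incremental cost-utility comparison of two arms
#'
#' Computes per-arm discounted totals, increments (arm A minus arm B), the
#' incremental cost-utility ratio ICUR = deltaC / deltaE when both increments
#' share a sign, dominance labels otherwise, and incremental net monetary
#' benefit lambda x deltaE - deltaC on the willingness-to-pay grid.
#'
#' @param ledger_A,ledger_B [accrue()] ledgers for arms A and B.
#' @param wtp_grid willingness-to-pay thresholds (currency/QALY).
#' @return an object of class \code{cua_result}.
#' @export
cua_compare <- function(ledger_A, ledger_B, wtp_grid = seq(0, 50000, length.out = 1000)) {
  ta <- ledger_totals(ledger_A); tb <- ledger_totals(ledger_B)
  dC <- ta$cost - tb$cost
  dE <- ta$qaly - tb$qaly
  dLY <- ta$ly - tb$ly
  lab <- cua_label(dC, dE)
  label <- lab$label; icur <- lab$icur
  structure(list(totals = list(A = ta, B = tb),
                 delta_cost = dC, delta_qaly = dE, delta_ly = dLY,
                 icur = icur, label = label,
                 nmb = wtp_grid * dE - dC, wtp_grid = wtp_grid),
            class = "cua_result")
}

#' Percentage cost shares by category
#'
#' @param cost_by_cat named vector of category cost totals.
#' @return percentages of the overall cost, summing to 100.
#' @export
category_shares <- function(cost_by_cat) {
  tot <- sum(cost_by_cat)
  if (tot <= 0) stop("category_shares: overall cost must be positive")
  100 * cost_by_cat / tot
}

#' Run the base-case cohort cost-utility analysis
#'
#' The model's central entry point: simulates both arms' cohort traces,
#' converts them to half-cycle-corrected person-time, accrues discounted
#' costs, life-years and QALYs, and compares the arms. The returned object
#' has \code{print}, \code{summary}, \code{plot} and \code{simulate} (=
#' probabilistic sensitivity analysis) methods.
#'
#' @param ps a valid \code{cua_parameters} object (see
#'   [base_case_parameters()] and [generate_parameterset()]).
#' @return an object of class \code{cua} bundling the parameter set, traces,
#'   ledgers and the \code{cua_result}.
#' @export
run_cua <- function(ps) {
  bad <- validate_parameters(ps)
  if (length(bad))
    stop("run_cua: invalid parameter set:\n  ", paste(bad, collapse = "\n  "))
  hc <- ps$econ$half_cycle
  traces <- lapply(stats::setNames(ARMS, ARMS), function(a) run_trace(ps, a))
  ledgers <- lapply(stats::setNames(ARMS, ARMS), function(a)
    accrue(person_time(traces[[a]], hc), ps, a))
  res <- cua_compare(ledgers$A, ledgers$B, ps$econ$wtp_grid)
  structure(list(parameters = ps, traces = traces, ledgers = ledgers,
                 result = res), class = "cua")
}

# Fast path used inside PSA iterations: returns only (cost, qaly, ly) per arm.
run_arms_totals <- function(ps) {
  hc <- ps$econ$half_cycle
  out <- matrix(0, 2L, 3L, dimnames = list(ARMS, c("cost", "qaly", "ly")))
  for (a in ARMS) {
    led <- accrue(person_time(run_trace(ps, a), hc), ps, a)
    tt <- ledger_totals(led)
    out[a, ] <- c(tt$cost, tt$qaly, tt$ly)
  }
  out
}
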