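#' @keywords internal
"_PACKAGE"

# Ordered living disease stages; the absorbing death state is appended by the
# engine as state 7.
STAGES <- c("stage0", "stage1", "stage2", "stage3", "stage4", "stage5")
DEATH <- "death"
ARMS <- c("A", "B")
COST_CATEGORIES <- c("diagnosis", "medication", "addon_followup", "osd_management")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stage labels of the disease model
#'
#' The model describes progressive open-angle glaucoma / ocular hypertension
#' (OAG/OHT) as six ordered living stages -- ocular hypertension (stage 0),
#' early (1), moderate (2), advanced (3), severe (4) and end-stage/blind
#' (5) -- plus an absorbing death state. Backward transitions are structurally
#' impossible.
#'
#' @param include_death logical; append the absorbing state label.
#' @return character vector of state labels.
#' @export
cua_stages <- function(include_death = FALSE) {
  if (include_death) c(STAGES, DEATH) else STAGES
}

#' Economic settings for a cohort run
#'
#' @param discount_rate annual real discount rate applied to costs, life-years
#'   and QALYs (fraction; default 0.025).
#' @param horizon_cycles number of annual cycles simulated (default 5).
#' @param cycle_length_days days per cycle (default 365.25, leap years
#'   averaged in).
#' @param cohort_size notional patients per arm (default 1000).
#' @param entry_age cohort entry age in years (default 47.31).
#' @param female_fraction fraction of the cohort that is female (default 0.5).
#' @param half_cycle logical; give within-cycle decedents half a cycle of
#'   costs and outcomes (default TRUE).
#' @param wtp_grid strictly increasing non-negative willingness-to-pay
#'   thresholds (currency per QALY) for net-monetary-benefit reporting;
#'   default 1000 thresholds over [0, 50000].
#' @param currency_year currency year tag (default "EUR2020").
#' @param discount_offset exponent of the discount factor in cycle 1: 0 means
#'   first-year flows are undiscounted (default), 1 discounts from the first
#'   cycle onward.
#' @return a list of validated economic settings.
#' @export
econ_settings <- function(discount_rate = 0.025, horizon_cycles = 5L,
                          cycle_length_days = 365.25, cohort_size = 1000,
                          entry_age = 47.31, female_fraction = 0.5,
                          half_cycle = TRUE,
                          wtp_grid = seq(0, 50000, length.out = 1000),
                          currency_year = "EUR2020", discount_offset = 0L) {
  list(discount_rate = discount_rate, horizon_cycles = as.integer(horizon_cycles),
       cycle_length_days = cycle_length_days, cohort_size = cohort_size,
       entry_age = entry_age, female_fraction = female_fraction,
       half_cycle = isTRUE(half_cycle), wtp_grid = as.numeric(wtp_grid),
       currency_year = currency_year, discount_offset = as.integer(discount_offset))
}

#' Standard error from a coefficient of variation
#'
#' When a parameter's elicited data carry no dispersion, its standard error is
#' imposed as SE = CV x mean.
#'
#' @param mean non-negative point estimate.
#' @param cv non-negative coefficient of variation (fraction).
#' @return the implied standard error.
#' @export
se_from_cv <- function(mean, cv) {
  if (any(mean < 0) || any(cv < 0)) stop("se_from_cv: mean and cv must be non-negative")
  cv * mean
}

#' Define a resource-use item
#'
#' Items carry a unit cost and an arm x stage table of expected annual volumes
#' (tests, visits) or annual probabilities (drug prescriptions). Items in the
#' diagnosis category default to one-time accrual at cohort entry. Drug items
#' set \code{days_per_year} so that annual cost = probability x per-diem x
#' days of therapy.
#'
#' @param name item label.
#' @param category one of diagnosis, medication, addon_followup,
#'   osd_management.
#' @param unit_cost unit cost (currency); a per-diem for drug items.
#' @param value 2 x 6 matrix (arms x stages) of annual volumes or
#'   probabilities; a single number is recycled.
#' @param type "volume" or "probability".
#' @param one_time accrue once at entry (cycle 1) instead of annually.
#' @param days_per_year for drug items, days of therapy per year the per-diem
#'   applies to; NULL for tariff-valued procedures.
#' @return a resource item list.
#' @export
resource_item <- function(name, category, unit_cost, value,
                          type = c("volume", "probability"),
                          one_time = identical(category, "diagnosis"),
                          days_per_year = NULL) {
  type <- match.arg(type)
  if (!is.matrix(value)) value <- matrix(value, nrow = 2, ncol = 6,
                                         dimnames = list(ARMS, STAGES))
  dimnames(value) <- list(ARMS, STAGES)
  list(name = name, category = category, unit_cost = unit_cost, value = value,
       type = type, one_time = isTRUE(one_time), days_per_year = days_per_year)
}

#' Declare the uncertainty of one model parameter
#'
#' Each non-fixed parameter carries a point estimate, a standard error (or one
#' derived from a coefficient of variation via [se_from_cv()]), a distribution
#' family consistent with its support, and optionally 95% CI / range bounds
#' used by the one-way sensitivity analysis.
#'
#' @param id unique parameter identifier (used in tornado output).
#' @param target list locating the parameter in the set; \code{target$kind} is
#'   one of utility, d_osd, p_osd, unit_cost, resource_value, adherence,
#'   transition_row, female_fraction, discount_rate.
#' @param dist distribution family: beta, gamma, normal, dirichlet or fixed.
#' @param mean,se first two moments (se ignored for dirichlet/fixed).
#' @param lo,hi bounds for one-way sensitivity analysis (NA to exclude).
#' @param fixed_in_psa exclude from probabilistic draws even if a
#'   distribution is attached.
#' @param ess Dirichlet effective sample size (rows only).
#' @return an uncertainty specification list.
#' @export
uncertainty_spec <- function(id, target, dist, mean = NA_real_, se = NA_real_,
                             lo = NA_real_, hi = NA_real_,
                             fixed_in_psa = identical(dist, "fixed"),
                             ess = NA_real_) {
  dist <- match.arg(dist, c("beta", "gamma", "normal", "dirichlet", "fixed"))
  list(id = id, target = target, dist = dist, mean = mean, se = se,
       lo = lo, hi = hi, fixed_in_psa = isTRUE(fixed_in_psa), ess = ess)
}

#' Assemble a complete model parameter set
#'
#' Bundles every input the cohort model needs for both arms: stage-transition
#' rows, life table, utilities and OSD disutility, arm-level OSD
#' probabilities, drug prices, resource-use items, adherence tables,
#' uncertainty specifications and economic settings.
#'
#' @param econ output of [econ_settings()].
#' @param transitions list with elements A and B, each a 6 x 6 row-stochastic
#'   upper-triangular matrix of annual stage transitions conditional on
#'   surviving the cycle.
#' @param life_table data.frame with columns sex ("f"/"m"), age (contiguous
#'   integers) and qx (annual all-cause death probability).
#' @param utilities list with u (2 x 6 arm x stage matrix in [0,1]) and d_osd
#'   (non-positive OSD disutility).
#' @param osd named vector of annual OSD probabilities per arm.
#' @param drugs list of drug price entries (name, per_diem or pack_price +
#'   pack_duration_days, therapy_days_per_year).
#' @param medication named character mapping each arm to its monotherapy drug.
#' @param resources list of [resource_item()]s.
#' @param adherence list per arm of 6 x horizon (stage x year) adherence
#'   probability matrices.
#' @param uncertainty list of [uncertainty_spec()]s.
#' @param arm_names display names for arms A and B.
#' @param provenance named character marking top-level fields "published" or
#'   "synthetic".
#' @return an object of class \code{cua_parameters}.
#' @export
parameter_set <- function(econ, transitions, life_table, utilities, osd,
                          drugs, medication, resources, adherence,
                          uncertainty = list(),
                          arm_names = c(A = "intervention", B = "comparator"),
                          provenance = character()) {
  names(resources) <- vapply(resources, `[[`, "", "name")
  for (arm in intersect(ARMS, names(transitions)))
    dimnames(transitions[[arm]]) <- list(STAGES, STAGES)
  for (arm in intersect(ARMS, names(adherence)))
    rownames(adherence[[arm]]) <- STAGES
  ps <- structure(list(schema_version = "1.0", econ = econ,
                       transitions = transitions, life_table = life_table,
                       utilities = utilities, osd = osd, drugs = drugs,
                       medication = medication, resources = resources,
                       adherence = adherence, uncertainty = uncertainty,
                       arm_names = arm_names, provenance = provenance),
                  class = "cua_parameters")
  ps
}

#' Per-diem drug cost from pack price and duration
#'
#' One pack of a topical therapy covers a mean number of treatment days
#' (e.g. 30 days for unit-dose containers, 29.73 days averaging multidose
#' bottles discarded after 28 days); the per-diem is the pack price divided by
#' that duration.
#'
#' @param pack_price pack price (currency).
#' @param pack_duration_days mean days of treatment per pack (> 0).
#' @return cost per day of therapy.
#' @export
per_diem_from_pack <- function(pack_price, pack_duration_days) {
  if (any(pack_duration_days <= 0)) stop("per_diem_from_pack: duration must be positive")
  pack_price / pack_duration_days
}

drug_per_diem <- function(drug) {
  if (!is.null(drug$per_diem)) return(drug$per_diem)
  per_diem_from_pack(drug$pack_price, drug$pack_duration_days)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs: transition rows on
#' the simplex and upper-triangular, probabilities in [0,1], utilities in
#' [0,1] with non-positive OSD disutility, non-negative costs and volumes,
#' contiguous life table covering the simulated ages for both sexes, complete
#' adherence tables, and a strictly increasing willingness-to-pay grid.
#'
#' @param ps a \code{cua_parameters} object.
#' @return character vector of violation messages; empty if the set is valid.
#' @export
validate_parameters <- function(ps) {
  bad <- character()
  note <- function(...) bad[[length(bad) + 1L]] <<- sprintf(...)
  e <- ps$econ
  if (e$discount_rate < 0) note("econ.discount_rate: negative (%g)", e$discount_rate)
  if (e$horizon_cycles < 1) note("econ.horizon_cycles: < 1")
  if (e$cohort_size < 1) note("econ.cohort_size: < 1")
  if (e$female_fraction < 0 || e$female_fraction > 1) note("econ.female_fraction: outside [0,1]")
  if (any(e$wtp_grid < 0) || any(diff(e$wtp_grid) <= 0))
    note("econ.wtp_grid: must be non-negative and strictly increasing")

  for (arm in ARMS) {
    tr <- ps$transitions[[arm]]
    if (is.null(tr) || !is.matrix(tr) || !all(dim(tr) == c(6L, 6L))) {
      note("transitions.%s: missing or not 6x6", arm); next
    }
    if (any(tr < 0 | tr > 1)) note("transitions.%s: entries outside [0,1]", arm)
    if (any(tr[lower.tri(tr)] != 0))
      note("transitions.%s: backward (less-severe) transition present", arm)
    rs <- rowSums(tr)
    off <- which(abs(rs - 1) > 1e-9)
    for (i in off) note("transitions.%s.%s: row sums to %.10g, not 1", arm, STAGES[i], rs[i])
  }

  lt <- ps$life_table
  if (!all(c("sex", "age", "qx") %in% names(lt))) {
    note("life_table: needs columns sex, age, qx")
  } else {
    if (any(lt$qx < 0 | lt$qx > 1)) note("life_table.qx: outside [0,1]")
    for (s in c("f", "m")) {
      ages <- sort(lt$age[lt$sex == s])
      if (!length(ages)) note("life_table: sex '%s' absent", s)
      else if (any(diff(ages) != 1)) note("life_table: ages not contiguous for sex '%s'", s)
    }
    amin <- min(lt$age); amax <- max(lt$age)
    if (e$entry_age < amin || e$entry_age + e$horizon_cycles > amax)
      note("life_table: does not cover ages %.2f..%.2f", e$entry_age,
           e$entry_age + e$horizon_cycles)
  }

  u <- ps$utilities$u
  if (!is.matrix(u) || !all(dim(u) == c(2L, 6L))) note("utilities.u: not a 2x6 arm x stage matrix")
  else {
    idx <- which(u < 0 | u > 1, arr.ind = TRUE)
    for (k in seq_len(nrow(idx)))
      note("utilities.u.%s.%s: %g outside [0,1]", ARMS[idx[k, 1]], STAGES[idx[k, 2]],
           u[idx[k, 1], idx[k, 2]])
  }
  if (ps$utilities$d_osd > 0) note("utilities.d_osd: positive disutility (%g)", ps$utilities$d_osd)
  for (arm in ARMS) {
    p <- ps$osd[[arm]]
    if (is.null(p) || is.na(p) || p < 0 || p > 1) note("osd.%s: outside [0,1]", arm)
  }

  for (d in ps$drugs) {
    pd <- tryCatch(drug_per_diem(d), error = function(e) -1)
    if (pd < 0) note("drugs.%s: invalid per-diem / pack definition", d$name)
    if ((d$therapy_days_per_year %||% 365.25) <= 0) note("drugs.%s: therapy days <= 0", d$name)
  }
  for (arm in ARMS)
    if (!(ps$medication[[arm]] %in% vapply(ps$drugs, `[[`, "", "name")))
      note("medication.%s: drug '%s' not defined", arm, ps$medication[[arm]])

  for (it in ps$resources) {
    if (!it$category %in% COST_CATEGORIES)
      note("resources.%s: unknown category '%s'", it$name, it$category)
    if (it$unit_cost < 0) note("resources.%s: negative unit cost", it$name)
    if (any(it$value < 0)) note("resources.%s: negative volume/probability", it$name)
    if (it$type == "probability" && any(it$value > 1))
      note("resources.%s: probability above 1", it$name)
  }

  H <- e$horizon_cycles
  for (arm in ARMS) {
    a <- ps$adherence[[arm]]
    if (is.null(a) || !is.matrix(a) || nrow(a) != 6L || ncol(a) < H) {
      note("adherence.%s: missing entries (need 6 stages x %d years)", arm, H); next
    }
    if (anyNA(a[, seq_len(H)])) {
      idx <- which(is.na(a[, seq_len(H)]), arr.ind = TRUE)
      for (k in seq_len(nrow(idx)))
        note("adherence.%s.%s.year%d: missing", arm, STAGES[idx[k, 1]], idx[k, 2])
    }
    if (any(a < 0 | a > 1, na.rm = TRUE)) note("adherence.%s: outside [0,1]", arm)
  }

  seen <- character()
  for (us in ps$uncertainty) {
    if (us$id %in% seen) note("uncertainty.%s: duplicated id", us$id)
    seen <- c(seen, us$id)
    if (!is.na(us$se) && us$se < 0) note("uncertainty.%s: negative SE", us$id)
    if (us$dist == "beta" && !is.na(us$mean) && (us$mean <= 0 || us$mean >= 1))
      note("uncertainty.%s: beta mean outside (0,1)", us$id)
    if (us$dist == "gamma" && !is.na(us$mean) && us$mean < 0 &&
        !identical(us$target$kind, "d_osd"))  # disutility: gamma on magnitude
      note("uncertainty.%s: gamma mean negative", us$id)
    if (us$dist == "fixed" && !us$fixed_in_psa)
      note("uncertainty.%s: fixed family must be fixed_in_psa", us$id)
  }
  bad
}

#' @export
print.cua_parameters <- function(x, ...) {
  e <- x$econ
  cat("Cohort cost-utility parameter set (schema", x$schema_version, ")\n")
  cat(sprintf("  arms: A=%s, B=%s\n", x$arm_names[["A"]], x$arm_names[["B"]]))
  cat(sprintf("  cohort: %g patients/arm, entry age %.2f, %d annual cycles\n",
              e$cohort_size, e$entry_age, e$horizon_cycles))
  cat(sprintf("  discount %.2f%%/yr, half-cycle correction %s\n",
              100 * e$discount_rate, if (e$half_cycle) "on" else "off"))
  cat(sprintf("  %d resource items, %d uncertain parameters\n",
              length(x$resources), length(x$uncertainty)))
  bad <- validate_parameters(x)
  if (length(bad)) cat("  INVALID:", length(bad), "violations (see validate_parameters)\n")
  invisible(x)
}

## ---- config (YAML) serialization ------------------------------------------

mat_to_rows <- function(m) {
  rn <- rownames(m) %||% as.character(seq_len(nrow(m)))
  stats::setNames(lapply(seq_len(nrow(m)), function(i) unname(m[i, ])), rn)
}

rows_to_mat <- function(lst, ncol, colnames = NULL) {
  m <- do.call(rbind, lapply(lst, function(r) as.numeric(r)))
  rownames(m) <- names(lst)
  if (!is.null(colnames)) colnames(m) <- colnames
  m
}

KNOWN_TOP_KEYS <- c("schema_version", "econ", "transitions", "life_table",
                    "utility", "osd_prob", "drugs", "medication", "resources",
                    "adherence", "uncertainty", "arm_names", "provenance")

#' Write a parameter set to a YAML configuration file
#'
#' The configuration is a single human-editable document with explicit units
#' in key names (\code{cost_eur}, \code{prob}, \code{rate}); it round-trips
#' through [load_parameters()] to an identical set.
#'
#' @param ps a valid \code{cua_parameters} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(ps, path) {
  cfg <- list(
    schema_version = ps$schema_version,
    econ = list(discount_rate = ps$econ$discount_rate,
                horizon_cycles = ps$econ$horizon_cycles,
                cycle_length_days = ps$econ$cycle_length_days,
                cohort_size = ps$econ$cohort_size,
                entry_age_years = ps$econ$entry_age,
                female_fraction = ps$econ$female_fraction,
                half_cycle = ps$econ$half_cycle,
                wtp_grid_eur_per_qaly = as.numeric(ps$econ$wtp_grid),
                currency_year = ps$econ$currency_year,
                discount_offset = ps$econ$discount_offset),
    arm_names = as.list(ps$arm_names),
    transitions = lapply(ps$transitions, mat_to_rows),
    life_table = list(sex = ps$life_table$sex, age = ps$life_table$age,
                      qx = ps$life_table$qx),
    utility = list(u = mat_to_rows(ps$utilities$u), d_osd = ps$utilities$d_osd),
    osd_prob = as.list(ps$osd),
    drugs = lapply(ps$drugs, function(d) d[!vapply(d, is.null, TRUE)]),
    medication = as.list(ps$medication),
    resources = lapply(ps$resources, function(it) {
      out <- list(name = it$name, category = it$category,
                  unit_cost_eur = it$unit_cost, type = it$type,
                  one_time = it$one_time, value = mat_to_rows(it$value))
      if (!is.null(it$days_per_year)) out$days_per_year <- it$days_per_year
      out
    }),
    adherence = lapply(ps$adherence, mat_to_rows),
    uncertainty = lapply(ps$uncertainty, function(us) {
      us$target <- us$target[!vapply(us$target, is.null, TRUE)]
      us[!vapply(us, function(z) is.null(z) || (length(z) == 1 && is.na(z)), TRUE) |
           names(us) %in% c("id", "target", "dist")]
    }),
    provenance = as.list(ps$provenance))
  writeLines(yaml::as.yaml(cfg, precision = 15L), path)
  invisible(path)
}

#' Load and validate a parameter configuration
#'
#' Reads a YAML configuration written by [write_parameters()] (or by hand),
#' rejects unknown top-level keys, rebuilds the \code{cua_parameters} object
#' and runs [validate_parameters()].
#'
#' @param path configuration file path.
#' @return a validated \code{cua_parameters} object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("load_parameters: file not found: ", path)
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("load_parameters: YAML parse failure in '", path, "': ",
         conditionMessage(e), call. = FALSE))
  unknown <- setdiff(names(cfg), KNOWN_TOP_KEYS)
  if (length(unknown))
    stop("load_parameters: unknown top-level key(s): ", paste(unknown, collapse = ", "))
  ec <- cfg$econ
  econ <- econ_settings(discount_rate = ec$discount_rate,
                        horizon_cycles = ec$horizon_cycles,
                        cycle_length_days = ec$cycle_length_days,
                        cohort_size = ec$cohort_size,
                        entry_age = ec$entry_age_years,
                        female_fraction = ec$female_fraction,
                        half_cycle = ec$half_cycle,
                        wtp_grid = ec$wtp_grid_eur_per_qaly,
                        currency_year = ec$currency_year,
                        discount_offset = ec$discount_offset)
  ps <- parameter_set(
    econ = econ,
    transitions = lapply(cfg$transitions, rows_to_mat, ncol = 6L, colnames = STAGES),
    life_table = data.frame(sex = cfg$life_table$sex, age = cfg$life_table$age,
                            qx = cfg$life_table$qx),
    utilities = list(u = rows_to_mat(cfg$utility$u, 6L, STAGES),
                     d_osd = cfg$utility$d_osd),
    osd = unlist(cfg$osd_prob),
    drugs = lapply(cfg$drugs, function(d) {
      d$therapy_days_per_year <- d$therapy_days_per_year %||% 365.25; d
    }),
    medication = unlist(cfg$medication),
    resources = lapply(cfg$resources, function(it)
      resource_item(it$name, it$category, it$unit_cost_eur,
                    rows_to_mat(it$value, 6L, STAGES), type = it$type,
                    one_time = it$one_time, days_per_year = it$days_per_year)),
    adherence = lapply(cfg$adherence, rows_to_mat, ncol = NULL, colnames = NULL),
    uncertainty = lapply(cfg$uncertainty, function(us)
      uncertainty_spec(us$id, us$target, us$dist,
                       mean = us$mean %||% NA_real_, se = us$se %||% NA_real_,
                       lo = us$lo %||% NA_real_, hi = us$hi %||% NA_real_,
                       fixed_in_psa = us$fixed_in_psa %||% identical(us$dist, "fixed"),
                       ess = us$ess %||% NA_real_)),
    arm_names = unlist(cfg$arm_names),
    provenance = unlist(cfg$provenance) %||% character())
  ps$schema_version <- cfg$schema_version %||% "1.0"
  bad <- validate_parameters(ps)
  if (length(bad))
    stop("load_parameters: invalid configuration:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  ps
}

## ---- parameter addressing (shared by OWSA and PSA) -------------------------

get_param <- function(ps, target) {
  switch(target$kind,
    utility = ps$utilities$u[target$arm, target$stage],
    d_osd = ps$utilities$d_osd,
    p_osd = ps$osd[[target$arm]],
    unit_cost = {
      it <- ps$resources[[target$item]]
      it$unit_cost
    },
    resource_value = ps$resources[[target$item]]$value[target$arm, target$stage],
    adherence = ps$adherence[[target$arm]][target$stage, target$year],
    transition_row = ps$transitions[[target$arm]][target$stage, ],
    female_fraction = ps$econ$female_fraction,
    discount_rate = ps$econ$discount_rate,
    stop("unknown parameter kind: ", target$kind))
}

set_param <- function(ps, target, value) {
  switch(target$kind,
    utility = ps$utilities$u[target$arm, target$stage] <- value,
    d_osd = ps$utilities$d_osd <- value,
    p_osd = ps$osd[[target$arm]] <- value,
    unit_cost = ps$resources[[target$item]]$unit_cost <- value,
    resource_value = ps$resources[[target$item]]$value[target$arm, target$stage] <- value,
    adherence = ps$adherence[[target$arm]][target$stage, target$year] <- value,
    transition_row = ps$transitions[[target$arm]][target$stage, ] <- value,
    female_fraction = ps$econ$female_fraction <- value,
    discount_rate = ps$econ$discount_rate <- value,
    stop("unknown parameter kind: ", target$kind))
  ps
}
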