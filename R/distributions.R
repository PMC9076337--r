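# Method-of-moments distribution fitting for probabilistic sensitivity
# analysis: beta for dichotomous probabilities and utilities, gamma for
# resource volumes and the OSD disutility magnitude, Dirichlet for transition
# rows, normal (truncated at 0 by resampling) for unit costs.

#' Fit a beta distribution by the method of moments
#'
#' Solves for (alpha, beta) such that the beta distribution reproduces the
#' given mean and standard error: nu = mean(1-mean)/se^2 - 1, alpha = mean nu,
#' beta = (1-mean) nu. An infeasible se (se^2 >= mean(1-mean)) is clamped to
#' 99% of the feasibility bound with a warning.
#'
#' @param mean mean in (0, 1).
#' @param se standard error (> 0).
#' @return named vector c(alpha, beta).
#' @export
fit_beta <- function(mean, se) {
  mean <- unname(mean); se <- unname(se)
  if (mean <= 0 || mean >= 1) stop("fit_beta: mean must lie in (0,1)")
  if (se <= 0) stop("fit_beta: se must be positive")
  bound <- mean * (1 - mean)
  if (se^2 >= bound) {
    warning(sprintf("fit_beta: se %g infeasible for mean %g; clamped", se, mean))
    se <- sqrt(0.99 * bound)
  }
  nu <- bound / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Fit a gamma distribution by the method of moments
#'
#' shape = (mean/se)^2, scale = se^2/mean; the fitted distribution reproduces
#' both moments exactly.
#'
#' @param mean mean (> 0).
#' @param se standard error (> 0).
#' @return named vector c(shape, scale).
#' @export
fit_gamma <- function(mean, se) {
  mean <- unname(mean); se <- unname(se)
  if (mean <= 0 || se <= 0) stop("fit_gamma: mean and se must be positive")
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Dirichlet concentration for a transition row
#'
#' Scales the probability row by an effective sample size: alpha_i = p_i x
#' ess. Structurally impossible (zero-probability) cells get alpha = 0 and are
#' never sampled positive.
#'
#' @param prob_row probability vector summing to 1.
#' @param ess effective sample size (> 0).
#' @return concentration vector with sum(alpha) = ess.
#' @export
fit_dirichlet <- function(prob_row, ess) {
  if (abs(sum(prob_row) - 1) > 1e-9) stop("fit_dirichlet: row must sum to 1")
  if (any(prob_row < 0)) stop("fit_dirichlet: negative probabilities")
  if (ess <= 0) stop("fit_dirichlet: ess must be positive")
  prob_row * ess
}

#' Draw from a Dirichlet distribution
#'
#' Gamma-ratio construction; cells with alpha = 0 stay exactly 0 and the draw
#' is renormalised to the simplex.
#'
#' @param alpha concentration vector (non-negative, at least one positive).
#' @return one probability vector.
#' @export
rdirichlet_row <- function(alpha) {
  g <- numeric(length(alpha))
  pos <- alpha > 0
  if (!any(pos)) stop("rdirichlet_row: all-zero concentration")
  g[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  if (sum(g) == 0) { g[which.max(alpha)] <- 1 }  # numeric underflow guard
  g / sum(g)
}

# Normal draw truncated at 0 by resampling (preserves shape above 0, no point
# mass at the boundary).
rnorm_pos <- function(mean, sd) {
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= 0) return(x)
  }
}

#' Percentile-method confidence interval
#'
#' Empirical interval from Monte Carlo draws using linearly interpolated order
#' statistics (the standard sample-quantile definition).
#'
#' @param draws numeric vector of at least 2 draws.
#' @param level confidence level (default 0.95).
#' @return named vector c(low, high).
#' @export
percentile_ci <- function(draws, level = 0.95) {
  if (length(draws) < 2L) stop("percentile_ci: need at least 2 draws")
  a <- (1 - level) / 2
  q <- stats::quantile(draws, c(a, 1 - a), names = FALSE, type = 7)
  c(low = q[1L], high = q[2L])
}
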