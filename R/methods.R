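# Methods for the fitted base-case object.

#' @export
print.cua <- function(x, ...) {
  r <- x$result
  nm <- x$parameters$arm_names
  cat("Cohort cost-utility analysis (discounted, per patient)\n")
  tab <- summary(x)$table
  print(tab, digits = 6)
  cat("\n")
  if (r$label == "icur")
    cat(sprintf("ICUR (deltaC/deltaQALY): %.2f per QALY gained\n", r$icur))
  else
    cat(sprintf("Dominance: arm A (%s) is %s\n", nm[["A"]], r$label))
  invisible(x)
}

#' Summarise a fitted base case
#'
#' @param object a \code{cua} object.
#' @param ... unused.
#' @return a \code{summary.cua} list whose \code{table} element mirrors the
#'   standard cost-utility reporting layout: per-arm category costs with
#'   percentage shares, overall cost, life-years and QALYs, and increments.
#' @export
summary.cua <- function(object, ...) {
  r <- object$result
  ta <- r$totals$A; tb <- r$totals$B
  sha <- category_shares(ta$cost_by_cat); shb <- category_shares(tb$cost_by_cat)
  tab <- data.frame(
    item = c(COST_CATEGORIES, "overall_cost", "lys", "qalys"),
    A = c(round(ta$cost_by_cat, 2), round(ta$cost, 2), round(ta$ly, 3), round(ta$qaly, 3)),
    A_share = c(round(sha, 2), 100, NA, NA),
    B = c(round(tb$cost_by_cat, 2), round(tb$cost, 2), round(tb$ly, 3), round(tb$qaly, 3)),
    B_share = c(round(shb, 2), 100, NA, NA),
    difference = c(round(ta$cost_by_cat - tb$cost_by_cat, 2),
                   round(r$delta_cost, 2), round(r$delta_ly, 3),
                   round(r$delta_qaly, 3)))
  rownames(tab) <- NULL
  out <- list(table = tab, icur = r$icur, label = r$label,
              delta_cost = r$delta_cost, delta_qaly = r$delta_qaly,
              delta_ly = r$delta_ly)
  class(out) <- "summary.cua"
  out
}

#' @export
print.summary.cua <- function(x, ...) {
  print(x$table, digits = 6)
  if (x$label == "icur") cat(sprintf("ICUR: %.2f per QALY\n", x$icur))
  else cat("Label:", x$label, "\n")
  invisible(x)
}

#' Plot the fitted cohort traces
#'
#' Stage occupancy over cycles for both arms (stages 0-5 and cumulative
#' deaths), one panel per arm.
#'
#' @param x a \code{cua} object.
#' @param ... passed to \code{matplot}.
#' @return \code{x}, invisibly.
#' @export
plot.cua <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  for (a in ARMS) {
    occ <- x$traces[[a]]$occupancy
    graphics::matplot(as.integer(rownames(occ)), occ, type = "l", lty = 1,
                      col = seq_len(ncol(occ)), xlab = "Cycle",
                      ylab = "Patients",
                      main = sprintf("Arm %s (%s)", a, x$parameters$arm_names[[a]]),
                      ...)
    graphics::legend("right", legend = colnames(occ), col = seq_len(ncol(occ)),
                     lty = 1, cex = 0.6, bty = "n")
  }
  invisible(x)
}
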