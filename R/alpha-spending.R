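#' O'Brien-Fleming type alpha-spending function
#'
#' Cumulative one-sided level spent by information fraction `t_star` under the
#' approximate O'Brien-Fleming spending function
#' \deqn{\alpha^{OBF}(t^*) = 2\left(1 - \Phi\!\big(\Phi^{-1}(1-\alpha_i/2)/\sqrt{t^*}\big)\right),}
#' which spends very little early and nearly the full level at the end.
#'
#' @param t_star Information fraction in \[0, 1\].
#' @param alpha_i Nominal one-sided level for the hypothesis, in (0, 1).
#' @return Cumulative spent level; 0 at `t_star = 0` (by continuity) and
#'   `alpha_i` at `t_star = 1`.
#' @export
spend_obf <- function(t_star, alpha_i) {
  check_spend_args(t_star, alpha_i)
  ifelse(t_star == 0, 0,
         2 * (1 - stats::pnorm(stats::qnorm(1 - alpha_i / 2) / sqrt(t_star))))
}

#' Pocock type alpha-spending function
#'
#' Cumulative one-sided level spent by information fraction `t_star` under the
#' approximate Pocock spending function
#' \deqn{\alpha^{PO}(t^*) = \alpha_i \log(1 + (e-1)t^*),}
#' which spends the level roughly evenly over the information scale.
#'
#' @inheritParams spend_obf
#' @return Cumulative spent level.
#' @export
spend_pocock <- function(t_star, alpha_i) {
  check_spend_args(t_star, alpha_i)
  alpha_i * log(1 + (exp(1) - 1) * t_star)
}

check_spend_args <- function(t_star, alpha_i) {
  if (any(t_star < 0 | t_star > 1)) stop("'t_star' must be in [0, 1]")
  if (any(alpha_i <= 0 | alpha_i >= 1)) stop("'alpha_i' must be in (0, 1)")
  invisible(NULL)
}

#' Spending-function object
#'
#' @param type `"OBF"` (O'Brien-Fleming type) or `"PO"` (Pocock type).
#' @return A list with the `type` and the spending `evaluator`
#'   `function(t_star, alpha_i)`.
#' @export
spending_function <- function(type = c("OBF", "PO")) {
  type <- match.arg(toupper(type), c("OBF", "PO"))
  structure(list(type = type,
                 evaluator = if (type == "OBF") spend_obf else spend_pocock),
            class = "spending_function")
}

as_spending <- function(spending) {
  if (inherits(spending, "spending_function")) spending
  else spending_function(spending)
}

## P(Z1 < z1, Z2 >= z2) for standard bivariate normal with correlation rho.
## Miwa's algorithm: deterministic, absolute error well below 1e-9 in 2-d.
pnorm2_lower_upper <- function(z1, z2, rho) {
  mvtnorm::pmvnorm(lower = c(-Inf, z2), upper = c(z1, Inf),
                   corr = matrix(c(1, rho, rho, 1), 2),
                   algorithm = mvtnorm::Miwa(steps = 4097))[1]
}

## Solve for the stage-2 one-sided p-value threshold a2 such that
## P(p1 > spend1, p <= a2) = total - spend1 under corr(Z1, Zfinal) = sqrt(t1).
solve_stage2 <- function(spend1, total, t1) {
  if (total <= spend1)
    stop("no level left for stage 2: spend at interim (", signif(spend1, 4),
         ") is not below the total level (", signif(total, 4), ")")
  target <- total - spend1
  z1 <- stats::qnorm(1 - spend1)
  rho <- sqrt(t1)
  f <- function(a2) pnorm2_lower_upper(z1, stats::qnorm(1 - a2), rho) - target
  stats::uniroot(f, lower = 1e-12, upper = total, tol = 1e-12,
                 f.lower = -target)$root
}

#' Two-stage group-sequential boundaries on the one-sided p-value scale
#'
#' Computes the interim (`a1`) and final (`a2`) one-sided nominal p-value
#' thresholds of a two-stage design at overall one-sided level
#' `nominal_alpha`. The interim threshold is the spending-function value at
#' the first-stage information fraction, `a1 = spend(t1, nominal_alpha)`; the
#' final threshold solves
#' \deqn{P(p^{(1)} \le a_1) + P(p^{(1)} > a_1,\; p \le a_2) = \alpha_i}
#' under the bivariate standard normal for the interim and
#' pooled-data final z-statistics with correlation \eqn{\sqrt{t_1}}
#' (proportional per-stage allocation). The design exhausts `nominal_alpha`
#' exactly; a non-binding futility bound, if any, is ignored in the
#' computation.
#'
#' @param nominal_alpha Overall one-sided level of the hypothesis, in (0, 1).
#' @param t1 First-stage information fraction, in (0, 1). Default 0.5.
#' @param spending A [spending_function()] or one of `"OBF"`, `"PO"`.
#' @param futility Optional non-binding one-sided futility bound on the
#'   interim p-value (stored for use by the scheduler, not used in the
#'   boundary computation).
#' @return An object of class `"two_stage_plan"` with elements
#'   `nominal_alpha`, `t1`, `a1`, `a2`, `spending`, `futility`,
#'   `correlation`.
#' @examples
#' two_stage_boundaries(0.05 / 3, 0.5, "PO")    # a1 = 0.0103, a2 = 0.0089
#' two_stage_boundaries(0.05 / 3, 0.5, "OBF")   # a1 = 0.0007, a2 = 0.0164
#' @export
two_stage_boundaries <- function(nominal_alpha, t1 = 0.5, spending = "OBF",
                                 futility = NULL) {
  if (nominal_alpha <= 0 || nominal_alpha >= 1)
    stop("'nominal_alpha' must be in (0, 1)")
  if (t1 <= 0 || t1 >= 1) stop("'t1' must be in (0, 1)")
  spending <- as_spending(spending)
  key <- sprintf("%s|%.15g|%.15g", spending$type, nominal_alpha, t1)
  cached <- .boundary_cache[[key]]
  if (!is.null(cached)) {
    cached$futility <- futility
    return(cached)
  }
  a1 <- spending$evaluator(t1, nominal_alpha)
  plan <- structure(list(nominal_alpha = nominal_alpha, t1 = t1, a1 = a1,
                         a2 = solve_stage2(a1, nominal_alpha, t1),
                         spending = spending$type, futility = futility,
                         correlation = sqrt(t1)),
                    class = "two_stage_plan")
  .boundary_cache[[key]] <- plan
  plan
}

.boundary_cache <- new.env(parent = emptyenv())

#' Final boundary exhausting an increased nominal level (gsLOND.II)
#'
#' When the LOND nominal level of a hypothesis rises between its interim and
#' final analysis (because other hypotheses were rejected in between), the
#' interim was already tested at the lower threshold `a1_spent` and that spend
#' cannot be revisited. gsLOND.II therefore allocates the full increment
#' `nominal_final - a1_spent` to the final analysis: the returned threshold
#' `a2` solves \eqn{P(p^{(1)} > a_1^{spent},\; p \le a_2) =
#' \alpha_i^{(2)} - a_1^{spent}} under correlation \eqn{\sqrt{t_1}}, so the
#' two-stage design exhausts `nominal_final` exactly. The resulting design no
#' longer follows the original spending function.
#'
#' @param nominal_final Updated overall one-sided level at the final analysis.
#' @param a1_spent Interim one-sided threshold actually used (the level
#'   already spent).
#' @param t1 First-stage information fraction.
#' @return The final one-sided nominal p-value threshold.
#' @examples
#' # toy example: interim tested at 0.0103 (level 0.0167), level then doubled
#' exhaust_increment_boundary(2 * 0.05 / 3, spend_pocock(0.5, 0.05 / 3), 0.5)
#' @export
exhaust_increment_boundary <- function(nominal_final, a1_spent, t1 = 0.5) {
  if (t1 <= 0 || t1 >= 1) stop("'t1' must be in (0, 1)")
  if (nominal_final <= a1_spent)
    stop("infeasible increment: 'nominal_final' must exceed 'a1_spent'")
  key <- sprintf("INC|%.15g|%.15g|%.15g", nominal_final, a1_spent, t1)
  cached <- .boundary_cache[[key]]
  if (!is.null(cached)) return(cached)
  out <- solve_stage2(a1_spent, nominal_final, t1)
  .boundary_cache[[key]] <- out
  out
}

#' @export
print.two_stage_plan <- function(x, ...) {
  cat(sprintf(
    "Two-stage plan (%s spending): level %.4g, t1 = %.3g, a1 = %.4f, a2 = %.4f\n",
    x$spending, x$nominal_alpha, x$t1, x$a1, x$a2))
  if (!is.null(x$futility))
    cat(sprintf("  non-binding futility bound: p1 >= %.3g stops the arm\n",
                x$futility))
  invisible(x)
}

#' Boundary table for a list of nominal levels
#'
#' Tabulates interim and final thresholds for each nominal level and both
#' spending types, as used to derive the group-sequential levels of LOND-type
#' procedures.
#'
#' @param alphas Vector of nominal one-sided levels.
#' @param spending Character vector of spending types to include.
#' @param t1 First-stage information fraction.
#' @return A data frame with columns `nominal_alpha`, `spending`, `t1`,
#'   `a1`, `a2`.
#' @export
boundary_table <- function(alphas, spending = c("PO", "OBF"), t1 = 0.5) {
  rows <- expand.grid(nominal_alpha = alphas, spending = spending,
                      stringsAsFactors = FALSE)
  plans <- Map(function(a, s) two_stage_boundaries(a, t1, s),
               rows$nominal_alpha, rows$spending)
  data.frame(nominal_alpha = rows$nominal_alpha, spending = rows$spending,
             t1 = t1,
             a1 = vapply(plans, `[[`, numeric(1), "a1"),
             a2 = vapply(plans, `[[`, numeric(1), "a2"))
}
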