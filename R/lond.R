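#' LOND nominal significance level
#'
#' The LOND procedure (significance Levels based On Number of Discoveries)
#' assigns hypothesis `i` the nominal level
#' \eqn{\alpha_i = \beta_i (R + 1)} where `R` is the number of rejections
#' among the previously decided hypotheses. Each rejection inflates the
#' levels of all later hypotheses, which is what keeps the procedure's FDR at
#' \eqn{\alpha} while the denominator of the FDR grows.
#'
#' @param beta_i Budget of hypothesis `i` (non-negative).
#' @param n_rejections Number of rejections among previous hypotheses
#'   (non-negative integer).
#' @return The nominal one-sided level \eqn{\beta_i (R + 1)}.
#' @seealso [lond_level_updated()] for the positive-dependence variant,
#'   [lond()] for running the procedure on a p-value stream.
#' @export
lond_level <- function(beta_i, n_rejections) {
  check_lond_args(beta_i, n_rejections)
  beta_i * (n_rejections + 1)
}

#' Updated-LOND nominal significance level
#'
#' The updated LOND variant uses \eqn{\alpha_i = \beta_i \max(R, 1)}; it is
#' the variant for which online FDR control is proven under positive
#' dependence (PRDS) of the p-values. It never exceeds the standard LOND
#' level and coincides with it once at least one rejection has occurred.
#'
#' @inheritParams lond_level
#' @return The nominal one-sided level \eqn{\beta_i \max(R, 1)}.
#' @export
lond_level_updated <- function(beta_i, n_rejections) {
  check_lond_args(beta_i, n_rejections)
  beta_i * pmax(n_rejections, 1)
}

check_lond_args <- function(beta_i, n_rejections) {
  if (any(beta_i < 0)) stop("'beta_i' must be non-negative")
  if (any(n_rejections < 0) || any(n_rejections != floor(n_rejections)))
    stop("'n_rejections' must be a non-negative integer")
  invisible(NULL)
}

#' Run fixed-sample-size LOND on an ordered p-value stream
#'
#' Processes one-sided p-values strictly in the predefined hypothesis order
#' (in a platform trial, the order of entry). The level for hypothesis `i`
#' depends only on the decisions for hypotheses `1..i-1`; a p-value equal to
#' its level counts as a rejection.
#'
#' @param pvalues Numeric vector of one-sided p-values in (0, 1\], in
#'   hypothesis order.
#' @param seq A [beta_sequence()] object.
#' @param variant `"standard"` (\eqn{\beta_i(R+1)}) or `"updated"`
#'   (\eqn{\beta_i\max(R,1)}, proven under positive dependence).
#' @return A data frame of class `"lond_decisions"` with one row per
#'   hypothesis: `index`, `beta`, `n_rejections` (before the decision),
#'   `level`, `p_value`, `rejected`.
#' @examples
#' lond(c(0.001, 0.5, 0.5), equal_sequence(0.05, 3))
#' @export
lond <- function(pvalues, seq, variant = c("standard", "updated")) {
  variant <- match.arg(variant)
  stopifnot(inherits(seq, "beta_sequence"))
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must be in (0, 1]")
  n <- length(pvalues)
  beta <- beta_values(seq, seq_len(max(n, 1))[seq_len(n)])
  level_fun <- if (variant == "standard") lond_level else lond_level_updated
  rej <- logical(n)
  level <- numeric(n)
  nrej <- integer(n)
  r <- 0L
  for (i in seq_len(n)) {
    nrej[i] <- r
    level[i] <- level_fun(beta[i], r)
    rej[i] <- pvalues[i] <= level[i]
    if (rej[i]) r <- r + 1L
  }
  structure(data.frame(index = seq_len(n), beta = beta, n_rejections = nrej,
                       level = level, p_value = pvalues, rejected = rej),
            class = c("lond_decisions", "data.frame"),
            variant = variant, alpha = seq$alpha)
}
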