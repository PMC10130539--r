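#' Descending budget sequence for the LOND procedure
#'
#' Evaluates the decreasing series that distributes the overall one-sided FDR
#' level \eqn{\alpha} across an unbounded stream of hypotheses,
#' \deqn{\beta_j = C\,\alpha\,\frac{\log(\max(j,2))}{j\,\exp(\sqrt{\log j})},}
#' the form proposed by Javanmard and Montanari for online FDR procedures.
#' With the conventional constant `C = 0.07720838` the first elements at
#' `alpha = 0.025` are 0.00134, 0.00029, 0.00025.
#'
#' `log` is the natural logarithm. The conventional constant is slightly
#' smaller than the exact normalizer of the series (see [lond_constant()]),
#' so the sequence sums to a bit less than `alpha`; this is conservative.
#'
#' @param j Hypothesis index (vector of positive integers).
#' @param alpha Overall one-sided FDR level, in (0, 1).
#' @param C Normalizing constant; default is the conventional published value.
#' @return Numeric vector of budgets \eqn{\beta_j}.
#' @seealso [beta_sequence()], [lond_constant()]
#' @examples
#' round(beta_descending(1:3, alpha = 0.025), 5)
#' @export
beta_descending <- function(j, alpha, C = 0.07720838) {
  if (any(j < 1) || any(j != floor(j))) stop("'j' must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (C <= 0) stop("'C' must be positive")
  C * alpha * log(pmax(j, 2)) / (j * exp(sqrt(log(j))))
}

#' Exact normalizing constant of the descending budget series
#'
#' Recomputes the constant `C` such that the descending series sums exactly to
#' `alpha` over the infinite hypothesis stream. The series converges very
#' slowly (the partial sum to one million terms covers barely half of the
#' total), so a plain truncated sum is useless; instead the partial sum to
#' `n_terms` is completed with the analytic tail
#' \deqn{\sum_{j>J} \frac{\log j}{j e^{\sqrt{\log j}}}
#'   \approx \int_{J+1/2}^\infty \frac{\log x}{x\,e^{\sqrt{\log x}}}\,dx
#'   = 2\,\Gamma(4, \sqrt{\log(J+1/2)}),}
#' an upper incomplete gamma function (midpoint rule; the integrand is smooth
#' and slowly varying there, so the correction error is far below the last
#' retained digit).
#'
#' The result, 0.0790820, differs from the conventional published constant
#' 0.07720838 by about 2.4%: the published value under-normalizes the series,
#' so budgets built with it sum to about 0.976 of `alpha`.
#'
#' @param n_terms Number of terms summed explicitly before the analytic tail.
#' @param tail If `FALSE`, return the plain truncated-sum normalizer
#'   (of interest only to illustrate the slow convergence).
#' @return The normalizing constant (scalar).
#' @export
lond_constant <- function(n_terms = 1e6, tail = TRUE) {
  j <- seq_len(n_terms)
  s <- sum(log(pmax(j, 2)) / (j * exp(sqrt(log(j)))))
  if (tail) {
    s <- s + 2 * gamma(4) * stats::pgamma(sqrt(log(n_terms + 0.5)), shape = 4,
                                          lower.tail = FALSE)
  }
  1 / s
}

#' Budget sequences for LOND-type online FDR procedures
#'
#' Constructs the sequence of non-negative budgets \eqn{\beta_i} with
#' \eqn{\sum_i \beta_i \le \alpha} that a LOND-type procedure spends on the
#' hypothesis stream.
#'
#' Four kinds are supported:
#' \describe{
#'   \item{`descending`}{the unbounded decreasing series of
#'     [beta_descending()].}
#'   \item{`descending_truncated`}{the same series rescaled on `1..N` so that
#'     \eqn{\sum_{i=1}^N \beta_i = \alpha} exactly (an a-priori upper bound
#'     `N` on the number of hypotheses), with \eqn{\beta_i = 0} beyond `N`.
#'     At `alpha = 0.025`, `N = 1000` this gives 0.00446, 0.00097, 0.00083
#'     for the first three budgets.}
#'   \item{`equal`}{\eqn{\beta_i = \alpha/N} on `1..N`, zero beyond.}
#'   \item{`dependent_adjusted`}{a base sequence (truncated-descending if `N`
#'     is given, otherwise descending) divided by the harmonic number
#'     \eqn{H_i = \sum_{j\le i} 1/j}, the Benjamini-Yekutieli-type correction
#'     under which LOND controls the FDR for arbitrarily dependent p-values.}
#' }
#'
#' @param alpha Overall one-sided FDR level, in (0, 1).
#' @param kind One of `"descending"`, `"descending_truncated"`, `"equal"`,
#'   `"dependent_adjusted"`.
#' @param N Upper bound on the number of hypotheses; required for the
#'   truncated and equal kinds, optional for `dependent_adjusted`.
#' @param C Normalizing constant of the descending series.
#' @return An object of class `"beta_sequence"`; use [beta_values()] to
#'   evaluate it and `as.data.frame()` to export the first `N` (or a chosen
#'   number of) budgets.
#' @examples
#' s <- beta_sequence(0.025, "descending_truncated", N = 1000)
#' round(beta_values(s, 1:3), 5)
#' @export
beta_sequence <- function(alpha,
                          kind = c("descending", "descending_truncated",
                                   "equal", "dependent_adjusted"),
                          N = NULL, C = 0.07720838) {
  kind <- match.arg(kind)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (kind %in% c("descending_truncated", "equal")) {
    if (is.null(N)) stop("'N' is required for kind = ", kind)
  }
  if (!is.null(N) && (length(N) != 1 || N < 1 || N != floor(N)))
    stop("'N' must be a positive integer")
  scale <- 1
  if (kind == "descending_truncated") {
    scale <- alpha / sum(beta_descending(seq_len(N), alpha, C))
  }
  structure(list(alpha = alpha, kind = kind, N = N, C = C, scale = scale),
            class = "beta_sequence")
}

#' Evaluate a budget sequence
#'
#' @param seq A [beta_sequence()] object.
#' @param i Hypothesis indices (positive integers).
#' @return Numeric vector of budgets \eqn{\beta_i}.
#' @export
beta_values <- function(seq, i) {
  stopifnot(inherits(seq, "beta_sequence"))
  if (any(i < 1) || any(i != floor(i))) stop("'i' must be a positive integer")
  out <- switch(seq$kind,
    descending = beta_descending(i, seq$alpha, seq$C),
    descending_truncated = beta_descending(i, seq$alpha, seq$C) * seq$scale,
    equal = rep(seq$alpha / seq$N, length(i)),
    dependent_adjusted = {
      base <- if (is.null(seq$N)) {
        beta_descending(i, seq$alpha, seq$C)
      } else {
        sc <- seq$alpha / sum(beta_descending(seq_len(seq$N), seq$alpha, seq$C))
        beta_descending(i, seq$alpha, seq$C) * sc
      }
      base / harmonic_number(i)
    })
  if (!is.null(seq$N)) out[i > seq$N] <- 0
  out
}

#' Rescale a descending sequence to a finite hypothesis bound
#'
#' Given an a-priori upper bound `N` on the total number of hypotheses, the
#' descending budgets are rescaled by \eqn{\alpha / \sum_{j=1}^N \beta_j}
#' (a factor \eqn{\ge 1}) so that the first `N` budgets exhaust `alpha`
#' exactly; budgets beyond `N` are zero.
#'
#' @param seq A `beta_sequence` of kind `"descending"`.
#' @param N Upper bound on the number of hypotheses.
#' @return A `beta_sequence` of kind `"descending_truncated"`.
#' @export
rescale_to_bound <- function(seq, N) {
  stopifnot(inherits(seq, "beta_sequence"))
  if (seq$kind != "descending")
    stop("rescale_to_bound() expects a sequence of kind 'descending'")
  beta_sequence(seq$alpha, "descending_truncated", N = N, C = seq$C)
}

#' Equal split of the level over a bounded hypothesis stream
#'
#' @param alpha Overall one-sided FDR level.
#' @param N Prefixed maximum number of hypotheses; each receives
#'   \eqn{\beta_i = \alpha/N}.
#' @return A `beta_sequence` of kind `"equal"`.
#' @export
equal_sequence <- function(alpha, N) beta_sequence(alpha, "equal", N = N)

harmonic_number <- function(i) {
  vapply(i, function(k) sum(1 / seq_len(k)), numeric(1))
}

#' Dependence adjustment of a budget
#'
#' Divides the i-th budget by the harmonic number \eqn{H_i = \sum_{j\le i}1/j}.
#' Running LOND with the adjusted budgets controls the FDR under arbitrary
#' dependence of the p-values (the analogue of the Benjamini-Yekutieli
#' correction); it is conservative and equals the unadjusted budget only at
#' `i = 1`.
#'
#' @param seq A `beta_sequence` object.
#' @param i Hypothesis indices.
#' @return Adjusted budgets \eqn{\beta_i / H_i}.
#' @export
dependent_adjustment <- function(seq, i) {
  if (any(i < 1) || any(i != floor(i))) stop("'i' must be a positive integer")
  beta_values(seq, i) / harmonic_number(i)
}

#' @export
print.beta_sequence <- function(x, ...) {
  cat("Budget sequence for LOND-type online FDR control\n")
  cat(sprintf("  kind: %s, alpha = %g%s\n", x$kind, x$alpha,
              if (is.null(x$N)) "" else sprintf(", N = %d", x$N)))
  k <- min(if (is.null(x$N)) 5L else x$N, 5L)
  cat("  beta[1..", k, "]: ", paste(signif(beta_values(x, seq_len(k)), 3),
                                    collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.beta_sequence <- function(x, row.names = NULL, optional = FALSE,
                                        n = NULL, ...) {
  if (is.null(n)) n <- if (is.null(x$N)) 100L else x$N
  data.frame(index = seq_len(n), beta = beta_values(x, seq_len(n)))
}
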