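#' Empirical online FDR at a decision step
#'
#' The online FDR after `i` decisions is
#' \eqn{E\!\left[ V(i) / \max(\sum_{j\le i} R_j, 1) \right]},
#' with `V(i)` the number of falsely rejected hypotheses among the first `i`
#' decisions. Estimated as the mean false discovery proportion over the
#' replicate ledgers, each ledger listing its hypotheses in decision-time
#' order with a rejection indicator and a truth label.
#'
#' @param ledgers A list of replicate ledgers: data frames with logical
#'   columns `rejected` and `null`, rows in decision order (as produced by
#'   [run_replicates()] in `$ledgers`).
#' @param i Decision step; `NULL` (default) uses each replicate's last step.
#' @return The empirical FDR (scalar).
#' @export
fdr_at_step <- function(ledgers, i = NULL) {
  if (!length(ledgers)) stop("no replicate ledgers supplied")
  fdp <- vapply(ledgers, function(l) {
    k <- if (is.null(i)) nrow(l) else min(i, nrow(l))
    if (k < 1) return(0)
    rej <- l$rejected[seq_len(k)]
    sum(rej & l$null[seq_len(k)]) / max(sum(rej), 1)
  }, numeric(1))
  mean(fdp)
}

#' Average power over replicate ledgers
#'
#' The proportion of rejected alternatives among all alternatives, averaged
#' over the replicates that contain at least one alternative (with a random
#' order of alternatives the per-replicate count varies, and replicates with
#' none carry no power information).
#'
#' @inheritParams fdr_at_step
#' @return The average power (scalar in \[0, 1\]).
#' @export
average_power <- function(ledgers) {
  if (!length(ledgers)) stop("no replicate ledgers supplied")
  pow <- vapply(ledgers, function(l) {
    na <- sum(!l$null)
    if (na == 0) NA_real_ else sum(l$rejected & !l$null) / na
  }, numeric(1))
  if (all(is.na(pow)))
    stop("no replicate contains an alternative; average power is undefined")
  mean(pow, na.rm = TRUE)
}
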