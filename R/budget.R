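#' Fixed-budget platform trial with immediate arm replacement
#'
#' The total treatment budget of the platform is fixed at `K * n`
#' observations (`K` initially planned arms; the pre-planned control accrual
#' is unchanged). Whenever an arm stops at its interim analysis - for
#' efficacy or futility - its `n2` stage-2 observations are freed, and as
#' soon as the freed observations amount to a whole arm a new treatment arm
#' opens immediately at the current control index, entering the hypothesis
#' stream with the next index. The fixed-sample comparator (`variant =
#' "LOND"`) never stops early, so it never adds arms.
#'
#' Truth and effect of an added arm follow the budget scenario:
#' \describe{
#'   \item{1}{`pi0` and `delta` stay constant.}
#'   \item{2}{effect drawn uniformly from \{0.4, 0.8, 1.2\} for every
#'     alternative (initial and added).}
#'   \item{3}{the null probability of the `m`-th added arm is
#'     `max(pi0 - m/80, 0)`.}
#'   \item{4}{added alternatives have effect 1.}
#' }
#'
#' @param scenario A [sim_scenario()] with `budget_mode` set (1-4).
#' @return A `"sim_result"`; its summary additionally reports
#'   `rejected_alternatives`, the mean total number of rejected alternatives
#'   per replicate, and `arms_opened`.
#' @export
run_budget_mode <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (is.null(scenario$budget_mode))
    stop("scenario has no budget_mode; use run_replicates()")
  if (scenario$n < 1 || scenario$K < 1)
    stop("budget must accommodate at least one arm")
  ledgers <- vector("list", scenario$n_reps)
  n_arms <- integer(scenario$n_reps)
  for (r in seq_len(scenario$n_reps)) {
    set.seed(scenario$seed + r)
    ledgers[[r]] <- budget_replicate(scenario)
    n_arms[r] <- nrow(ledgers[[r]])
  }
  rej_alt <- vapply(ledgers, function(l) sum(l$rejected & !l$null), numeric(1))
  extra <- data.frame(
    metric = c("rejected_alternatives", "arms_opened"),
    value = c(mean(rej_alt), mean(n_arms)),
    mc_se = c(stats::sd(rej_alt), stats::sd(n_arms)) / sqrt(length(rej_alt)))
  summarize_sim(scenario, ledgers, extra = extra)
}

## Truth draw for one added arm (index i, m-th addition).
budget_truth <- function(scenario, m) {
  mode <- scenario$budget_mode
  pi0 <- if (mode == 3) max(scenario$pi0 - m / 80, 0) else scenario$pi0
  alt <- stats::runif(1) >= pi0
  delta <- 0
  if (alt) {
    delta <- if (mode == 2) sample(c(0.4, 0.8, 1.2), 1)
             else if (mode == 4) 1
             else if (length(scenario$delta) > 1) sample(scenario$delta, 1)
             else scenario$delta
  }
  list(alt = alt, delta = delta)
}

budget_replicate <- function(scenario) {
  K0 <- scenario$K; n <- scenario$n; n1 <- scenario$n1; n2 <- scenario$n2
  nd <- scenario$n_delta
  treat_budget <- K0 * n
  ncc <- scenario$controls == "NCC_CC"

  # initial arms: truth drawn as in the plain simulator, then (for budget
  # scenario 2) effects redrawn from the distributed-effect set
  truth0 <- sim_truth(scenario)
  if (scenario$budget_mode == 2 && any(truth0$alt))
    truth0$delta[truth0$alt] <- sample(c(0.4, 0.8, 1.2), sum(truth0$alt),
                                       replace = TRUE)
  controls <- stats::rnorm((K0 - 1) * nd + n)
  get_controls <- function(upto) {
    while (length(controls) < upto)
      controls <<- c(controls, stats::rnorm(max(upto - length(controls), n)))
    controls[seq_len(upto)]
  }

  arms <- list()  # per arm: open (control index), alt, delta, obs
  open_arm <- function(i, open_at, tr) {
    arms[[i]] <<- list(open = open_at, alt = tr$alt, delta = tr$delta,
                       obs = stats::rnorm(n) + tr$delta)
  }
  for (i in seq_len(K0)) open_arm(i, (i - 1L) * nd,
                                  list(alt = truth0$alt[i],
                                       delta = truth0$delta[i]))
  committed <- K0 * n
  n_added <- 0L

  if (scenario$variant == "LOND") {
    # fixed design: no interim, no early stop, no additions
    pf <- vapply(seq_len(K0), function(i) {
      s <- arms[[i]]$open
      y <- if (ncc) get_controls(s + n) else get_controls(s + n)[(s + 1):(s + n)]
      pooled_t_p(arms[[i]]$obs, y)
    }, numeric(1))
    dec <- lond(pf, scenario$beta_seq)
    return(data.frame(hypothesis = seq_len(K0), rejected = dec$rejected,
                      null = !truth0$alt, stopped_interim = FALSE))
  }

  sch <- scheduler_new(scenario$beta_seq, scenario$spending, scenario$variant,
                       t1 = n1 / n, futility = scenario$futility,
                       alpha = scenario$alpha, K = K0)
  # pending analyses: one per running arm
  pend_arm <- seq_len(K0)
  pend_stage <- rep("interim", K0)
  pend_time <- vapply(seq_len(K0), function(i) arms[[i]]$open + n1, numeric(1))
  rejected <- stopped <- logical(K0)
  null_lab <- !truth0$alt
  dec_order <- integer(0)
  rank <- 0L

  while (length(pend_arm)) {
    k <- order(pend_time, pend_arm)[1]
    i <- pend_arm[k]; stage <- pend_stage[k]; at <- pend_time[k]
    pend_arm <- pend_arm[-k]; pend_stage <- pend_stage[-k]
    pend_time <- pend_time[-k]
    s <- arms[[i]]$open
    m <- if (stage == "interim") n1 else n
    y <- if (ncc) get_controls(s + m) else get_controls(s + m)[(s + 1):(s + m)]
    p <- pooled_t_p(arms[[i]]$obs[seq_len(m)], y)
    rank <- rank + 1L
    res <- sch$step(i, stage, rank, p)
    if (res$decision == "continue") {
      pend_arm <- c(pend_arm, i)
      pend_stage <- c(pend_stage, "final")
      pend_time <- c(pend_time, s + n)
      next
    }
    # decided
    dec_order <- c(dec_order, i)
    rejected[i] <- res$decision == "reject"
    stopped[i] <- stage == "interim"
    if (stage == "interim") {
      committed <- committed - n2
      while (committed + n <= treat_budget) {
        n_added <- n_added + 1L
        j <- length(arms) + 1L
        tr <- budget_truth(scenario, n_added)
        open_arm(j, at, tr)
        committed <- committed + n
        rejected <- c(rejected, FALSE); stopped <- c(stopped, FALSE)
        null_lab <- c(null_lab, !tr$alt)
        pend_arm <- c(pend_arm, j)
        pend_stage <- c(pend_stage, "interim")
        pend_time <- c(pend_time, at + n1)
      }
    }
  }
  data.frame(hypothesis = dec_order, rejected = rejected[dec_order],
             null = null_lab[dec_order], stopped_interim = stopped[dec_order])
}
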