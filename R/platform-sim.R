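#' Platform-trial simulation scenario
#'
#' Describes a simulated platform trial with staggered arm entry and a shared
#' control arm: control patients accrue one per time unit from the start of
#' the platform; a new treatment arm opens after every `n_delta` control
#' patients; each arm recruits `n` patients (allocation 1:1:...:1 with the
#' control and all concurrently open arms, so an arm's k-th patient accrues
#' together with the k-th control patient after its opening), with an interim
#' analysis after `n1` of them and a final analysis after all `n`.
#' Observations are N(delta, 1) for alternative arms and N(0, 1) for null
#' arms and controls; one-sided pooled-variance two-sample t-tests compare
#' each arm to either its concurrent controls (`controls = "CC"`, equal
#' group sizes) or to all controls accrued so far (`"NCC_CC"`).
#'
#' Defaults are the reference study conditions: `K = 10` arms of `n = 50`
#' (25/25), a new arm every 20 controls, effect 0.6, one-sided level 0.025,
#' futility stop at interim if p > 0.5, O'Brien-Fleming spending, truncated
#' descending budgets with bound `N = 100`, pooled NCC+CC controls, 5000
#' replicates.
#'
#' @param K Number of treatment arms (initially planned arms in budget mode).
#' @param N Upper bound for the budget sequence (`NULL` for the unbounded
#'   descending sequence).
#' @param n Per-arm treatment sample size.
#' @param n1 First-stage treatment sample size (`n - n1` is saved on an
#'   interim stop).
#' @param n_delta Number of control patients between successive arm entries.
#' @param delta Effect size of alternative arms; a vector means each
#'   alternative draws its effect uniformly from the set.
#' @param pi0 Proportion of true null hypotheses.
#' @param order Arrangement of alternatives over the arm sequence:
#'   `"random"` (each arm null with probability `pi0`),
#'   `"alternatives_first"`, or `"alternatives_last"` (deterministic blocks
#'   of `round(K(1-pi0))` alternatives).
#' @param controls `"NCC_CC"` (all controls so far) or `"CC"` (concurrent
#'   only).
#' @param alpha Overall one-sided FDR level.
#' @param futility Non-binding futility bound on interim p-values (`NULL`
#'   disables futility stopping).
#' @param spending `"OBF"` or `"PO"`.
#' @param variant Testing procedure: a group-sequential LOND variant, a
#'   comparator (`"level_alpha"`, `"bonferroni"`), or `"LOND"` for the
#'   fixed-sample design without interim analyses.
#' @param beta_kind Kind of budget sequence (see [beta_sequence()]); the
#'   bound `N` applies when given.
#' @param budget_mode `NULL`, or 1-4: fixed total treatment budget `K * n`
#'   with immediate replacement of early-stopped arms (see
#'   [run_budget_mode()]).
#' @param n_reps Number of Monte-Carlo replicates.
#' @param seed Base RNG seed; replicate `r` uses `seed + r`.
#' @return An object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(K = 10, N = 100, n = 50, n1 = 25, n_delta = 20,
                         delta = 0.6, pi0 = 0.5,
                         order = c("random", "alternatives_first",
                                   "alternatives_last"),
                         controls = c("NCC_CC", "CC"),
                         alpha = 0.025, futility = 0.5,
                         spending = c("OBF", "PO"),
                         variant = "gsLOND",
                         beta_kind = c("descending_truncated", "equal",
                                       "descending", "dependent_adjusted"),
                         budget_mode = NULL, n_reps = 5000, seed = 1) {
  order <- match.arg(order)
  controls <- match.arg(controls)
  spending <- match.arg(spending)
  beta_kind <- match.arg(beta_kind)
  variant <- match.arg(variant, c(gs_variants, "LOND"))
  if (n1 < 2 || n1 >= n) stop("need 2 <= n1 < n")
  if (n_delta < 1) stop("'n_delta' must be >= 1")
  if (pi0 < 0 || pi0 > 1) stop("'pi0' must be in [0, 1]")
  if (!is.null(budget_mode) && !budget_mode %in% 1:4)
    stop("'budget_mode' must be NULL or 1, 2, 3, 4")
  if (is.null(N) && beta_kind %in% c("descending_truncated", "equal"))
    stop("beta_kind '", beta_kind, "' requires a finite N")
  seq <- if (variant %in% c("level_alpha", "bonferroni")) NULL
         else beta_sequence(alpha, beta_kind, N = N)
  structure(list(K = K, N = N, n = n, n1 = n1, n2 = n - n1,
                 n_delta = n_delta, delta = delta, pi0 = pi0, order = order,
                 controls = controls, alpha = alpha, futility = futility,
                 spending = spending, variant = variant,
                 beta_kind = beta_kind, beta_seq = seq,
                 budget_mode = budget_mode, n_reps = n_reps, seed = seed),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "Platform-trial scenario: K = %d arms (n = %d = %d + %d), new arm every %d controls\n",
    x$K, x$n, x$n1, x$n2, x$n_delta))
  cat(sprintf("  %s, %s spending, %s controls, alpha = %g, futility = %s\n",
              x$variant, x$spending, x$controls, x$alpha,
              if (is.null(x$futility)) "none" else format(x$futility)))
  cat(sprintf("  pi0 = %g, delta = %s, order = %s, beta: %s (N = %s)\n",
              x$pi0, paste(x$delta, collapse = "/"), x$order, x$beta_kind,
              if (is.null(x$N)) "Inf" else x$N))
  cat(sprintf("  %d replicates, seed %d%s\n", x$n_reps, x$seed,
              if (is.null(x$budget_mode)) ""
              else paste0(", budget scenario ", x$budget_mode)))
  invisible(x)
}

## Truth assignment for the K initially planned arms.
sim_truth <- function(scenario, K = scenario$K) {
  alt <- switch(scenario$order,
    random = stats::runif(K) >= scenario$pi0,
    alternatives_first = {
      m1 <- round(K * (1 - scenario$pi0))
      seq_len(K) <= m1
    },
    alternatives_last = {
      m1 <- round(K * (1 - scenario$pi0))
      seq_len(K) > K - m1
    })
  delta <- numeric(K)
  if (any(alt)) {
    delta[alt] <- if (length(scenario$delta) > 1) {
      sample(scenario$delta, sum(alt), replace = TRUE)
    } else scenario$delta
  }
  list(alt = alt, delta = delta)
}

## One-sided pooled-variance two-sample t-test p-value for H1: mu_x > mu_y.
pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  mx <- sum(x) / nx; my <- sum(y) / ny
  df <- nx + ny - 2
  s2 <- (sum((x - mx)^2) + sum((y - my)^2)) / df
  tt <- (mx - my) / sqrt(s2 * (1 / nx + 1 / ny))
  stats::pt(tt, df, lower.tail = FALSE)
}

#' Generate one platform-trial replicate
#'
#' Draws control and treatment observations for the scenario and computes the
#' chronologically ordered stream of interim and final analysis events. Arm
#' `i` opens after `(i-1) * n_delta` control patients; using the control
#' index as the time scale, its interim analysis falls at control index
#' `(i-1) n_delta + n1` and its final analysis at `(i-1) n_delta + n`.
#' Simultaneous analyses of different arms are ordered by arm index (the
#' predefined order of entry) and the emitted event times are the resulting
#' ranks, so the stream carries an explicit strict total order; the control
#' index is kept in column `info_time`.
#'
#' @param scenario A [sim_scenario()].
#' @param truth Optional list with elements `alt` (logical) and `delta`
#'   (numeric per-arm effects), e.g. from a paired run; drawn from the
#'   scenario when `NULL`. Random draws use the current RNG state.
#' @param keep_data If `TRUE`, also return the simulated `controls` vector
#'   and `treatment` matrix (n x K).
#' @return A list with `events` (an [analysis_events()] stream with extra
#'   column `info_time`), `truth`, and the per-arm interim/final p-values.
#' @export
generate_trial <- function(scenario, truth = NULL, keep_data = FALSE) {
  K <- scenario$K; n <- scenario$n; n1 <- scenario$n1
  nd <- scenario$n_delta
  if (is.null(truth)) truth <- sim_truth(scenario)
  n_controls <- (K - 1) * nd + n
  controls <- stats::rnorm(n_controls)
  treat <- matrix(stats::rnorm(n * K), n, K)
  if (any(truth$alt))
    treat <- treat + rep(truth$delta, each = n)
  ncc <- scenario$controls == "NCC_CC"
  p1 <- pf <- numeric(K)
  for (i in seq_len(K)) {
    s <- (i - 1L) * nd
    y1 <- if (ncc) controls[seq_len(s + n1)] else controls[(s + 1):(s + n1)]
    yf <- if (ncc) controls[seq_len(s + n)] else controls[(s + 1):(s + n)]
    p1[i] <- pooled_t_p(treat[seq_len(n1), i], y1)
    pf[i] <- pooled_t_p(treat[, i], yf)
  }
  s0 <- (seq_len(K) - 1L) * nd
  ev <- data.frame(hypothesis = rep(seq_len(K), 2L),
                   stage = rep(c("interim", "final"), each = K),
                   info_time = c(s0 + n1, s0 + n),
                   p_value = c(p1, pf))
  ev <- ev[order(ev$info_time, ev$hypothesis, ev$stage != "final"), ]
  # for the same arm the interim (smaller info_time) always comes first;
  # across arms ties are broken by index
  ev$time <- seq_len(nrow(ev))
  rownames(ev) <- NULL
  ev <- ev[, c("hypothesis", "stage", "time", "p_value", "info_time")]
  class(ev) <- c("analysis_events", "data.frame")
  out <- list(events = ev, truth = truth, p_interim = p1, p_final = pf)
  if (keep_data) {
    out$controls <- controls
    out$treatment <- treat
  }
  out
}

## Decision ledger (one replicate): hypotheses in decision-time order with
## rejection indicator and truth label.
trial_ledger <- function(rejected, stopped_interim, decision_order, alt) {
  data.frame(hypothesis = decision_order,
             rejected = rejected[decision_order],
             null = !alt[decision_order],
             stopped_interim = stopped_interim[decision_order])
}

run_one_replicate <- function(scenario) {
  trial <- generate_trial(scenario)
  K <- scenario$K
  alt <- trial$truth$alt
  if (scenario$variant == "LOND") {
    dec <- lond(trial$p_final, scenario$beta_seq)
    rejected <- dec$rejected
    stopped <- rep(FALSE, K)
    order_dec <- seq_len(K)
  } else {
    log <- run_schedule(trial$events, scenario$beta_seq, scenario$spending,
                        scenario$variant, t1 = scenario$n1 / scenario$n,
                        futility = scenario$futility,
                        alpha = scenario$alpha, K = K, skip_resolved = TRUE)
    rejected <- stopped <- logical(K)
    dec_time <- numeric(K)
    decided <- log$decision %in% c("reject", "futility", "retain")
    for (r in which(decided)) {
      h <- log$hypothesis[r]
      rejected[h] <- log$decision[r] == "reject"
      stopped[h] <- log$stage[r] == "interim"
      dec_time[h] <- log$time[r]
    }
    order_dec <- order(dec_time)
  }
  trial_ledger(rejected, stopped, order_dec, alt)
}

#' Run the Monte-Carlo replicates of a scenario
#'
#' Runs `n_reps` independent platform-trial replicates (replicate `r` is
#' seeded with `seed + r`, so runs are reproducible and scenarios differing
#' only in the analysis settings are paired by common random numbers) and
#' aggregates the operating characteristics: empirical FDR at the last
#' decision step, average power (proportion of rejected alternatives among
#' all alternatives, over replicates containing alternatives), and the
#' average percentage of stage-2 treatment observations saved by interim
#' stopping.
#'
#' @param scenario A [sim_scenario()].
#' @return An object of class `"sim_result"`: list with the `scenario`, the
#'   per-replicate `ledgers` (see [fdr_at_step()]), and a `summary` data
#'   frame of metrics with Monte-Carlo standard errors.
#' @export
run_replicates <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  ledgers <- vector("list", scenario$n_reps)
  for (r in seq_len(scenario$n_reps)) {
    set.seed(scenario$seed + r)
    ledgers[[r]] <- run_one_replicate(scenario)
  }
  summarize_sim(scenario, ledgers)
}

summarize_sim <- function(scenario, ledgers, extra = NULL) {
  fdp <- vapply(ledgers, function(l) {
    R <- sum(l$rejected)
    sum(l$rejected & l$null) / max(R, 1)
  }, numeric(1))
  pow <- vapply(ledgers, function(l) {
    na <- sum(!l$null)
    if (na == 0) NA_real_ else sum(l$rejected & !l$null) / na
  }, numeric(1))
  stage2_frac <- scenario$n2 / scenario$n
  saved <- vapply(ledgers, function(l) {
    100 * stage2_frac * sum(l$stopped_interim) / nrow(l)
  }, numeric(1))
  if (scenario$variant == "LOND") saved[] <- 0
  mse <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_))
    c(mean(x), stats::sd(x) / sqrt(length(x)))
  }
  rows <- rbind(fdr = mse(fdp), power = mse(pow), saved_pct = mse(saved))
  summary <- data.frame(metric = rownames(rows), value = rows[, 1],
                        mc_se = rows[, 2], row.names = NULL)
  if (!is.null(extra)) summary <- rbind(summary, extra)
  structure(list(scenario = scenario, ledgers = ledgers, summary = summary),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Platform-trial simulation: %s, %d replicates\n",
              x$scenario$variant, length(x$ledgers)))
  s <- x$summary
  for (k in seq_len(nrow(s))) {
    if (is.na(s$value[k])) next
    cat(sprintf("  %-22s %8.4f  (MC-SE %.4f)\n", s$metric[k], s$value[k],
                s$mc_se[k]))
  }
  invisible(x)
}

#' Average percentage of treatment sample size saved by interim stopping
#'
#' The percentage of the fixed-sample design's total treatment sample size
#' (`K * n` observations) actually saved by early stopping for efficacy or
#' futility: each arm stopped at its interim analysis saves its `n2` stage-2
#' observations, so the per-replicate saving is
#' `100 * n2 * (arms stopped at interim) / (K * n)`, averaged over
#' replicates. Under the global null with a futility bound of 0.5 about half
#' the arms stop at interim, saving about 25% when the stages are equal.
#'
#' @param result A `"sim_result"` from [run_replicates()].
#' @return The mean percentage (0-100).
#' @export
saved_sample_size <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  if (result$scenario$variant == "LOND")
    stop("saved sample size is not applicable to the fixed-sample design")
  result$summary$value[result$summary$metric == "saved_pct"]
}
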