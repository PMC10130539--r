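#' Analysis-event stream for the group-sequential scheduler
#'
#' Bundles and validates the chronology of interim and final analyses of the
#' (possibly overlapping) hypotheses of a platform trial. Timestamps must be
#' strictly increasing: the chronology is a total order, and any real-time
#' ties must be resolved before building the stream (the simulator breaks
#' them by hypothesis index, the predefined order of entry).
#'
#' @param hypothesis Integer vector of hypothesis indices (>= 1).
#' @param stage Character vector, `"interim"` or `"final"`.
#' @param time Strictly increasing numeric timestamps.
#' @param p_value One-sided p-values in (0, 1\] (cumulative-data p-value for
#'   final analyses).
#' @return A data frame of class `"analysis_events"`.
#' @export
analysis_events <- function(hypothesis, stage, time, p_value) {
  ev <- data.frame(hypothesis = as.integer(hypothesis),
                   stage = as.character(stage),
                   time = as.numeric(time),
                   p_value = as.numeric(p_value))
  validate_events(ev)
  class(ev) <- c("analysis_events", "data.frame")
  ev
}

validate_events <- function(ev) {
  req <- c("hypothesis", "stage", "time", "p_value")
  if (!all(req %in% names(ev)))
    stop("events need columns: ", paste(req, collapse = ", "))
  if (nrow(ev) == 0) return(invisible(ev))
  if (!all(ev$stage %in% c("interim", "final")))
    stop("'stage' must be 'interim' or 'final'")
  if (any(ev$hypothesis < 1)) stop("hypothesis indices must be >= 1")
  if (any(ev$p_value <= 0 | ev$p_value > 1))
    stop("p-values must be in (0, 1]")
  if (is.unsorted(ev$time, strictly = TRUE))
    stop("event times must be strictly increasing (sorted, no ties)")
  for (h in unique(ev$hypothesis)) {
    st <- ev$stage[ev$hypothesis == h]
    if (anyDuplicated(st))
      stop("hypothesis ", h, " has a duplicated ", st[duplicated(st)][1],
           " analysis")
    if ("final" %in% st && "interim" %in% st &&
        which(ev$stage == "final" & ev$hypothesis == h) <
          which(ev$stage == "interim" & ev$hypothesis == h))
      stop("hypothesis ", h, ": final analysis precedes its interim analysis")
  }
  invisible(ev)
}

gs_variants <- c("gsLOND", "gsLOND.II", "gsLOND.III", "gsLOND.II.III",
                 "level_alpha", "bonferroni")

#' Comparator nominal levels (no online updating)
#'
#' The unadjusted level-alpha test uses `alpha` for every hypothesis; the
#' group-sequential Bonferroni comparator uses `alpha / K` with the true
#' number of hypotheses `K` (a best case, since `K` is unknown in a real
#' platform trial). Group-sequential boundaries are then derived from these
#' constant nominal levels.
#'
#' @param i Hypothesis index (ignored; levels are constant).
#' @param mode `"level_alpha"` or `"bonferroni"`.
#' @param alpha Overall one-sided level.
#' @param K Number of hypotheses (required for Bonferroni).
#' @return The nominal one-sided level.
#' @export
comparator_levels <- function(i, mode = c("level_alpha", "bonferroni"),
                              alpha, K = NULL) {
  mode <- match.arg(mode)
  if (mode == "level_alpha") return(rep(alpha, length(i)))
  if (is.null(K) || K < 1) stop("Bonferroni comparator requires K >= 1")
  rep(alpha / K, length(i))
}

## Incremental scheduler state. Exposed internally so that the budget-mode
## simulator can feed events one at a time as arms are opened adaptively.
scheduler_new <- function(seq, spending = "PO",
                          variant = c("gsLOND", "gsLOND.II", "gsLOND.III",
                                      "gsLOND.II.III", "level_alpha",
                                      "bonferroni"),
                          t1 = 0.5, futility = NULL,
                          alpha = NULL, K = NULL) {
  variant <- match.arg(variant)
  spending <- as_spending(spending)
  if (variant %in% c("level_alpha", "bonferroni")) {
    if (is.null(alpha)) stop("comparator variants require 'alpha'")
    const_level <- comparator_levels(1L, variant, alpha, K)
  } else {
    stopifnot(inherits(seq, "beta_sequence"))
    const_level <- NULL
  }
  st <- new.env(parent = emptyenv())
  st$rej_hyp <- integer(0)     # indices of rejected hypotheses
  st$rej_time <- numeric(0)    # their decision times
  st$hyp <- list()             # per-hypothesis records
  st$last_time <- -Inf
  uses_J <- variant %in% c("gsLOND.III", "gsLOND.II.III")
  uses_increment <- variant %in% c("gsLOND.II", "gsLOND.II.III")
  lond_type <- !(variant %in% c("level_alpha", "bonferroni"))

  cnt_before <- function(i, t, jset) {
    keep <- st$rej_time < t & (if (jset) st$rej_hyp != i else st$rej_hyp < i)
    sum(keep)
  }
  level_at <- function(i, t, jset) {
    if (!lond_type) return(const_level)
    lond_level(beta_values(seq, i), cnt_before(i, t, jset))
  }

  step <- function(hypothesis, stage, time, p_value) {
    i <- as.integer(hypothesis)
    if (time <= st$last_time)
      stop("events out of order: time ", time, " not after ", st$last_time)
    st$last_time <- time
    key <- as.character(i)
    h <- st$hyp[[key]]
    if (stage == "interim") {
      if (!is.null(h)) stop("hypothesis ", i, " already had its interim")
      n_rej <- cnt_before(i, time, uses_J)
      level <- level_at(i, time, uses_J)
      a1 <- two_stage_boundaries(level, t1, spending)$a1
      decision <- if (p_value <= a1) "reject"
                  else if (!is.null(futility) && p_value >= futility) "futility"
                  else "continue"
      st$hyp[[key]] <- list(
        status = switch(decision, reject = "rejected_interim",
                        futility = "stopped_futility", continue = "open"),
        interim_level_I = if (lond_type)
          lond_level(beta_values(seq, i), cnt_before(i, time, FALSE))
          else const_level,
        level_used = level, a1_used = a1)
      if (decision == "reject") {
        st$rej_hyp <- c(st$rej_hyp, i)
        st$rej_time <- c(st$rej_time, time)
      }
      list(n_rejections = n_rej, level = level, boundary = a1,
           decision = decision)
    } else if (stage == "final") {
      if (is.null(h)) stop("hypothesis ", i, ": final without interim")
      if (h$status != "open")
        stop("hypothesis ", i, ": final analysis after ", h$status)
      n_rej <- cnt_before(i, time, uses_J)
      level <- level_at(i, time, uses_J)
      level_I <- if (lond_type)
        lond_level(beta_values(seq, i), cnt_before(i, time, FALSE))
        else const_level
      a2 <- if (uses_increment && level_I > h$interim_level_I + 1e-12) {
        exhaust_increment_boundary(level, h$a1_used, t1)
      } else {
        two_stage_boundaries(level, t1, spending)$a2
      }
      decision <- if (p_value <= a2) "reject" else "retain"
      st$hyp[[key]]$status <- if (decision == "reject") "rejected_final"
                              else "retained"
      if (decision == "reject") {
        st$rej_hyp <- c(st$rej_hyp, i)
        st$rej_time <- c(st$rej_time, time)
      }
      list(n_rejections = n_rej, level = level, boundary = a2,
           decision = decision)
    } else stop("unknown stage: ", stage)
  }

  status <- function(i) {
    h <- st$hyp[[as.character(i)]]
    if (is.null(h)) "pending" else h$status
  }

  list(step = step, status = status, state = st, variant = variant)
}

#' Run a group-sequential LOND variant over an event chronology
#'
#' Processes the events strictly in time order. At an interim analysis the
#' nominal level is the LOND level computed from the rejections decided
#' strictly before that time (among earlier-entering hypotheses for gsLOND
#' and gsLOND.II; among all other hypotheses for gsLOND.III and
#' gsLOND.II.III), the boundary is the spending-function value at `t1`, and
#' the arm stops early for efficacy (`p <= a1`) or futility
#' (`p >= futility`, non-binding). At a final analysis the level is
#' recomputed from the rejections decided by then; gsLOND and gsLOND.III
#' rebuild the two-stage plan at the updated level with the original spending
#' function, while gsLOND.II (and the combination gsLOND.II.III) exhausts the
#' increment over the interim spend actually used whenever the level
#' increased because an earlier-entering hypothesis was rejected in between
#' (see [exhaust_increment_boundary()]). Decisions are never revisited.
#'
#' The comparators `"level_alpha"` (no multiplicity adjustment) and
#' `"bonferroni"` (`alpha / K`) use constant nominal levels.
#'
#' @param events An [analysis_events()] stream (or a data frame with the same
#'   columns, already sorted with strictly increasing times).
#' @param seq A [beta_sequence()] (ignored by the comparator variants).
#' @param spending A [spending_function()] or `"OBF"` / `"PO"`.
#' @param variant One of `"gsLOND"`, `"gsLOND.II"`, `"gsLOND.III"`,
#'   `"gsLOND.II.III"`, `"level_alpha"`, `"bonferroni"`.
#' @param t1 First-stage information fraction (default 0.5).
#' @param futility Optional non-binding one-sided futility bound on interim
#'   p-values; `NULL` disables futility stopping.
#' @param alpha,K Level and hypothesis count for the comparator variants.
#' @param skip_resolved If `TRUE`, a final event for a hypothesis already
#'   stopped at its interim analysis is skipped (recorded with decision
#'   `"skipped"`) instead of raising an error. Useful for event streams that
#'   enumerate the full potential chronology, such as the simulator's, where
#'   a final analysis never takes place once the arm stopped early.
#' @return A data frame of class `"gs_decisions"`: one row per event with
#'   `hypothesis`, `stage`, `time`, `p_value`, `n_rejections` (the count the
#'   level was based on), `level`, `boundary`, `decision` (`"reject"`,
#'   `"continue"`, `"futility"`, `"retain"`).
#' @examples
#' ev <- analysis_events(hypothesis = 1, stage = c("interim", "final"),
#'                       time = 1:2, p_value = c(0.2, 0.004))
#' run_schedule(ev, equal_sequence(0.05, 3), spending = "PO")
#' @export
run_schedule <- function(events, seq = NULL, spending = "PO",
                         variant = "gsLOND", t1 = 0.5, futility = NULL,
                         alpha = NULL, K = NULL, skip_resolved = FALSE) {
  validate_events(events)
  sch <- scheduler_new(seq, spending, variant, t1, futility, alpha, K)
  n <- nrow(events)
  n_rejections <- integer(n); level <- numeric(n)
  boundary <- numeric(n); decision <- character(n)
  for (r in seq_len(n)) {
    if (skip_resolved && events$stage[r] == "final" &&
        sch$status(events$hypothesis[r]) %in%
          c("rejected_interim", "stopped_futility")) {
      n_rejections[r] <- NA_integer_; level[r] <- NA_real_
      boundary[r] <- NA_real_; decision[r] <- "skipped"
      next
    }
    res <- sch$step(events$hypothesis[r], events$stage[r], events$time[r],
                    events$p_value[r])
    n_rejections[r] <- res$n_rejections
    level[r] <- res$level
    boundary[r] <- res$boundary
    decision[r] <- res$decision
  }
  out <- data.frame(hypothesis = events$hypothesis, stage = events$stage,
                    time = events$time, p_value = events$p_value,
                    n_rejections = n_rejections, level = level,
                    boundary = boundary, decision = decision)
  structure(out, class = c("gs_decisions", "data.frame"),
            variant = sch$variant)
}

#' Per-hypothesis outcome of a scheduler run
#'
#' @param log A `"gs_decisions"` data frame from [run_schedule()].
#' @return A data frame with one row per hypothesis: `hypothesis`, `rejected`
#'   (logical), `stopped_interim` (stopped at interim for efficacy or
#'   futility, i.e. stage-2 sample saved), `status`.
#' @export
hypothesis_outcomes <- function(log) {
  hyps <- sort(unique(log$hypothesis))
  res <- lapply(hyps, function(h) {
    d <- log[log$hypothesis == h, , drop = FALSE]
    rej <- any(d$decision == "reject")
    interim_stop <- d$decision[d$stage == "interim"][1] %in%
      c("reject", "futility")
    status <- if (rej && interim_stop) "rejected_interim"
      else if (rej) "rejected_final"
      else if (isTRUE(interim_stop)) "stopped_futility"
      else if (any(d$stage == "final")) "retained"
      else "pending"
    data.frame(hypothesis = h, rejected = rej,
               stopped_interim = isTRUE(interim_stop), status = status)
  })
  do.call(rbind, res)
}
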