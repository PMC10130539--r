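#' Nominal levels and two-stage boundaries of the three-hypothesis example
#'
#' The worked example used throughout the package: at most `K = 3` hypotheses
#' tested at one-sided `alpha = 0.05` split equally (`beta_i = alpha/3`).
#' For 0, 1 or 2 previous rejections this tabulates the LOND nominal level
#' `beta_i * (R + 1)` and the corresponding interim/final thresholds of the
#' Pocock and O'Brien-Fleming spending designs at information fraction `t1`.
#'
#' @param alpha Overall one-sided level (default 0.05).
#' @param K Number of hypotheses the level is split over (default 3).
#' @param t1 First-stage information fraction (default 0.5).
#' @param digits Rounding applied to the returned table; `NULL` for full
#'   precision.
#' @return A data frame with columns `n_rejections`, `lond_level`, `po_a1`,
#'   `po_a2`, `obf_a1`, `obf_a2`.
#' @examples
#' reproduce_table1()
#' @export
reproduce_table1 <- function(alpha = 0.05, K = 3, t1 = 0.5, digits = 4) {
  beta <- alpha / K
  R <- 0:(K - 1)
  lv <- lond_level(beta, R)
  po <- lapply(lv, two_stage_boundaries, t1 = t1, spending = "PO")
  obf <- lapply(lv, two_stage_boundaries, t1 = t1, spending = "OBF")
  out <- data.frame(n_rejections = R, lond_level = lv,
                    po_a1 = vapply(po, `[[`, numeric(1), "a1"),
                    po_a2 = vapply(po, `[[`, numeric(1), "a2"),
                    obf_a1 = vapply(obf, `[[`, numeric(1), "a1"),
                    obf_a2 = vapply(obf, `[[`, numeric(1), "a2"))
  if (!is.null(digits)) out[-1] <- round(out[-1], digits)
  out
}

#' Event chronology of the three-hypothesis example
#'
#' The staggered two-stage chronology used by the worked example: three arms
#' enter in order, each with one interim and one final analysis, interleaved
#' as interim(H1), interim(H2), final(H1), interim(H3), final(H2), final(H3).
#' Timestamps are the event ranks 1..6.
#'
#' @param p_interim,p_final Numeric vectors of length 3: the interim and
#'   final one-sided p-values of the three hypotheses.
#' @return An [analysis_events()] stream.
#' @export
toy_chronology <- function(p_interim, p_final) {
  stopifnot(length(p_interim) == 3, length(p_final) == 3)
  analysis_events(
    hypothesis = c(1L, 2L, 1L, 3L, 2L, 3L),
    stage = c("interim", "interim", "final", "interim", "final", "final"),
    time = 1:6,
    p_value = c(p_interim[1], p_interim[2], p_final[1],
                p_interim[3], p_final[2], p_final[3]))
}

## p-values that force a prescribed outcome for one hypothesis, for any
## boundary configuration of the example: every interim boundary is below
## 0.04 and every final boundary is below 0.05, so 0.4 always continues and
## 0.99 always retains, while 1e-8 always rejects.
toy_force <- function(outcome) {
  switch(outcome,
         retain = c(interim = 0.4, final = 0.99),
         reject_interim = c(interim = 1e-8, final = 0.99),
         reject_final = c(interim = 0.4, final = 1e-8),
         stop("unknown outcome: ", outcome))
}

toy_run <- function(outcomes, variant, alpha = 0.05, t1 = 0.5,
                    spending = "PO") {
  ps <- vapply(outcomes, toy_force, numeric(2))
  ev <- toy_chronology(ps["interim", ], ps["final", ])
  run_schedule(ev, equal_sequence(alpha, 3), spending = spending,
               variant = variant, t1 = t1, futility = NULL,
               skip_resolved = TRUE)
}

#' Boundaries of H2 under all outcome combinations of H1 and H3
#'
#' Drives the scheduler through the example chronology with p-values forcing
#' each of the nine outcome combinations for H1 and H3 (retained, rejected at
#' interim, rejected at final) while H2 runs to its final analysis, and
#' records H2's interim and final boundaries under the four group-sequential
#' LOND variants (Pocock design). The variants only differ when the relevant
#' rejection count changes between H2's interim and final analysis: a
#' rejection of H1 at its final analysis (after H2's interim) triggers the
#' increment-exhausting boundary of gsLOND.II, and a rejection of H3 at its
#' interim (before H2's final) enters the count only for gsLOND.III and
#' gsLOND.II.III.
#'
#' @inheritParams reproduce_table1
#' @return A data frame with one row per (H1, H3) outcome combination:
#'   `h1`, `h3`, `stage1`, `stage2_gslond`, `stage2_gslond2`,
#'   `stage2_gslond3`, `stage2_gslond23`.
#' @export
reproduce_table2 <- function(alpha = 0.05, t1 = 0.5, digits = 4) {
  outs <- c("retain", "reject_interim", "reject_final")
  grid <- expand.grid(h3 = outs, h1 = outs, stringsAsFactors = FALSE)[2:1]
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    oc <- c(grid$h1[k], "retain", grid$h3[k])
    get2 <- function(variant) {
      log <- toy_run(oc, variant, alpha, t1)
      h2 <- log[log$hypothesis == 2L, ]
      c(h2$boundary[h2$stage == "interim"], h2$boundary[h2$stage == "final"])
    }
    b <- vapply(c("gsLOND", "gsLOND.II", "gsLOND.III", "gsLOND.II.III"),
                get2, numeric(2))
    data.frame(h1 = grid$h1[k], h3 = grid$h3[k],
               stage1 = b[1, "gsLOND"],
               stage2_gslond = b[2, "gsLOND"],
               stage2_gslond2 = b[2, "gsLOND.II"],
               stage2_gslond3 = b[2, "gsLOND.III"],
               stage2_gslond23 = b[2, "gsLOND.II.III"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(digits)) out[-(1:2)] <- round(out[-(1:2)], digits)
  out
}

#' Boundaries of H3 under the outcome combinations of H1 and H2
#'
#' As [reproduce_table2()], but for the last-entering hypothesis H3: H1 is
#' fully decided before H3's interim analysis, so only two outcomes for H1
#' matter (retained / rejected), while a rejection of H2 at its final
#' analysis - which falls between H3's interim and final - raises H3's level
#' only at the final analysis, where gsLOND.II exhausts the increment
#' (boundaries 0.0279 and 0.0389 instead of the plan values 0.0190, 0.0297).
#'
#' @inheritParams reproduce_table1
#' @return A data frame with columns `h1`, `h2`, `stage1`, `stage2_gslond`,
#'   `stage2_gslond2`.
#' @export
reproduce_table3 <- function(alpha = 0.05, t1 = 0.5, digits = 4) {
  grid <- data.frame(
    h1 = c("retain", "reject_interim", "retain", "retain",
           "reject_interim", "reject_interim"),
    h2 = c("retain", "retain", "reject_interim", "reject_final",
           "reject_interim", "reject_final"))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    oc <- c(grid$h1[k], grid$h2[k], "retain")
    get3 <- function(variant) {
      log <- toy_run(oc, variant, alpha, t1)
      h3 <- log[log$hypothesis == 3L, ]
      c(h3$boundary[h3$stage == "interim"], h3$boundary[h3$stage == "final"])
    }
    b <- vapply(c("gsLOND", "gsLOND.II"), get3, numeric(2))
    data.frame(h1 = grid$h1[k], h2 = grid$h2[k],
               stage1 = b[1, "gsLOND"],
               stage2_gslond = b[2, "gsLOND"],
               stage2_gslond2 = b[2, "gsLOND.II"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(digits)) out[-(1:2)] <- round(out[-(1:2)], digits)
  out
}
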