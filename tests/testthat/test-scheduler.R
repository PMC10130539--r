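# Expected boundaries for the three-hypothesis worked example (equal beta,
# alpha = 0.05 one-sided, Pocock design, t1 = 0.5), frozen after verification
# against the exact two-stage computation.
tab2_expected <- data.frame(
  stage1          = c(0.0103, 0.0103, 0.0103, 0.0207, 0.0207, 0.0207,
                      0.0103, 0.0103, 0.0103),
  stage2_gslond   = c(0.0089, 0.0089, 0.0089, 0.0190, 0.0190, 0.0190,
                      0.0190, 0.0190, 0.0190),
  stage2_gslond2  = c(0.0089, 0.0089, 0.0089, 0.0190, 0.0190, 0.0190,
                      0.0279, 0.0279, 0.0279),
  stage2_gslond3  = c(0.0089, 0.0190, 0.0089, 0.0190, 0.0297, 0.0190,
                      0.0190, 0.0297, 0.0190),
  stage2_gslond23 = c(0.0089, 0.0190, 0.0089, 0.0190, 0.0297, 0.0190,
                      0.0279, 0.0459, 0.0279))
tab3_expected <- data.frame(
  stage1         = c(0.0103, 0.0207, 0.0207, 0.0103, 0.0310, 0.0207),
  stage2_gslond  = c(0.0089, 0.0190, 0.0190, 0.0190, 0.0297, 0.0297),
  stage2_gslond2 = c(0.0089, 0.0190, 0.0190, 0.0279, 0.0297, 0.0389))

test_that("all outcome combinations for the middle hypothesis give the expected boundaries", {
  tab2 <- reproduce_table2(digits = NULL)
  for (col in names(tab2_expected))
    expect_lt(max(abs(tab2[[col]] - tab2_expected[[col]])), 1e-4,
              label = paste(col, "absolute deviation"))
})

test_that("all outcome combinations for the last hypothesis give the expected boundaries", {
  tab3 <- reproduce_table3(digits = NULL)
  for (col in names(tab3_expected))
    expect_lt(max(abs(tab3[[col]] - tab3_expected[[col]])), 1e-4,
              label = paste(col, "absolute deviation"))
})

test_that("variants only raise final boundaries relative to gsLOND", {
  tab2 <- reproduce_table2(digits = NULL)
  expect_true(all(tab2$stage2_gslond2 >= tab2$stage2_gslond - 1e-12))
  expect_true(all(tab2$stage2_gslond3 >= tab2$stage2_gslond - 1e-12))
  expect_true(all(tab2$stage2_gslond23 >= tab2$stage2_gslond - 1e-12))
  # equality whenever no in-between rejection occurred (rows 1 and 3:
  # nothing decided between H2's interim and final except H3's final)
  expect_equal(tab2$stage2_gslond2[c(1, 3)], tab2$stage2_gslond[c(1, 3)])
  expect_equal(tab2$stage2_gslond3[c(1, 3)], tab2$stage2_gslond[c(1, 3)])
})

test_that("gsLOND levels are online: future events never change earlier levels", {
  seq3 <- equal_sequence(0.05, 3)
  base <- run_schedule(toy_chronology(c(0.4, 0.4, 1e-8), c(0.99, 0.99, 0.99)),
                       seq3, "PO", "gsLOND", skip_resolved = TRUE)
  # change H3's p-values entirely; H1 and H2 rows must be identical
  alt <- run_schedule(toy_chronology(c(0.4, 0.4, 0.4), c(0.99, 0.99, 1e-8)),
                      seq3, "PO", "gsLOND", skip_resolved = TRUE)
  keep <- base$hypothesis != 3
  expect_equal(base[keep, c("level", "boundary", "decision")],
               alt[keep, c("level", "boundary", "decision")])
})

test_that("gsLOND.III differs from gsLOND exactly by later-entering rejections", {
  seq3 <- equal_sequence(0.05, 3)
  # H3 rejected at interim, between H2's analyses
  ev <- toy_chronology(c(0.4, 0.4, 1e-8), c(0.99, 0.99, 0.99))
  g1 <- run_schedule(ev, seq3, "PO", "gsLOND", skip_resolved = TRUE)
  g3 <- run_schedule(ev, seq3, "PO", "gsLOND.III", skip_resolved = TRUE)
  h2f <- function(x) x[x$hypothesis == 2 & x$stage == "final", ]
  expect_equal(h2f(g3)$n_rejections - h2f(g1)$n_rejections, 1)
  # interim rows (before any j > i decision) are identical
  expect_equal(g1[g1$stage == "interim", "level"],
               g3[g3$stage == "interim", "level"])
})

test_that("rejection sets are monotone across variants on random streams", {
  s <- beta_sequence(0.1, "descending_truncated", N = 10)
  for (sd in 1:8) {
    ev <- random_event_stream(K = 5, seed = sd)
    r0 <- rejected_set(run_schedule(ev, s, "PO", "gsLOND",
                                    skip_resolved = TRUE))
    for (v in c("gsLOND.II", "gsLOND.III", "gsLOND.II.III")) {
      rv <- rejected_set(run_schedule(ev, s, "PO", v, skip_resolved = TRUE))
      expect_true(all(r0 %in% rv),
                  label = sprintf("seed %d, %s contains gsLOND", sd, v))
    }
  }
})

test_that("a single hypothesis reduces to a plain two-stage test at beta_1", {
  s <- beta_sequence(0.025, "descending_truncated", N = 10)
  b1 <- beta_values(s, 1)
  pl <- two_stage_boundaries(b1, 0.5, "OBF")
  ev <- analysis_events(c(1, 1), c("interim", "final"), 1:2, c(0.2, 0.9))
  for (v in c("gsLOND", "gsLOND.II", "gsLOND.III", "gsLOND.II.III")) {
    log <- run_schedule(ev, s, "OBF", v)
    expect_equal(log$boundary, c(pl$a1, pl$a2), tolerance = 1e-12)
    expect_equal(log$level, c(b1, b1))
  }
})

test_that("futility stops at interim without rejection and saves the final", {
  s <- equal_sequence(0.05, 3)
  ev <- toy_chronology(rep(0.9, 3), rep(0.9, 3))
  log <- run_schedule(ev, s, "PO", "gsLOND", futility = 0.5,
                      skip_resolved = TRUE)
  ints <- log[log$stage == "interim", ]
  expect_true(all(ints$decision == "futility"))
  expect_true(all(log$decision[log$stage == "final"] == "skipped"))
  # futility stops never inflate later levels
  expect_equal(ints$level, rep(0.05 / 3, 3))
  out <- hypothesis_outcomes(log)
  expect_true(all(!out$rejected))
  expect_true(all(out$status == "stopped_futility"))
})

test_that("comparator variants use constant nominal levels", {
  expect_equal(comparator_levels(1:5, "level_alpha", 0.025), rep(0.025, 5))
  expect_equal(comparator_levels(1:5, "bonferroni", 0.025, K = 10),
               rep(0.0025, 5))
  expect_equal(comparator_levels(1, "bonferroni", 0.025, K = 1), 0.025)
  expect_error(comparator_levels(1, "bonferroni", 0.025, K = 0), "K >= 1")
  ev <- toy_chronology(c(1e-8, 0.4, 0.4), c(0.99, 1e-8, 0.99))
  log <- run_schedule(ev, NULL, "PO", "level_alpha", alpha = 0.025,
                      skip_resolved = TRUE)
  expect_true(all(log$level[log$decision != "skipped"] == 0.025))
})

test_that("malformed event streams are rejected", {
  expect_error(analysis_events(1:2, c("interim", "interim"), c(2, 1),
                               c(0.5, 0.5)), "strictly increasing")
  expect_error(analysis_events(c(1, 2), c("interim", "interim"), c(1, 1),
                               c(0.5, 0.5)), "strictly increasing")
  expect_error(analysis_events(1, "final2", 1, 0.5), "interim")
  expect_error(analysis_events(c(1, 1), c("interim", "interim"), 1:2,
                               c(0.5, 0.5)), "duplicated")
  expect_error(analysis_events(c(1, 1), c("final", "interim"), 1:2,
                               c(0.5, 0.5)), "precedes")
  s <- equal_sequence(0.05, 3)
  # final after an interim rejection is a sequencing error in strict mode
  ev <- analysis_events(c(1, 1), c("interim", "final"), 1:2, c(1e-8, 0.5))
  expect_error(run_schedule(ev, s, "PO", "gsLOND"), "rejected_interim")
  # final without interim
  ev2 <- analysis_events(1, "final", 1, 0.5)
  expect_error(run_schedule(ev2, s, "PO", "gsLOND"), "without interim")
})
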