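test_that("the simulator's p-values agree with stats::t.test", {
  sc <- sim_scenario(K = 3, n_reps = 1, seed = 1, controls = "CC")
  set.seed(2)
  tr <- generate_trial(sc, keep_data = TRUE)
  for (i in 1:3) {
    s <- (i - 1) * sc$n_delta
    y1 <- tr$controls[(s + 1):(s + sc$n1)]
    ref <- t.test(tr$treatment[1:sc$n1, i], y1, alternative = "greater",
                  var.equal = TRUE)$p.value
    expect_equal(tr$p_interim[i], ref, tolerance = 1e-12)
    yf <- tr$controls[(s + 1):(s + sc$n)]
    reff <- t.test(tr$treatment[, i], yf, alternative = "greater",
                   var.equal = TRUE)$p.value
    expect_equal(tr$p_final[i], reff, tolerance = 1e-12)
  }
})

test_that("event chronology follows the control-index clock with index tie-breaks", {
  sc <- sim_scenario(K = 4, n_reps = 1, seed = 1)
  set.seed(1)
  tr <- generate_trial(sc)
  ev <- tr$events
  expect_equal(ev$time, seq_len(nrow(ev)))
  expect_true(!is.unsorted(ev$info_time))
  # arm i: interim at (i-1)*20 + 25, final at (i-1)*20 + 50
  for (i in 1:4) {
    expect_equal(ev$info_time[ev$hypothesis == i & ev$stage == "interim"],
                 (i - 1) * 20 + 25)
    expect_equal(ev$info_time[ev$hypothesis == i & ev$stage == "final"],
                 (i - 1) * 20 + 50)
  }
  # ties on info_time resolved by arm index
  ties <- split(ev$hypothesis, ev$info_time)
  for (g in ties) expect_true(!is.unsorted(g))
})

test_that("null p-values are uniform and interim/final statistics correlate as sqrt(t1)", {
  sc <- sim_scenario(K = 5, pi0 = 1, n_reps = 1, seed = 1, controls = "CC")
  p1 <- pf <- NULL
  set.seed(31)
  for (r in 1:2000) {
    tr <- generate_trial(sc)
    p1 <- c(p1, tr$p_interim); pf <- c(pf, tr$p_final)
  }
  expect_gt(ks.test(p1, "punif")$p.value, 0.01)
  expect_gt(ks.test(pf, "punif")$p.value, 0.01)
  co <- cor(qnorm(1 - p1), qnorm(1 - pf))
  expect_lt(abs(co - sqrt(0.5)), 0.02)
})

test_that("treatment observations are shared between CC and NCC+CC runs", {
  sc_cc <- sim_scenario(K = 4, n_reps = 1, seed = 9, controls = "CC")
  sc_ncc <- sim_scenario(K = 4, n_reps = 1, seed = 9, controls = "NCC_CC")
  set.seed(10); a <- generate_trial(sc_cc, keep_data = TRUE)
  set.seed(10); b <- generate_trial(sc_ncc, keep_data = TRUE)
  expect_identical(a$treatment, b$treatment)
  expect_identical(a$controls, b$controls)
  # arm 1 has no earlier controls: its p-values coincide
  expect_equal(a$p_interim[1], b$p_interim[1])
  expect_equal(a$p_final[1], b$p_final[1])
  # later arms gain controls under NCC+CC
  expect_false(isTRUE(all.equal(a$p_interim[3], b$p_interim[3])))
})

test_that("deterministic alternative orderings place the blocks correctly", {
  sc <- sim_scenario(K = 10, pi0 = 0.8, order = "alternatives_first",
                     n_reps = 1, seed = 1)
  tr <- sim_truth(gslond:::sim_scenario(K = 10, pi0 = 0.8,
                                        order = "alternatives_first"))
  expect_equal(tr$alt, c(rep(TRUE, 2), rep(FALSE, 8)))
  tr2 <- sim_truth(gslond:::sim_scenario(K = 10, pi0 = 0.8,
                                         order = "alternatives_last"))
  expect_equal(tr2$alt, c(rep(FALSE, 8), rep(TRUE, 2)))
})

test_that("replicate runs aggregate FDR, power and saved sample size", {
  sc <- sim_scenario(K = 5, N = 20, pi0 = 0.4, n_reps = 60, seed = 21)
  res <- run_replicates(sc)
  s <- res$summary
  expect_equal(s$metric, c("fdr", "power", "saved_pct"))
  expect_true(all(s$value[1] >= 0 & s$value[1] <= 1))
  expect_true(s$value[2] >= 0 && s$value[2] <= 1)
  expect_true(s$value[3] >= 0 && s$value[3] <= 100)
  expect_equal(length(res$ledgers), 60)
  # reproducibility: identical seed, identical output
  res2 <- run_replicates(sc)
  expect_identical(res$summary, res2$summary)
})

test_that("the fixed-sample comparator saves nothing and rejects a subset", {
  sc_gs <- sim_scenario(K = 5, N = 20, pi0 = 0.5, n_reps = 40, seed = 3)
  sc_fx <- sim_scenario(K = 5, N = 20, pi0 = 0.5, n_reps = 40, seed = 3,
                        variant = "LOND")
  res_fx <- run_replicates(sc_fx)
  expect_equal(res_fx$summary$value[res_fx$summary$metric == "saved_pct"], 0)
  expect_error(saved_sample_size(res_fx), "not applicable")
  expect_gt(saved_sample_size(run_replicates(sc_gs)), 0)
})

test_that("budget mode conserves the treatment budget and replaces arms", {
  sc <- sim_scenario(K = 6, N = 50, pi0 = 0.5, delta = 0.8, n_reps = 40,
                     seed = 17, budget_mode = 1)
  res <- run_budget_mode(sc)
  for (l in res$ledgers) {
    consumed <- nrow(l) * sc$n - sum(l$stopped_interim) * sc$n2
    expect_lte(consumed, sc$K * sc$n)
  }
  arms <- res$summary$value[res$summary$metric == "arms_opened"]
  expect_gte(arms, sc$K)  # replacement can only add arms
  # the fixed-sample design never stops early, so never adds arms
  sc_fx <- sim_scenario(K = 6, N = 50, pi0 = 0.5, delta = 0.8, n_reps = 10,
                        seed = 17, budget_mode = 1, variant = "LOND")
  res_fx <- run_budget_mode(sc_fx)
  expect_equal(res_fx$summary$value[res_fx$summary$metric == "arms_opened"],
               sc_fx$K)
  expect_error(run_budget_mode(sim_scenario(K = 3, n_reps = 2)),
               "budget_mode")
})

test_that("budget scenario 3 floors the null probability at zero", {
  sc <- sim_scenario(K = 4, pi0 = 0.02, budget_mode = 3, n_reps = 1, seed = 1)
  set.seed(1)
  draws <- replicate(200, gslond:::budget_truth(sc, m = 5)$alt)
  expect_true(all(draws))  # pi0 - 5/80 < 0, clamped: always alternative
})
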