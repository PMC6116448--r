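quiet_fit <- function(net, cfg) suppressWarnings(fit_nma(net, cfg))

test_that("swap_trial replaces in place, reversibly, without side effects", {
  net <- chain_net()
  original <- net$arms[net$arms$study_id == "BC", ]
  sim <- make_arms("BC", c("B", "C"), c(10L, 9L), 40, n_subjects = 40L)
  swapped <- swap_trial(net, "BC", sim)
  expect_equal(swapped$arms$relapses[swapped$arms$study_id == "BC"],
               c(10L, 9L))
  expect_identical(net, chain_net())          # input unmodified
  restored <- swap_trial(swapped, "BC", original)
  expect_equal(restored, net)
  # no-op swap returns an identical network
  expect_equal(swap_trial(net, "BC", original), net)
  expect_error(swap_trial(net, "nope", sim), "not in the network")
})

test_that("no-op substitution reproduces the posterior exactly", {
  net <- chain_net()
  cfg <- nma_config(chains = 2L, burn_in = 300L, draws = 400L, seed = 5L)
  p1 <- quiet_fit(net, cfg)
  net2 <- swap_trial(net, "BC", net$arms[net$arms$study_id == "BC", ])
  p2 <- quiet_fit(net2, cfg)
  expect_identical(p1$draws, p2$draws)
})

test_that("shrinking a study widens the posterior without moving the point", {
  truth <- generator_truth(seed = 19)
  net <- generate_network(truth)$network
  cfg <- nma_config(seed = 23L)
  p_big <- quiet_fit(net, cfg)
  # replace one large study with a quarter-size simulated one of equal truth
  des <- trial_design(arm_labels = c("Placebo", "DrugB"), n_per_arm = 50L,
                      follow_up = 2, seed = 101L)
  sc <- truth_scenario(0.55, truth$d_true[["DrugB"]], dispersion = 1)
  sim <- simulated_study("SYN01", des, sc)
  p_small <- quiet_fit(swap_trial(net, "SYN01", sim), cfg)
  dg_big <- p_big$diagnostics
  dg_small <- p_small$diagnostics
  sd_big <- dg_big$sd[dg_big$parameter == "d[DrugB]"]
  sd_small <- dg_small$sd[dg_small$parameter == "d[DrugB]"]
  expect_gt(sd_small, sd_big)
  joint_sd <- sqrt(sd_big^2 + sd_small^2)
  expect_lt(abs(dg_small$mean[dg_small$parameter == "d[DrugB]"] -
                dg_big$mean[dg_big$parameter == "d[DrugB]"]), 2 * joint_sd)
})

test_that("compare_nma: identity, antisymmetry, and refusal on mismatch", {
  net <- chain_net()
  p1 <- quiet_fit(net, nma_config(chains = 2L, burn_in = 400L, draws = 600L,
                                  seed = 5L))
  self <- compare_nma(p1, p1)
  expect_true(all(self$contrasts$ratio_of_ratios == 1))
  expect_true(all(self$contrasts$spread_delta == 0))
  expect_equal(self$rank_agreement, 1)
  # two seeds on identical, well-identified data agree within joint MC error
  gnet <- generate_network(generator_truth(seed = 6))$network
  g1 <- quiet_fit(gnet, nma_config(seed = 5L))
  g2 <- quiet_fit(gnet, nma_config(seed = 6L))
  cmp <- compare_nma(g1, g2)
  expect_true(all(abs(log(cmp$contrasts$ratio_of_ratios)) < 0.1))
  expect_gt(cmp$rank_agreement, 0.95)
  # antisymmetry of the ratio-of-ratios
  p2 <- quiet_fit(net, nma_config(chains = 2L, burn_in = 400L, draws = 600L,
                                  seed = 6L))
  rev <- compare_nma(p2, p1)
  cmp <- compare_nma(p1, p2)
  key <- paste(cmp$contrasts$treatment_a, cmp$contrasts$treatment_b)
  key_rev <- paste(rev$contrasts$treatment_a, rev$contrasts$treatment_b)
  expect_equal(cmp$contrasts$ratio_of_ratios,
               1 / rev$contrasts$ratio_of_ratios[match(key, key_rev)])
  # mismatched treatment sets are refused with the difference listed
  px <- quiet_fit(symmetric_net(), nma_config(chains = 2L, burn_in = 200L,
                                              draws = 200L, seed = 1L))
  expect_error(compare_nma(p1, px), "only in a")
})

test_that("timeline projection arithmetic and linearity", {
  expect_equal(projected_months(568, recruitment_assumptions(100)), 5.68)
  originals <- data.frame(trial = c("T1", "T2"), n_total = c(840, 840),
                          months_observed = c(8.4, 8.4))
  tl <- project_timeline(c(840, 568), originals)
  expect_equal(tl$months_saved, c(0, 2.72))
  expect_equal(attr(tl, "total_months_saved"), 2.72)
  # savings linear in n_total at fixed rate
  tl2 <- project_timeline(c(840 - 100, 840 - 200), originals)
  expect_equal(tl2$months_saved[2L], 2 * tl2$months_saved[1L])
  expect_error(project_timeline(c(1, 1), transform(originals,
                                                   months_observed = 0)),
               "positive")
})

test_that("run_milestone plans the next trial end to end", {
  net <- generate_network(generator_truth(seed = 3))$network
  cfg <- nma_config(chains = 2L, burn_in = 1000L, draws = 2000L, seed = 7L)
  recruit <- recruitment_assumptions(100)
  des_strong <- trial_design(arm_labels = c("Placebo", "DrugB"),
                             follow_up = 2, replicates = 300L, seed = 11L)
  plan <- suppressWarnings(
    run_milestone(net, cfg, des_strong, recruit, n_lo = 50L, n_hi = 400L,
                  coarse_step = 50L, stage_label = "after phase II"))
  expect_s3_class(plan, "milestone_plan")
  expect_true(plan$attained)
  expect_equal(plan$n_total, 2L * plan$recommended_n_per_arm)
  expect_equal(plan$projected_recruitment_months, plan$n_total / 100)
  # a weak-effect comparison needs more patients under identical settings
  des_weak <- trial_design(arm_labels = c("Placebo", "DrugD"),
                           follow_up = 2, replicates = 300L, seed = 11L)
  plan_weak <- suppressWarnings(
    run_milestone(net, cfg, des_weak, recruit, n_lo = 50L, n_hi = 400L,
                  coarse_step = 50L))
  expect_gt(plan_weak$recommended_n_per_arm + (!plan_weak$attained) * 1000L,
            plan$recommended_n_per_arm)
  # absent comparison refused by name
  des_bad <- trial_design(arm_labels = c("Placebo", "DrugZ"))
  expect_error(run_milestone(net, cfg, des_bad, recruit), "DrugZ")
})
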