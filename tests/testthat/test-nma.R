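# sampler fits in these tests are intentionally small; convergence warnings
# about borderline effective sample sizes are not the behaviour under test
quiet_fit <- function(net, cfg) suppressWarnings(fit_nma(net, cfg))

test_that("no-effect symmetry: identical arms give a rate ratio near 1", {
  post <- quiet_fit(symmetric_net(), nma_config(seed = 3))
  rr <- exp(contrast_draws(post, "B", "A"))
  expect_lt(abs(median(rr) - 1), 3 * sd(rr) / sqrt(400))  # well inside MC error
  expect_lt(abs(median(rr) - 1), 0.1)
})

test_that("Poisson-limit single study matches the closed-form MLE", {
  arms <- make_arms("S1", c("A", "B"), c(300L, 210L), 300)
  net <- evidence_network(arms, reference = "A")
  post <- quiet_fit(net, nma_config(effects_mode = "fixed",
                                    kappa_fixed = 1e7, seed = 4))
  cd <- contrast_draws(post, "B", "A")
  expect_lt(abs(median(cd) - log(210 / 300)), 2 * sd(cd))
})

test_that("the fit recovers generating truth on the default synthetic world", {
  gen <- generate_network(generator_truth(seed = 7))
  post <- quiet_fit(gen$network, nma_config(seed = 11))
  dg <- post$diagnostics
  dd <- dg[match(sprintf("d[%s]", names(gen$truth$d_true)), dg$parameter), ]
  expect_true(all(abs(dd$mean - gen$truth$d_true) <= 3 * dd$sd))
  expect_true(all(dg$rhat < 1.05, na.rm = TRUE))
})

test_that("evidence is pooled at face value: source tags never reach the likelihood", {
  arms <- symmetric_net()$arms
  arms$source <- c("RWE", "RWE", "RCT", "RCT")
  p1 <- quiet_fit(evidence_network(arms, reference = "A"), nma_config(seed = 9))
  arms$source <- "RCT"
  p2 <- quiet_fit(evidence_network(arms, reference = "A"), nma_config(seed = 9))
  expect_identical(p1$draws, p2$draws)
})

test_that("identical config + data + seed reproduce draws bit-identically", {
  net <- symmetric_net()
  cfg <- nma_config(chains = 2L, burn_in = 200L, draws = 300L, seed = 21L)
  expect_identical(quiet_fit(net, cfg)$draws, quiet_fit(net, cfg)$draws)
})

test_that("disconnected networks are refused at fit time, naming components", {
  arms <- rbind(chain_net()$arms,
                make_arms("XY", c("X", "Y"), c(5L, 6L), 50))
  net <- evidence_network(arms, reference = "A")
  expect_error(fit_nma(net, nma_config()), "X, Y")
})

test_that("rate-ratio matrices are exactly consistent and reciprocal per draw", {
  post <- quiet_fit(chain_net(), nma_config(chains = 2L, burn_in = 500L,
                                            draws = 500L, seed = 2L))
  # reciprocity: contrast draws are exact negations
  ab <- contrast_draws(post, "A", "B")
  ba <- contrast_draws(post, "B", "A")
  expect_identical(ab, -ba)
  # per-draw loop consistency
  ac <- contrast_draws(post, "A", "C")
  bc <- contrast_draws(post, "B", "C")
  expect_equal(ac, ab + bc)
  mat <- rate_ratio_matrix(post)
  expect_identical(unname(diag(mat$point)), rep(1, 4))
  expect_identical(unname(diag(mat$spread)), rep(0, 4))
  # mean vs median summaries both work
  expect_s3_class(rate_ratio_matrix(post, "mean"), "rate_ratio_matrix")
  expect_error(contrast_draws(post, "A", "nope"), "unknown treatment")
  # a well-identified posterior summarised per draw has no flaggable
  # triangles: medians of jointly near-normal contrasts are near-additive
  gen <- generate_network(generator_truth(seed = 7))
  post_g <- quiet_fit(gen$network, nma_config(seed = 11))
  checks <- consistency_check(rate_ratio_matrix(post_g), tolerance = 0.05)
  expect_false(any(checks$flagged))
})

test_that("predictive effects add fresh between-study variation", {
  # fixed effects: predictive draws equal the posterior contrast draws
  post_f <- fake_posterior(matrix(rnorm(2000, -0.5, 0.1)), sigma = 0,
                           treatments = c("A", "B"), effects_mode = "fixed")
  expect_identical(predictive_effect(post_f, "B", "A"),
                   contrast_draws(post_f, "B", "A"))
  # random effects: predictive variance is at least the contrast variance
  post_r <- fake_posterior(matrix(rnorm(4000, -0.5, 0.1)), sigma = 0.3,
                           treatments = c("A", "B"))
  set.seed(1)
  pe <- predictive_effect(post_r, "B", "A")
  expect_gt(var(pe), var(contrast_draws(post_r, "B", "A")))
  # degenerate posterior: constant d = log(0.5), constant sigma = 0.1
  post_c <- fake_posterior(matrix(log(0.5), nrow = 1e4), sigma = 0.1,
                           treatments = c("A", "B"))
  set.seed(2)
  pe <- predictive_effect(post_c, "B", "A")
  expect_lt(abs(mean(pe) - log(0.5)), 0.005)
  expect_lt(abs(sd(pe) - 0.1) / 0.1, 0.05)
})

test_that("rankings: dominance, symmetry, and rows summing to one", {
  # B beats the reference in every draw -> rank 1 with probability 1
  post <- fake_posterior(cbind(rnorm(500, -2, 0.05), rnorm(500, -0.5, 0.05)),
                         treatments = c("ref", "B", "C"))
  rk <- rank_treatments(post, lower_is_better = TRUE)
  expect_equal(unname(rk$prob["B", "rank1"]), 1)
  expect_equal(unname(rowSums(rk$prob)), rep(1, 3))
  expect_equal(sum(rk$p_best), 1)
  # two exchangeable treatments split rank 1 evenly (label symmetry)
  post2 <- quiet_fit(symmetric_net(), nma_config(seed = 3))
  rk2 <- rank_treatments(post2)
  expect_lt(abs(rk2$prob["B", "rank1"] - 0.5), 0.08)
  # direction flag flips the ordering
  rk_hi <- rank_treatments(post, lower_is_better = FALSE)
  expect_equal(unname(rk_hi$prob["B", "rank3"]), 1)
})

test_that("consistency_check flags inflated triangles and rejects bad shapes", {
  m <- matrix(c(1, 0.5, 0.25,
                2, 1, 0.5,
                4, 2, 1), 3L, 3L, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_false(any(consistency_check(m, 0.01)$flagged))
  m2 <- m; m2["A", "C"] <- m2["A", "C"] + 0.05
  chk <- consistency_check(m2, 0.01)
  expect_true(chk$flagged[chk$a == "A" & chk$c == "C"])
  expect_error(consistency_check(matrix(1, 2, 3)), "square")
  expect_error(consistency_check(matrix(2, 2, 2)), "diagonal")
})

test_that("posterior artefacts are written as delimited text", {
  post <- quiet_fit(symmetric_net(), nma_config(chains = 2L, burn_in = 200L,
                                                draws = 200L, seed = 5L))
  p1 <- write_posterior_summary(post, tempfile(fileext = ".csv"))
  expect_true(all(c("parameter", "median", "rhat", "ess") %in%
                  names(read.csv(p1))))
  p2 <- write_contrast_draws(post, tempfile(fileext = ".csv"))
  dr <- read.csv(p2, check.names = FALSE)
  expect_equal(nrow(dr), nrow(post$draws))
  expect_true("sigma" %in% names(dr))
  p3 <- write_rate_ratio_matrix(rate_ratio_matrix(post),
                                tempfile(fileext = ".csv"))
  expect_equal(unname(as.matrix(read.csv(p3, row.names = 1))),
               unname(rate_ratio_matrix(post)$point))
})
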