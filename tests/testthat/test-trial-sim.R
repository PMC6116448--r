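test_that("simulate_counts has the stated negative binomial moments", {
  d <- trial_design(n_per_arm = 1e5L, follow_up = 2)
  set.seed(10)
  # Poisson limit: variance approaches the mean
  cnt <- simulate_counts(d, truth_scenario(0.5, 0, dispersion = 1e8))
  expect_lt(abs(mean(cnt$control) - 1.0), 0.02)
  expect_lt(abs(var(cnt$control) / mean(cnt$control) - 1), 0.02)
  # dispersion 1: variance = mean + mean^2 = 2 at mean 1
  cnt <- simulate_counts(d, truth_scenario(0.5, 0, dispersion = 1))
  expect_lt(abs(var(cnt$control) - 2) / 2, 0.03)
  # null symmetry
  expect_lt(abs(mean(cnt$control) - mean(cnt$experimental)), 0.03)
  # non-null effect scales the experimental mean
  cnt <- simulate_counts(d, truth_scenario(0.5, log(0.6), dispersion = 1))
  expect_lt(abs(mean(cnt$experimental) / mean(cnt$control) - 0.6), 0.03)
})

test_that("analyze_trial agrees with two independent oracles", {
  set.seed(77)
  scenarios <- list(list(n = 60L, mu = c(0.9, 0.5), size = 0.8, fu = 1),
                    list(n = 150L, mu = c(1.2, 1.1), size = 2.0, fu = 2),
                    list(n = 40L, mu = c(2.0, 0.9), size = 1.0, fu = 0.5))
  for (sc in scenarios) {
    y_c <- rnbinom(sc$n, size = sc$size, mu = sc$mu[1L])
    y_e <- rnbinom(sc$n, size = sc$size, mu = sc$mu[2L])
    res <- analyze_trial(list(control = y_c, experimental = y_e),
                         follow_up = sc$fu)
    # oracle 1: IRLS + theta-ML route of MASS::glm.nb
    df <- data.frame(y = c(y_c, y_e), trt = rep(0:1, each = sc$n))
    gm <- MASS::glm.nb(y ~ trt + offset(rep(log(sc$fu), 2 * sc$n)), data = df)
    expect_equal(res$log_rate_ratio_hat, unname(coef(gm)[2L]),
                 tolerance = 1e-5)
    expect_equal(res$standard_error, unname(sqrt(diag(vcov(gm)))[2L]),
                 tolerance = 1e-4)
    expect_equal(res$kappa_hat, gm$theta, tolerance = 1e-3)
    # oracle 2: brute-force maximisation of the joint NB log-likelihood
    nll <- function(par) {
      mu <- exp(c(par[1L], par[1L] + par[2L]) + log(sc$fu))
      -sum(dnbinom(y_c, size = exp(par[3L]), mu = mu[1L], log = TRUE)) -
        sum(dnbinom(y_e, size = exp(par[3L]), mu = mu[2L], log = TRUE))
    }
    opt <- optim(c(0, 0, 0), nll, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    expect_equal(res$log_rate_ratio_hat, opt$par[2L], tolerance = 1e-3)
    expect_equal(res$kappa_hat, exp(opt$par[3L]), tolerance = 1e-2)
  }
})

test_that("analyze_trial handles identical and degenerate arms", {
  y <- c(rep(2L, 30L), rep(0L, 20L))
  res <- analyze_trial(list(control = y, experimental = y))
  expect_equal(res$log_rate_ratio_hat, 0)
  expect_false(res$rejected)
  expect_equal(unname(res$arr), c(mean(y), mean(y)))
  # Poisson-limit closed form, exact by saturation
  y_c <- rpois(100L, 1.2); y_e <- rpois(100L, 0.8)
  res <- analyze_trial(list(control = y_c, experimental = y_e), follow_up = 2)
  expect_equal(round(res$log_rate_ratio_hat, 4),
               round(log(sum(y_e) / sum(y_c)), 4))
  # refusals and flags
  z <- rep(0L, 10L)
  expect_error(analyze_trial(list(control = z, experimental = z)),
               "inestimable")
  one_sided <- analyze_trial(list(control = z, experimental = c(1L, z)))
  expect_false(one_sided$converged)
  expect_error(analyze_trial(list(control = integer(0), experimental = z)),
               "non-empty")
})

test_that("likelihood-ratio test switch behaves like the Wald test", {
  set.seed(5)
  y_c <- rnbinom(150L, size = 1, mu = 1.0)
  y_e <- rnbinom(150L, size = 1, mu = 0.55)
  w <- analyze_trial(list(control = y_c, experimental = y_e), test = "wald")
  l <- analyze_trial(list(control = y_c, experimental = y_e), test = "lrt")
  expect_equal(l$log_rate_ratio_hat, w$log_rate_ratio_hat)
  expect_gt(l$p_value, 0); expect_lt(l$p_value, 1)
  expect_lt(abs(log(l$p_value / w$p_value)), 1)  # same order of magnitude
})

test_that("estimate_power is deterministic and calibrated", {
  des <- trial_design(n_per_arm = 200L, replicates = 2000L, seed = 42L)
  null_truth <- truth_scenario(0.5, 0, dispersion = 1)
  p1 <- estimate_power(des, null_truth)
  p2 <- estimate_power(des, null_truth)
  expect_identical(p1, p2)
  se <- sqrt(0.05 * 0.95 / 2000L)
  expect_lt(abs(p1$rejected_fraction - 0.05), 3 * se)
  expect_true(p1$ci[1L] <= p1$rejected_fraction &&
              p1$rejected_fraction <= p1$ci[2L])
  # overwhelming effect
  big <- truth_scenario(0.5, -1.5, dispersion = 1)
  expect_gt(estimate_power(trial_design(n_per_arm = 200L, replicates = 300L,
                                        seed = 1L), big)$rejected_fraction,
            0.99)
  # direction argument only counts correctly-signed rejections
  pdir <- estimate_power(des, null_truth, direction = "less")
  expect_lt(pdir$rejected_fraction, p1$rejected_fraction + 1e-12)
})

test_that("excluded replicates are counted and capped loudly", {
  # almost every replicate yields all-zero arms at this tiny rate
  des <- trial_design(n_per_arm = 3L, replicates = 200L, seed = 7L)
  expect_error(estimate_power(des, truth_scenario(0.001, 0, dispersion = 1)),
               "excluded")
})

test_that("power_curve uses independent sub-streams and smooths isotonic", {
  des <- trial_design(replicates = 400L, seed = 31L)
  truth <- truth_scenario(0.5, log(0.6), dispersion = 1)
  pc <- power_curve(des, truth, c(50L, 100L, 200L, 400L))
  expect_identical(pc$table$smoothed, cummax(pc$table$smoothed))
  expect_gt(pc$table$smoothed[4L], pc$table$smoothed[1L])
  expect_error(power_curve(des, truth, c(100L, 50L)))
  # determinism across calls
  pc2 <- power_curve(des, truth, c(50L, 100L, 200L, 400L))
  expect_identical(pc$table, pc2$table)
})

test_that("find_sample_size honours the normal-approximation upper bound", {
  # analytic n* for 95% power; the search targets 90%, so n <= n*
  arr <- 0.5; fu <- 2; rr <- 0.6; kappa <- 1
  mu_c <- arr * fu; mu_e <- mu_c * rr
  w <- function(m) m / (1 + m / kappa)
  n_star <- ceiling((qnorm(0.975) + qnorm(0.95))^2 *
                    (1 / w(mu_c) + 1 / w(mu_e)) / log(rr)^2)
  des <- trial_design(follow_up = fu, target_power = 0.90,
                      replicates = 600L, seed = 13L)
  truth <- truth_scenario(arr, log(rr), dispersion = kappa)
  res <- find_sample_size(des, truth, n_lo = 50L, n_hi = 400L)
  expect_true(res$attained)
  expect_lte(res$n, n_star)
  expect_gte(res$n, 50L)
})

test_that("an unreachable target reports its boundary, not a number", {
  des <- trial_design(replicates = 200L, seed = 3L)
  null_truth <- truth_scenario(0.5, 0, dispersion = 1)
  expect_message(res <- find_sample_size(des, null_truth, 50L, 150L,
                                         coarse_step = 50L),
                 "unattained")
  expect_false(res$attained)
  expect_equal(res$n, 150L)
})

test_that("probability_of_replication reduces to the power machinery", {
  des <- trial_design(n_per_arm = 150L, replicates = 1500L, seed = 9L)
  p0 <- probability_of_replication(des, control_arr = 0.5, log_rate_ratio = 0)
  se <- sqrt(0.05 * 0.95 / 1500L)
  expect_lt(abs(p0$rejected_fraction - 0.05), 4 * se)
  # with reported uncertainty the effect is redrawn per replicate
  pu <- probability_of_replication(des, control_arr = 0.5,
                                   log_rate_ratio = log(0.6), se = 0.1)
  expect_gt(pu$rejected_fraction, 0.5)
  expect_identical(pu, probability_of_replication(des, control_arr = 0.5,
                                                  log_rate_ratio = log(0.6),
                                                  se = 0.1))
})

test_that("assurance power never exceeds plug-in power by more than MC noise
           for symmetric effect draws around the median", {
  set.seed(8)
  draws <- rnorm(3000L, log(0.6), 0.15)
  truth <- truth_scenario(0.5, dispersion = 1, effect_draws = draws)
  des <- trial_design(n_per_arm = 250L, replicates = 1200L, seed = 17L,
                      follow_up = 2)
  plug <- estimate_power(des, truth, effect_mode = "plugin")
  assur <- estimate_power(des, truth, effect_mode = "assurance")
  expect_lt(assur$rejected_fraction,
            plug$rejected_fraction + 3 * sqrt(0.2 * 0.8 / 1200L))
})
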