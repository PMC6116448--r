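#' Specify a simulated two-arm trial
#'
#' @param arm_labels length-2 character vector `c(control, experimental)`.
#' @param n_per_arm patients per arm.
#' @param follow_up years of follow-up per patient (person-years of exposure
#'   per patient); default 1.
#' @param alpha two-sided significance level, default 0.05.
#' @param target_power default 0.90.
#' @param replicates Monte-Carlo replicates per power estimate, default 1000.
#' @param seed integer; together with the design and truth it fully
#'   determines every simulation output.
#' @param test `"wald"` (default) or `"lrt"` for the per-replicate analysis.
#' @return a `trial_design` object.
#' @export
trial_design <- function(arm_labels = c("control", "experimental"),
                         n_per_arm = 100L, follow_up = 1, alpha = 0.05,
                         target_power = 0.90, replicates = 1000L,
                         seed = 1L, test = c("wald", "lrt")) {
  test <- match.arg(test)
  stopifnot(length(arm_labels) == 2L, n_per_arm >= 1L, follow_up > 0,
            alpha > 0, alpha < 1, target_power > 0, target_power < 1,
            replicates >= 1L)
  structure(list(arm_labels = as.character(arm_labels),
                 n_per_arm = as.integer(n_per_arm), follow_up = follow_up,
                 alpha = alpha, target_power = target_power,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), test = test),
            class = "trial_design")
}

#' Specify the true state of nature for trial simulation
#'
#' @param control_arr true annualised relapse rate in the control arm
#'   (relapses per person-year). The packaged default 0.5 (and dispersion 1)
#'   are test defaults, not values estimated from any trial.
#' @param log_rate_ratio true log rate ratio, experimental vs control
#'   (negative favours the experimental arm). May be `NULL` when
#'   `effect_draws` is supplied.
#' @param dispersion per-patient negative binomial overdispersion `kappa`
#'   (`Var = mu + mu^2 / kappa`).
#' @param effect_draws optional collection of per-draw log rate ratios (e.g.
#'   from [predictive_effect()]); used as the effect distribution instead of
#'   a fixed value.
#' @return a `truth_scenario` object.
#' @export
truth_scenario <- function(control_arr = 0.5, log_rate_ratio = NULL,
                           dispersion = 1, effect_draws = NULL) {
  stopifnot(control_arr > 0, dispersion > 0)
  if (is.null(log_rate_ratio) && is.null(effect_draws)) {
    stop("supply log_rate_ratio and/or effect_draws", call. = FALSE)
  }
  structure(list(control_arr = control_arr,
                 log_rate_ratio = log_rate_ratio,
                 dispersion = dispersion, effect_draws = effect_draws),
            class = "truth_scenario")
}

truth_effect <- function(truth, mode = c("plugin", "assurance")) {
  mode <- match.arg(mode)
  if (mode == "plugin") {
    if (!is.null(truth$log_rate_ratio)) return(function() truth$log_rate_ratio)
    med <- median(truth$effect_draws)
    return(function() med)
  }
  if (is.null(truth$effect_draws)) {
    stop("assurance mode needs effect_draws in the truth scenario",
         call. = FALSE)
  }
  function() truth$effect_draws[sample.int(length(truth$effect_draws), 1L)]
}

#' Simulate per-patient relapse counts for one trial
#'
#' Each patient's count is drawn from the negative binomial with mean
#' `arm ARR x follow_up` and per-patient overdispersion `truth$dispersion`;
#' the experimental arm's ARR is `control_arr * exp(log_rate_ratio)`. Draws
#' consume the caller's RNG stream (wrap in `set.seed()` to reproduce).
#'
#' @param design a [trial_design()].
#' @param truth a [truth_scenario()] (plug-in effect used).
#' @param log_rate_ratio optional effect override for this trial.
#' @return list with integer vectors `control` and `experimental` and the
#'   `follow_up` used.
#' @export
simulate_counts <- function(design, truth, log_rate_ratio = NULL) {
  stopifnot(inherits(design, "trial_design"), inherits(truth, "truth_scenario"))
  eff <- if (is.null(log_rate_ratio)) truth_effect(truth, "plugin")()
         else log_rate_ratio
  n <- design$n_per_arm
  mu_c <- truth$control_arr * design$follow_up
  mu_e <- mu_c * exp(eff)
  list(control = stats::rnbinom(n, size = truth$dispersion, mu = mu_c),
       experimental = stats::rnbinom(n, size = truth$dispersion, mu = mu_e),
       follow_up = design$follow_up)
}

# Profile log-likelihood of the dispersion for the saturated two-group model,
# using count frequency tables so cost is O(#distinct counts).
nb2_profile_ll <- function(log_kappa, tabs, mus, ns) {
  k <- exp(log_kappa)
  ll <- 0
  for (g in seq_along(tabs)) {
    v <- tabs[[g]]$value
    nv <- tabs[[g]]$freq
    mu <- mus[g]
    ll <- ll + sum(nv * (lgamma(v + k) - lgamma(k) - lgamma(v + 1))) +
      ns[g] * k * (log_kappa - log(k + mu)) +
      sum(nv * v) * (log(mu) - log(k + mu))
  }
  ll
}

count_tab <- function(y) {
  f <- tabulate(y + 1L)
  keep <- f > 0L
  list(value = (seq_along(f) - 1L)[keep], freq = f[keep])
}

#' Analyse one simulated trial with negative binomial regression
#'
#' Maximum-likelihood negative binomial regression of the per-patient counts
#' on a treatment indicator with a log follow-up offset:
#' `log E(y) = beta0 + treat * beta1 + log(follow_up)`. Because the two-group
#' model is saturated, the ML estimates of the group means are the sample
#' means for any dispersion, so `beta1` is the log ratio of observed ARRs
#' exactly; the common dispersion is profiled out by 1-D optimisation and the
#' Wald (default) or likelihood-ratio test of `beta1 = 0` is applied at
#' `alpha`. The Wald standard error comes from the expected information with
#' the dispersion fixed at its MLE, matching standard NB-regression output.
#'
#' @param counts list with integer vectors `control` and `experimental`
#'   (e.g. from [simulate_counts()]).
#' @param follow_up years of follow-up per patient; either a single value or
#'   length 2 `c(control, experimental)`.
#' @param alpha two-sided significance level.
#' @param test `"wald"` or `"lrt"`.
#' @return a `trial_result`: `log_rate_ratio_hat`, `standard_error`,
#'   `p_value`, `rejected`, `arr` (observed per-arm ARRs), `kappa_hat`,
#'   `converged`.
#' @export
analyze_trial <- function(counts, follow_up = 1, alpha = 0.05,
                          test = c("wald", "lrt")) {
  test <- match.arg(test)
  y_c <- counts$control
  y_e <- counts$experimental
  if (length(y_c) == 0L || length(y_e) == 0L) {
    stop("both arms must be non-empty", call. = FALSE)
  }
  fu <- rep_len(follow_up, 2L)
  if (sum(y_c) == 0L && sum(y_e) == 0L) {
    stop("inestimable effect: all counts are zero in both arms",
         call. = FALSE)
  }
  n <- c(length(y_c), length(y_e))
  mus <- c(mean(y_c), mean(y_e))
  arr <- mus / fu
  result <- function(est, se, p, kappa, converged) {
    structure(list(log_rate_ratio_hat = est, standard_error = se,
                   p_value = p, rejected = isTRUE(p < alpha),
                   arr = stats::setNames(arr, c("control", "experimental")),
                   kappa_hat = kappa, alpha = alpha, test = test,
                   converged = converged),
              class = "trial_result")
  }
  if (any(mus == 0)) {
    # one arm without events: the MLE of beta1 is infinite
    return(result(est = log(arr[2L] / arr[1L]), se = Inf, p = NA_real_,
                  kappa = NA_real_, converged = FALSE))
  }
  tabs <- list(count_tab(y_c), count_tab(y_e))
  opt <- optimize(nb2_profile_ll, interval = c(-8, 16), tabs = tabs,
                  mus = mus, ns = n, maximum = TRUE, tol = 1e-6)
  kappa <- exp(opt$maximum)
  beta1 <- log(arr[2L] / arr[1L])
  w <- mus / (1 + mus / kappa)
  se <- sqrt(sum(1 / (n * w)))
  if (test == "wald") {
    p <- 2 * stats::pnorm(-abs(beta1 / se))
  } else {
    mu0 <- sum(y_c) + sum(y_e)
    rate0 <- mu0 / (n[1L] * fu[1L] + n[2L] * fu[2L])
    mus0 <- rate0 * fu
    opt0 <- optimize(nb2_profile_ll, interval = c(-8, 16), tabs = tabs,
                     mus = mus0, ns = n, maximum = TRUE, tol = 1e-6)
    lr <- 2 * (opt$objective - opt0$objective)
    p <- stats::pchisq(max(lr, 0), df = 1L, lower.tail = FALSE)
  }
  result(est = beta1, se = se, p = p, kappa = kappa, converged = TRUE)
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("Trial analysis (%s test, alpha = %.3g)\n", x$test, x$alpha))
  cat(sprintf("  log rate ratio: %.4f (SE %.4f), p = %.4g -> %s\n",
              x$log_rate_ratio_hat, x$standard_error, x$p_value,
              if (isTRUE(x$rejected)) "rejected" else "not rejected"))
  cat(sprintf("  observed ARR: control %.4f, experimental %.4f; kappa %.3g\n",
              x$arr[1L], x$arr[2L], x$kappa_hat))
  if (!x$converged) cat("  NOTE: analysis did not converge\n")
  invisible(x)
}

#' Estimate power (or false-positive rate) by simulation
#'
#' Runs [simulate_counts()] + [analyze_trial()] for `design$replicates`
#' replicates of the design under the given truth and reports the fraction
#' of replicates rejecting the null at `design$alpha`, with a Clopper-Pearson
#' Monte-Carlo interval. With `direction` set, only rejections whose
#' estimated effect has the stated sign are counted. Replicates whose
#' analysis is refused or fails to converge are excluded from the tally and
#' counted; more than 1% exclusions aborts the run loudly. Output is a pure
#' function of (design, truth, seed).
#'
#' @param design a [trial_design()] (its `seed` drives the replicate stream).
#' @param truth a [truth_scenario()].
#' @param direction `NULL`, `"less"` (count rejections with negative
#'   estimated log rate ratio) or `"greater"`.
#' @param effect_mode `"plugin"` (fixed effect, or the median of
#'   `effect_draws`) or `"assurance"` (redraw the effect per replicate from
#'   `effect_draws`).
#' @return a `power_estimate`: `rejected_fraction`, `ci` (95% binomial),
#'   `n_rejected`, `n_used`, `n_excluded`.
#' @export
estimate_power <- function(design, truth, direction = NULL,
                           effect_mode = c("plugin", "assurance")) {
  effect_mode <- match.arg(effect_mode)
  stopifnot(inherits(design, "trial_design"), inherits(truth, "truth_scenario"))
  if (!is.null(direction)) direction <- match.arg(direction, c("less", "greater"))
  eff_fun <- truth_effect(truth, effect_mode)
  with_local_seed(design$seed, {
    rejected <- 0L
    excluded <- 0L
    for (r in seq_len(design$replicates)) {
      eff <- eff_fun()
      counts <- simulate_counts(design, truth, log_rate_ratio = eff)
      res <- tryCatch(analyze_trial(counts, design$follow_up, design$alpha,
                                    design$test),
                      error = function(e) NULL)
      if (is.null(res) || !res$converged) {
        excluded <- excluded + 1L
        next
      }
      hit <- res$rejected &&
        (is.null(direction) ||
         (direction == "less" && res$log_rate_ratio_hat < 0) ||
         (direction == "greater" && res$log_rate_ratio_hat > 0))
      if (hit) rejected <- rejected + 1L
    }
    used <- design$replicates - excluded
    if (excluded > 0.01 * design$replicates) {
      stop(sprintf(
        "%d of %d replicates excluded for inestimable/non-convergent analyses (cap 1%%)",
        excluded, design$replicates), call. = FALSE)
    }
    ci <- as.numeric(stats::binom.test(rejected, used)$conf.int)
    structure(list(rejected_fraction = rejected / used,
                   ci = ci, n_rejected = rejected, n_used = used,
                   n_excluded = excluded, alpha = design$alpha,
                   effect_mode = effect_mode),
              class = "power_estimate")
  })
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Rejection fraction %.4f (95%% MC interval %.4f-%.4f), %d/%d replicates",
              x$rejected_fraction, x$ci[1L], x$ci[2L], x$n_rejected, x$n_used))
  if (x$n_excluded > 0L) cat(sprintf(" [%d excluded]", x$n_excluded))
  cat("\n")
  invisible(x)
}

smooth_isotonic <- function(n, frac) {
  if (length(n) == 1L) return(frac)
  stats::isoreg(n, frac)$yf
}

#' Power curve over a grid of per-arm sample sizes
#'
#' [estimate_power()] at each grid point, each with an independent sub-stream
#' derived deterministically from `design$seed`. Raw rejection fractions are
#' Monte-Carlo noisy; the returned `smoothed` column applies isotonic
#' regression (power is non-decreasing in n for a fixed non-null effect).
#'
#' @inheritParams estimate_power
#' @param n_grid strictly increasing vector of per-arm sample sizes.
#' @return a `power_curve`: data.frame `table` (n, fraction, lo, hi,
#'   smoothed, n_excluded) plus the scenario.
#' @export
power_curve <- function(design, truth, n_grid, direction = NULL,
                        effect_mode = c("plugin", "assurance")) {
  effect_mode <- match.arg(effect_mode)
  stopifnot(all(diff(n_grid) > 0))
  sub_seeds <- with_local_seed(design$seed,
    sample.int(.Machine$integer.max, length(n_grid)))
  rows <- lapply(seq_along(n_grid), function(i) {
    d_i <- design
    d_i$n_per_arm <- as.integer(n_grid[i])
    d_i$seed <- sub_seeds[i]
    p <- estimate_power(d_i, truth, direction, effect_mode)
    data.frame(n = n_grid[i], fraction = p$rejected_fraction,
               lo = p$ci[1L], hi = p$ci[2L], n_excluded = p$n_excluded)
  })
  tab <- do.call(rbind, rows)
  tab$smoothed <- smooth_isotonic(tab$n, tab$fraction)
  structure(list(table = tab, truth = truth, design = design,
                 effect_mode = effect_mode),
            class = "power_curve")
}

#' @export
print.power_curve <- function(x, ...) {
  cat("Simulated power curve (per-arm n)\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Smallest per-arm sample size reaching the target power
#'
#' Grid search: a coarse pass (default step 25) over `[n_lo, n_hi]`, isotonic
#' smoothing, then a fine pass (default step 1) bracketing the first
#' crossing; all evaluated points are pooled, smoothed again, and the
#' smallest n whose smoothed power reaches `design$target_power` is returned
#' (ties broken toward the smaller n by construction). When no grid point
#' qualifies the boundary is reported with `attained = FALSE` — never an
#' arbitrary number.
#'
#' @inheritParams estimate_power
#' @param n_lo,n_hi per-arm search bounds, `n_lo < n_hi`.
#' @param coarse_step,fine_step grid steps for the two passes.
#' @return a `sample_size_result`: `n` (recommended per-arm size, or the
#'   upper boundary when unattained), `attained`, `power_at_n`, `ci`, and the
#'   full evaluation `table`.
#' @export
find_sample_size <- function(design, truth, n_lo, n_hi,
                             coarse_step = 25L, fine_step = 1L,
                             direction = NULL,
                             effect_mode = c("plugin", "assurance")) {
  effect_mode <- match.arg(effect_mode)
  stopifnot(n_lo >= 1L, n_lo < n_hi)
  coarse <- unique(c(seq(n_lo, n_hi, by = coarse_step), n_hi))
  pc <- power_curve(design, truth, coarse, direction, effect_mode)
  tab <- pc$table
  cross <- which(tab$smoothed >= design$target_power)
  if (length(cross) == 0L) {
    message(sprintf(
      "target power %.2f unattained on [%d, %d]; boundary power %.3f",
      design$target_power, n_lo, n_hi, tab$smoothed[nrow(tab)]))
    return(structure(list(n = n_hi, attained = FALSE,
                          power_at_n = tab$fraction[nrow(tab)],
                          ci = c(tab$lo[nrow(tab)], tab$hi[nrow(tab)]),
                          table = tab),
                     class = "sample_size_result"))
  }
  hi_idx <- cross[1L]
  fine_lo <- if (hi_idx == 1L) n_lo else tab$n[hi_idx - 1L] + fine_step
  fine_hi <- tab$n[hi_idx]
  fine <- setdiff(seq(fine_lo, fine_hi, by = fine_step), tab$n)
  if (length(fine) > 0L) {
    pf <- power_curve(design, truth, fine, direction, effect_mode)
    tab <- rbind(tab[, names(pf$table)], pf$table)
    tab <- tab[order(tab$n), , drop = FALSE]
  }
  tab$smoothed <- smooth_isotonic(tab$n, tab$fraction)
  sel <- which(tab$smoothed >= design$target_power)[1L]
  structure(list(n = tab$n[sel], attained = TRUE,
                 power_at_n = tab$fraction[sel],
                 ci = c(tab$lo[sel], tab$hi[sel]), table = tab),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  if (x$attained) {
    cat(sprintf("Smallest qualifying per-arm n: %d (power %.3f, MC interval %.3f-%.3f)\n",
                x$n, x$power_at_n, x$ci[1L], x$ci[2L]))
  } else {
    cat(sprintf("Target power unattained on the grid; boundary n = %d had power %.3f\n",
                x$n, x$power_at_n))
  }
  invisible(x)
}

#' Probability of replicating a reported trial result
#'
#' Uses the power-estimation machinery with the truth set from a published
#' effect: given a reported log rate ratio (optionally with a standard error,
#' in which case the effect is redrawn per replicate from the implied
#' normal), estimates the probability that a new trial of `n_per_arm`
#' patients per arm would reject at the design alpha.
#'
#' @param design a [trial_design()].
#' @param control_arr assumed control-arm ARR.
#' @param log_rate_ratio reported log rate ratio (experimental vs control).
#' @param se optional standard error of the reported log rate ratio.
#' @param dispersion assumed per-patient overdispersion.
#' @param n_per_arm per-arm size to evaluate; defaults to the design's.
#' @param direction passed to [estimate_power()].
#' @return a `power_estimate`.
#' @export
probability_of_replication <- function(design, control_arr, log_rate_ratio,
                                       se = NULL, dispersion = 1,
                                       n_per_arm = design$n_per_arm,
                                       direction = NULL) {
  design$n_per_arm <- as.integer(n_per_arm)
  if (is.null(se)) {
    truth <- truth_scenario(control_arr, log_rate_ratio, dispersion)
    return(estimate_power(design, truth, direction, "plugin"))
  }
  draws <- with_local_seed(design$seed + 1L,
    rnorm(4000L, log_rate_ratio, se))
  truth <- truth_scenario(control_arr, dispersion = dispersion,
                          effect_draws = draws)
  estimate_power(design, truth, direction, "assurance")
}
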