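#' Recruitment assumptions for timeline projection
#'
#' @param patients_per_month average recruitment rate.
#' @return a `recruitment_assumptions` object.
#' @export
recruitment_assumptions <- function(patients_per_month) {
  stopifnot(patients_per_month > 0)
  structure(list(patients_per_month = patients_per_month),
            class = "recruitment_assumptions")
}

#' Projected recruitment duration
#'
#' @param n_total total patients to recruit.
#' @param recruit a [recruitment_assumptions()].
#' @return months needed at the assumed average rate.
#' @export
projected_months <- function(n_total, recruit) {
  stopifnot(inherits(recruit, "recruitment_assumptions"), n_total > 0)
  n_total / recruit$patients_per_month
}

#' Run one planning milestone
#'
#' One turn of the sequential strategy: fit the NMA to all evidence available
#' at this milestone, form the predictive effect for the next trial's
#' comparison, search for the smallest per-arm sample size reaching the
#' design's target power, and project the recruitment time of the re-sized
#' trial.
#'
#' The trial's truth scenario is assembled from the fitted network:
#' the control-arm ARR defaults to the pooled observed ARR of the control
#' treatment across the network's arms (total relapses / total person-years),
#' and the dispersion defaults to the posterior median of `kappa`. Either can
#' be overridden. The predictive effect enters as the full draw collection;
#' `effect_mode` chooses plug-in (predictive median) or assurance
#' (per-replicate redraw).
#'
#' @param net a connected [evidence_network()].
#' @param cfg an [nma_config()].
#' @param design a [trial_design()] whose `arm_labels` are
#'   `c(control, experimental)` network treatments.
#' @param recruit a [recruitment_assumptions()].
#' @param n_lo,n_hi per-arm sample-size search bounds.
#' @param stage_label free-text label for the milestone.
#' @param control_arr,dispersion optional overrides of the derived truth.
#' @param effect_mode passed to [find_sample_size()].
#' @param coarse_step coarse grid step of the search.
#' @return a `milestone_plan`: the posterior, next design,
#'   `recommended_n_per_arm`, `power_at_n`, `projected_recruitment_months`,
#'   the truth scenario used, and the sample-size search table.
#' @export
run_milestone <- function(net, cfg, design, recruit,
                          n_lo = 50L, n_hi = 600L,
                          stage_label = "milestone",
                          control_arr = NULL, dispersion = NULL,
                          effect_mode = c("plugin", "assurance"),
                          coarse_step = 25L) {
  effect_mode <- match.arg(effect_mode)
  stopifnot(inherits(design, "trial_design"),
            inherits(recruit, "recruitment_assumptions"))
  labs <- canonicalise_treatments(c(net$treatments, design$arm_labels))
  labs <- labs[length(net$treatments) + 1:2]
  if (!all(labs %in% net$treatments)) {
    stop(sprintf("design comparison %s vs %s is not in the network",
                 dQuote(labs[2L]), dQuote(labs[1L])), call. = FALSE)
  }
  post <- fit_nma(net, cfg)
  eff_draws <- with_local_seed(design$seed,
    predictive_effect(post, labs[2L], labs[1L]))  # experimental vs control
  if (is.null(control_arr)) {
    ctrl_arms <- net$arms[net$arms$treatment == labs[1L], , drop = FALSE]
    control_arr <- sum(ctrl_arms$relapses) / sum(ctrl_arms$person_years)
  }
  if (is.null(dispersion)) {
    kap_cols <- grep("^kappa", colnames(post$draws), value = TRUE)
    dispersion <- median(post$draws[, kap_cols[1L]])
  }
  truth <- truth_scenario(control_arr = control_arr,
                          dispersion = dispersion,
                          effect_draws = eff_draws)
  ss <- find_sample_size(design, truth, n_lo, n_hi,
                         coarse_step = coarse_step,
                         effect_mode = effect_mode)
  n_total <- 2L * ss$n
  structure(list(stage_label = stage_label, network = net,
                 posterior = post, next_design = design,
                 truth = truth,
                 recommended_n_per_arm = ss$n,
                 attained = ss$attained,
                 power_at_n = ss$power_at_n,
                 n_total = n_total,
                 projected_recruitment_months = projected_months(n_total,
                                                                 recruit),
                 search = ss),
            class = "milestone_plan")
}

#' @export
print.milestone_plan <- function(x, ...) {
  cat(sprintf("Milestone plan: %s\n", x$stage_label))
  cat(sprintf("  comparison: %s vs %s\n", x$next_design$arm_labels[2L],
              x$next_design$arm_labels[1L]))
  cat(sprintf("  recommended per-arm n: %d%s (power %.3f at target %.2f)\n",
              x$recommended_n_per_arm,
              if (x$attained) "" else " [target unattained]",
              x$power_at_n, x$next_design$target_power))
  cat(sprintf("  projected recruitment: %.2f months for %d patients\n",
              x$projected_recruitment_months, x$n_total))
  invisible(x)
}

#' Build an arm-level summary of a simulated trial
#'
#' Simulates one trial under the design and truth and collapses it to the
#' network's native input: per-arm totals of relapses and person-years. The
#' NMA then consumes the simulated study exactly like a real one.
#'
#' @param study_id study label the summary will carry.
#' @param design a [trial_design()] (its seed drives the draw).
#' @param truth a [truth_scenario()] (plug-in effect).
#' @param source evidence tag, default `"RCT"`.
#' @return data.frame of two study arms.
#' @export
simulated_study <- function(study_id, design, truth, source = "RCT") {
  counts <- with_local_seed(design$seed, simulate_counts(design, truth))
  data.frame(study_id = study_id, source = source,
             treatment = design$arm_labels,
             n_subjects = design$n_per_arm,
             relapses = c(sum(counts$control), sum(counts$experimental)),
             person_years = design$n_per_arm * design$follow_up,
             edss = NA_real_, stringsAsFactors = FALSE)
}

#' Replace a study in a network with a simulated one
#'
#' Returns a new network in which the arms of `study_id` are replaced by the
#' supplied simulated study summary (arm-level treatments, subjects, relapses
#' and person-years), inserted at the original study's position so that
#' swapping a study with an identical copy reproduces the input network
#' exactly. The input network is not modified.
#'
#' @param net an [evidence_network()].
#' @param study_id label of the study to replace.
#' @param simulated data.frame of replacement arms (>= 2 arms over existing
#'   or new treatments), e.g. from [simulated_study()]; its `study_id` is
#'   rewritten to `study_id` unless `keep_id = TRUE`.
#' @param keep_id keep the replacement's own study label.
#' @return a new [evidence_network()].
#' @export
swap_trial <- function(net, study_id, simulated, keep_id = FALSE) {
  stopifnot(inherits(net, "evidence_network"))
  arms <- net$arms
  idx <- which(arms$study_id == study_id)
  if (length(idx) == 0L) {
    stop(sprintf("study %s is not in the network", dQuote(study_id)),
         call. = FALSE)
  }
  sim <- as.data.frame(simulated, stringsAsFactors = FALSE)
  if (!keep_id) sim$study_id <- study_id
  if (!"edss" %in% names(sim)) sim$edss <- NA_real_
  if (!"source" %in% names(sim)) sim$source <- arms$source[idx[1L]]
  sim <- sim[c(ARM_COLUMNS, "edss")]
  before <- arms[seq_len(min(idx) - 1L), , drop = FALSE]
  after <- arms[setdiff(seq(min(idx), nrow(arms)), idx), , drop = FALSE]
  evidence_network(rbind(before, sim, after), reference = net$reference)
}

#' Compare two fitted posteriors
#'
#' Quantifies the difference in the totality of evidence between two NMAs of
#' the same treatment set (e.g. before and after substituting simulated
#' trials): per-contrast ratio-of-ratios (summary rate ratio under `a`
#' divided by that under `b`; 1 means no change), the change in posterior
#' spread, and a rank-agreement scalar (Pearson correlation of the expected
#' ranks from the two ranking tables) alongside the paired rank tables.
#'
#' @param a,b `nma_posterior` objects over identical treatment sets.
#' @param summary summary statistic for the rate-ratio matrices.
#' @return an `nma_comparison`: `contrasts` data.frame (treatment pair,
#'   rr_a, rr_b, ratio_of_ratios, spread_a, spread_b, spread_delta),
#'   `rank_agreement`, `ranks_a`, `ranks_b`.
#' @export
compare_nma <- function(a, b, summary = c("median", "mean")) {
  summary <- match.arg(summary)
  stopifnot(inherits(a, "nma_posterior"), inherits(b, "nma_posterior"))
  if (!setequal(a$treatments, b$treatments)) {
    only_a <- setdiff(a$treatments, b$treatments)
    only_b <- setdiff(b$treatments, a$treatments)
    stop(sprintf(
      "treatment sets differ; only in a: {%s}; only in b: {%s}",
      paste(only_a, collapse = ", "), paste(only_b, collapse = ", ")),
      call. = FALSE)
  }
  ma <- rate_ratio_matrix(a, summary)
  mb <- rate_ratio_matrix(b, summary)
  trts <- a$treatments
  pairs <- utils::combn(trts, 2L)
  contrasts <- data.frame(
    treatment_a = pairs[1L, ], treatment_b = pairs[2L, ],
    rr_a = ma$point[t(pairs)], rr_b = mb$point[cbind(pairs[1L, ], pairs[2L, ])],
    spread_a = ma$spread[t(pairs)],
    spread_b = mb$spread[cbind(pairs[1L, ], pairs[2L, ])],
    stringsAsFactors = FALSE)
  contrasts$ratio_of_ratios <- contrasts$rr_a / contrasts$rr_b
  contrasts$spread_delta <- contrasts$spread_b - contrasts$spread_a
  ra <- rank_treatments(a)
  rb <- rank_treatments(b)
  agreement <- if (sd(ra$expected_rank) == 0 || sd(rb$expected_rank) == 0) {
    if (all(ra$expected_rank == rb$expected_rank)) 1 else NA_real_
  } else {
    stats::cor(ra$expected_rank, rb$expected_rank[names(ra$expected_rank)])
  }
  structure(list(contrasts = contrasts, rank_agreement = agreement,
                 ranks_a = ra, ranks_b = rb, summary = summary),
            class = "nma_comparison")
}

#' @export
print.nma_comparison <- function(x, digits = 3, ...) {
  cat("NMA comparison (a vs b)\n")
  print(cbind(x$contrasts[, c("treatment_a", "treatment_b")],
              round(x$contrasts[, c("rr_a", "rr_b", "ratio_of_ratios",
                                    "spread_a", "spread_b",
                                    "spread_delta")], digits)),
        row.names = FALSE)
  cat(sprintf("Rank agreement (expected-rank correlation): %.3f\n",
              x$rank_agreement))
  invisible(x)
}

#' Contrast original and alternative recruitment timelines
#'
#' For each trial, the original programme's implied recruitment rate is
#' `n_total / months_observed`; the alternative design of `alt_n_total`
#' patients is projected at that rate, and the saving is the difference in
#' months. Suitable for external Gantt rendering.
#'
#' @param plans either a list of `milestone_plan` objects (their `n_total`
#'   is used) or a numeric vector of alternative total sample sizes.
#' @param originals data.frame with columns `trial`, `n_total`,
#'   `months_observed`, one row per plan.
#' @return data.frame `timeline`: trial, original and projected months,
#'   `months_saved`, plus a `total_months_saved` attribute.
#' @export
project_timeline <- function(plans, originals) {
  alt_n <- if (is.numeric(plans)) plans
           else vapply(plans, function(p) p$n_total, numeric(1))
  stopifnot(all(c("trial", "n_total", "months_observed") %in% names(originals)),
            nrow(originals) == length(alt_n))
  if (any(originals$months_observed <= 0) || any(originals$n_total <= 0)) {
    stop("original recruitment records must have positive n_total and months",
         call. = FALSE)
  }
  rate <- originals$n_total / originals$months_observed
  out <- data.frame(trial = originals$trial,
                    original_n = originals$n_total,
                    original_months = originals$months_observed,
                    alternative_n = alt_n,
                    patients_per_month = rate,
                    projected_months = alt_n / rate)
  out$months_saved <- out$original_months - out$projected_months
  attr(out, "total_months_saved") <- sum(out$months_saved)
  out
}
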