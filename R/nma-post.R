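check_treatments <- function(post, ...) {
  labs <- canonicalise_treatments(c(post$treatments, unlist(list(...))))
  labs <- labs[-seq_along(post$treatments)]
  missing <- setdiff(labs, post$treatments)
  if (length(missing) > 0L) {
    stop(sprintf("unknown treatment label(s): %s",
                 paste(dQuote(missing), collapse = ", ")), call. = FALSE)
  }
  labs
}

#' Posterior rate-ratio matrix
#'
#' Entry `[a, b]` summarises, per draw, the annualised-relapse-rate ratio
#' `exp(d_a - d_b)` of the row treatment relative to the column treatment
#' (the reference treatment has `d = 0`); `spread` is the per-draw posterior
#' standard deviation of the ratio. Ratios below 1 favour the row treatment.
#' Within each draw the ratios are exactly consistent
#' (`RR(a,c) = RR(a,b) * RR(b,c)`) and reciprocal (`RR(a,b) * RR(b,a) = 1`);
#' the summarised `point` matrix keeps a unit diagonal exactly.
#'
#' @param post an [fit_nma()] posterior.
#' @param summary `"median"` (default; robust for ratios) or `"mean"` (for
#'   comparison with arithmetic-mean reporting).
#' @return a `rate_ratio_matrix`: list with `treatments`, `point` and
#'   `spread` square matrices.
#' @export
rate_ratio_matrix <- function(post, summary = c("median", "mean")) {
  summary <- match.arg(summary)
  stopifnot(inherits(post, "nma_posterior"))
  d <- posterior_d(post)
  T_ <- ncol(d)
  point <- spread <- matrix(NA_real_, T_, T_,
                            dimnames = list(post$treatments, post$treatments))
  sfun <- if (summary == "median") median else mean
  for (a in seq_len(T_)) {
    for (b in seq_len(T_)) {
      if (a == b) {
        point[a, b] <- 1
        spread[a, b] <- 0
      } else {
        rr <- exp(d[, a] - d[, b])
        point[a, b] <- sfun(rr)
        spread[a, b] <- sd(rr)
      }
    }
  }
  structure(list(treatments = post$treatments, point = point,
                 spread = spread, summary = summary),
            class = "rate_ratio_matrix")
}

#' @export
print.rate_ratio_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Annualised relapse rate ratios (posterior %s, SD in parentheses)\n",
              x$summary))
  txt <- matrix(sprintf("%.*f (%.*f)", digits, x$point, 2, x$spread),
                nrow = nrow(x$point),
                dimnames = dimnames(x$point))
  diag(txt) <- "-"
  print(txt, quote = FALSE)
  invisible(x)
}

#' Predictive treatment effect for a new study
#'
#' Per posterior draw, returns the contrast `d_a - d_b` plus a fresh normal
#' perturbation with that draw's between-study SD `sigma` — the predictive
#' distribution of the log rate ratio a *new* study would estimate. Under
#' fixed effects the perturbation is zero and predictive draws equal the
#' posterior contrast draws. The perturbation consumes the caller's RNG
#' stream; wrap in `set.seed()` for reproducibility.
#'
#' @param post an [fit_nma()] posterior.
#' @param treatment_a,treatment_b treatment labels (effect of `a` vs `b`).
#' @return numeric vector of per-draw predicted log rate ratios.
#' @export
predictive_effect <- function(post, treatment_a, treatment_b) {
  labs <- check_treatments(post, treatment_a, treatment_b)
  d <- posterior_d(post)
  contrast <- d[, labs[1L]] - d[, labs[2L]]
  if (post$effects_mode == "fixed") return(contrast)
  contrast + rnorm(length(contrast), 0, posterior_sigma(post))
}

#' Posterior contrast draws
#'
#' The per-draw log rate ratio `d_a - d_b` without predictive perturbation.
#'
#' @inheritParams predictive_effect
#' @return numeric vector of per-draw log rate ratios.
#' @export
contrast_draws <- function(post, treatment_a, treatment_b) {
  labs <- check_treatments(post, treatment_a, treatment_b)
  d <- posterior_d(post)
  d[, labs[1L]] - d[, labs[2L]]
}

#' Rank treatments from the posterior
#'
#' Per draw, treatments are ranked by their contrast versus the reference
#' (with `lower_is_better = TRUE`, the default for relapse rates, the
#' treatment with the lowest predicted rate ranks first). Ties within a draw
#' share averaged ranks. Returns the rank-probability table (rows are
#' treatments and sum to 1), expected ranks, and the probability of being
#' best — the numbers a rank heatmap displays.
#'
#' @param post an [fit_nma()] posterior.
#' @param lower_is_better logical; rank smaller effects first.
#' @return a `treatment_ranking`: list with `prob` (treatments x ranks
#'   matrix), `expected_rank`, `p_best` and `lower_is_better`.
#' @export
rank_treatments <- function(post, lower_is_better = TRUE) {
  stopifnot(inherits(post, "nma_posterior"))
  d <- posterior_d(post)
  if (!lower_is_better) d <- -d
  T_ <- ncol(d)
  ranks <- t(apply(d, 1L, rank, ties.method = "average"))
  prob <- matrix(0, T_, T_, dimnames = list(post$treatments,
                                            paste0("rank", seq_len(T_))))
  for (r in seq_len(T_)) prob[, r] <- colMeans(ranks == r)
  # fractional (tied) ranks distribute between the neighbouring integers
  frac <- colMeans(ranks) - prob %*% seq_len(T_)
  if (any(abs(frac) > 1e-12)) {
    for (tr in seq_len(T_)) {
      leftover <- ranks[, tr][ranks[, tr] %% 1 != 0]
      for (v in leftover) {
        lo <- floor(v); hi <- ceiling(v)
        w <- v - lo
        prob[tr, lo] <- prob[tr, lo] + (1 - w) / nrow(ranks)
        prob[tr, hi] <- prob[tr, hi] + w / nrow(ranks)
      }
    }
  }
  structure(list(prob = prob,
                 expected_rank = rowSums(sweep(prob, 2L, seq_len(T_), `*`)),
                 p_best = prob[, 1L],
                 lower_is_better = lower_is_better),
            class = "treatment_ranking")
}

#' @export
print.treatment_ranking <- function(x, digits = 3, ...) {
  cat("Treatment ranking probabilities",
      if (x$lower_is_better) "(lower rate ranks better)\n" else "\n")
  print(round(x$prob, digits))
  cat("\nExpected rank:\n")
  print(round(x$expected_rank, 2))
  invisible(x)
}

#' Triangle-loop consistency check on a rate-ratio matrix
#'
#' Evaluates every treatment triangle `(a, b, c)` of a summarised rate-ratio
#' matrix and reports the discrepancy `|point[a, c] - point[a, b] *
#' point[b, c]|`. A matrix built per draw from basic parameters is exactly
#' consistent up to summary rounding; discrepancies above `tolerance` are
#' flagged. Useful as a diagnostic when a matrix is assembled from published
#' point summaries rather than joint draws.
#'
#' @param mat a [rate_ratio_matrix()] or a square numeric matrix with unit
#'   diagonal.
#' @param tolerance positive flag threshold on the absolute discrepancy.
#' @return data.frame with columns `a`, `b`, `c`, `discrepancy`, `flagged`.
#' @export
consistency_check <- function(mat, tolerance = 0.01) {
  stopifnot(tolerance > 0)
  if (inherits(mat, "rate_ratio_matrix")) mat <- mat$point
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) {
    stop("rate-ratio matrix must be square", call. = FALSE)
  }
  if (any(abs(diag(mat) - 1) > 1e-8)) {
    stop("rate-ratio matrix must have a unit diagonal", call. = FALSE)
  }
  labs <- rownames(mat)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(mat)))
  if (nrow(mat) < 3L) {
    return(data.frame(a = character(), b = character(), c = character(),
                      discrepancy = numeric(), flagged = logical()))
  }
  tri <- utils::combn(seq_len(nrow(mat)), 3L)
  out <- data.frame(
    a = labs[tri[1L, ]], b = labs[tri[2L, ]], c = labs[tri[3L, ]],
    discrepancy = abs(mat[cbind(tri[1L, ], tri[3L, ])] -
                      mat[cbind(tri[1L, ], tri[2L, ])] *
                      mat[cbind(tri[2L, ], tri[3L, ])]),
    stringsAsFactors = FALSE)
  out$flagged <- out$discrepancy > tolerance
  out
}

#' Write posterior summaries and per-draw contrasts
#'
#' `write_posterior_summary()` writes the diagnostics table (parameter,
#' posterior mean/SD/median, credible bounds, R-hat, ESS) as delimited text.
#' `write_contrast_draws()` exports per-draw basic-parameter contrasts for
#' the trial simulator, one column per non-reference treatment.
#'
#' @param post an [fit_nma()] posterior.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_posterior_summary <- function(post, path) {
  write.csv(post$diagnostics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posterior_summary
#' @export
write_contrast_draws <- function(post, path) {
  d <- posterior_d(post)
  out <- cbind(as.data.frame(d[, -1L, drop = FALSE]),
               sigma = posterior_sigma(post))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posterior_summary
#' @param mat a [rate_ratio_matrix()].
#' @export
write_rate_ratio_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "rate_ratio_matrix"))
  write.csv(as.data.frame(mat$point), path, row.names = TRUE)
  invisible(path)
}
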