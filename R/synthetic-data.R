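# RNG hygiene: run expr under a seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Declare the truth underlying a synthetic evidence network
#'
#' A generator truth records everything needed to simulate a multi-study
#' network of negative-binomially distributed relapse counts with known true
#' log rate ratios: the treatment labels (reference first), the true basic
#' log rate ratios `d_true` of each non-reference treatment versus the
#' reference, the between-study standard deviation `sigma_true` of
#' study-specific contrasts, the range study baseline annualised relapse
#' rates are drawn from, the per-patient overdispersion, and a per-study
#' design (treatments, subjects per arm, follow-up).
#'
#' Defaults are the package's documented test world: 4 treatments, 12 two-arm
#' studies of 200 subjects per arm followed for 2 years, true rate ratios
#' roughly 0.46, 0.70 and 0.90 versus the reference, `sigma_true = 0.1`,
#' dispersion 1 and baseline ARR between 0.4 and 0.7 relapses per
#' person-year.
#'
#' @param treatments character vector of treatment labels, reference first.
#' @param d_true numeric vector of true log rate ratios, one per
#'   non-reference treatment.
#' @param sigma_true non-negative between-study SD on the log-rate-ratio
#'   scale.
#' @param baseline_arr_range length-2 positive range for study baseline ARRs.
#' @param dispersion_true positive per-patient overdispersion (kappa).
#' @param designs list of per-study designs, each a list with `treatments`
#'   (>= 2 labels), `n_per_arm`, `follow_up`; `NULL` uses a connected default
#'   cycling through all treatment pairs.
#' @param n_studies number of studies when `designs` is `NULL`.
#' @param n_per_arm,follow_up defaults used when `designs` is `NULL`.
#' @param source evidence-source tag for generated studies.
#' @param seed integer seed fully determining the generated network.
#' @return an object of class `generator_truth`.
#' @seealso [generate_network()]
#' @export
generator_truth <- function(treatments = c("Placebo", "DrugB", "DrugC", "DrugD"),
                            d_true = c(-0.77, -0.35, -0.10),
                            sigma_true = 0.1,
                            baseline_arr_range = c(0.4, 0.7),
                            dispersion_true = 1,
                            designs = NULL,
                            n_studies = 12L,
                            n_per_arm = 200L,
                            follow_up = 2,
                            source = c("RCT", "RWE"),
                            seed = 1L) {
  source <- match.arg(source)
  treatments <- canonicalise_treatments(treatments)
  stopifnot(length(treatments) >= 2L,
            length(d_true) == length(treatments) - 1L,
            sigma_true >= 0, dispersion_true > 0,
            length(baseline_arr_range) == 2L,
            all(baseline_arr_range > 0),
            baseline_arr_range[1] <= baseline_arr_range[2])
  if (is.null(designs)) {
    pairs <- utils::combn(treatments, 2L, simplify = FALSE)
    designs <- lapply(seq_len(n_studies), function(i) {
      list(treatments = pairs[[(i - 1L) %% length(pairs) + 1L]],
           n_per_arm = n_per_arm, follow_up = follow_up)
    })
  }
  for (dsg in designs) {
    stopifnot(length(dsg$treatments) >= 2L,
              all(canonicalise_treatments(dsg$treatments) %in% treatments),
              dsg$n_per_arm >= 1L, dsg$follow_up > 0)
  }
  truth <- structure(list(treatments = treatments,
                          reference = treatments[1L],
                          d_true = stats::setNames(d_true, treatments[-1L]),
                          sigma_true = sigma_true,
                          baseline_arr_range = baseline_arr_range,
                          dispersion_true = dispersion_true,
                          designs = designs,
                          source = source,
                          seed = as.integer(seed)),
                     class = "generator_truth")
  # refuse disconnected designs up front
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(treatments), name = treatments)
  for (dsg in designs) {
    tr <- canonicalise_treatments(dsg$treatments)
    cmb <- utils::combn(tr, 2L)
    g <- igraph::add_edges(g, as.vector(cmb))
  }
  if (igraph::components(g)$no != 1L) {
    stop("requested study designs leave the treatment network disconnected",
         call. = FALSE)
  }
  truth
}

#' Generate a synthetic evidence network with known truth
#'
#' Per study, a baseline annualised relapse rate is drawn uniformly (on the
#' natural scale) from `baseline_arr_range`; study-specific contrasts are
#' drawn normally around the true basic-parameter contrasts with SD
#' `sigma_true` (between-arm correlation 1/2 for multi-arm studies); and each
#' arm's relapse total is drawn from the negative binomial implied by
#' `n_per_arm` patients with per-patient dispersion `dispersion_true`.
#' Person-years per arm equal subjects x follow-up (no dropout). The output
#' is deterministic given `truth$seed` and leaves the caller's RNG state
#' untouched.
#'
#' @param truth a [generator_truth()].
#' @return list with `network` (an [evidence_network()]) and `truth` (the
#'   input echoed back, so the record round-trips alongside the data).
#' @export
generate_network <- function(truth) {
  stopifnot(inherits(truth, "generator_truth"))
  with_local_seed(truth$seed, {
    rows <- list()
    for (i in seq_along(truth$designs)) {
      dsg <- truth$designs[[i]]
      tr <- canonicalise_treatments(dsg$treatments)
      # baseline arm = first design treatment; order arms by network order
      tr <- tr[order(match(tr, truth$treatments))]
      base_arr <- runif(1L, truth$baseline_arr_range[1L],
                        truth$baseline_arr_range[2L])
      d_full <- c(0, truth$d_true)[match(tr, truth$treatments)]
      md <- d_full - d_full[1L]        # contrasts vs study baseline arm
      m <- length(tr) - 1L
      delta <- c(0, draw_re_contrasts(md[-1L], truth$sigma_true))
      log_arr <- log(base_arr) + delta
      n <- rep_len(dsg$n_per_arm, length(tr))
      fu <- rep_len(dsg$follow_up, length(tr))
      rows[[i]] <- data.frame(
        study_id = sprintf("SYN%02d", i),
        source = truth$source,
        treatment = tr,
        n_subjects = as.integer(n),
        relapses = vapply(seq_along(tr), function(k) {
          as.integer(rnb_arm_total(n[k], exp(log_arr[k]), fu[k],
                                   truth$dispersion_true))
        }, integer(1)),
        person_years = n * fu,
        edss = NA_real_,
        stringsAsFactors = FALSE)
    }
    net <- evidence_network(do.call(rbind, rows),
                            reference = truth$reference)
    list(network = net, truth = truth)
  })
}

# Multivariate normal study contrasts: mean md, covariance
# sigma^2 * (I + J)/2 (unit variances, correlation 1/2), drawn conditionally
# arm by arm; standard multi-arm correction.
draw_re_contrasts <- function(md, sigma) {
  m <- length(md)
  if (m == 0L) return(numeric(0))
  if (sigma == 0) return(md)
  delta <- numeric(m)
  for (j in seq_len(m)) {
    if (j == 1L) {
      mean_j <- md[1L]
      var_j <- sigma^2
    } else {
      mean_j <- md[j] + mean(delta[seq_len(j - 1L)] - md[seq_len(j - 1L)])
      var_j <- sigma^2 * (j + 1) / (2 * j)
    }
    delta[j] <- rnorm(1L, mean_j, sqrt(var_j))
  }
  delta
}

#' The packaged real-world-evidence network
#'
#' Returns the curated 9-study RWE network of disease-modifying treatments in
#' relapsing-remitting multiple sclerosis shipped with the package (arm-level
#' subjects, relapses, person-years and descriptive EDSS). Ambiguities in the
#' typeset source table were resolved once; see
#' `system.file("extdata", "rwe_studies_provenance.md", package = "nmaplan")`
#' for the cell-by-cell provenance notes.
#'
#' @param reference reference treatment, default `"Placebo"`.
#' @return an [evidence_network()] with 9 RWE studies.
#' @examples
#' net <- fixture_rwe()
#' network_summary(net)
#' @export
fixture_rwe <- function(reference = "Placebo") {
  path <- system.file("extdata", "rwe_studies.csv", package = "nmaplan")
  read_study_table(path, source_default = "RWE", reference = reference)
}

#' Combine two evidence networks
#'
#' Stacks the study-arm records of two networks (study identifiers must not
#' collide) and rebuilds the comparison graph.
#'
#' @param a,b [evidence_network()] objects.
#' @param reference reference treatment for the combined network; defaults to
#'   `a`'s reference.
#' @return an [evidence_network()].
#' @export
combine_networks <- function(a, b, reference = a$reference) {
  stopifnot(inherits(a, "evidence_network"), inherits(b, "evidence_network"))
  clash <- intersect(unique(a$arms$study_id), unique(b$arms$study_id))
  if (length(clash) > 0L) {
    stop(sprintf("study identifier(s) present in both networks: %s",
                 paste(clash, collapse = ", ")), call. = FALSE)
  }
  evidence_network(rbind(a$arms, b$arms), reference = reference)
}
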