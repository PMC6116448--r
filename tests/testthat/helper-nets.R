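# small in-code fixtures shared across test files

make_arms <- function(study_id, treatment, relapses, person_years,
                      n_subjects = 100L, source = "RCT") {
  data.frame(study_id = study_id, source = source, treatment = treatment,
             n_subjects = n_subjects, relapses = relapses,
             person_years = person_years, edss = NA_real_,
             stringsAsFactors = FALSE)
}

# two studies, both with identical arms (no treatment effect)
symmetric_net <- function() {
  evidence_network(make_arms(
    study_id = rep(c("S1", "S2"), each = 2L),
    treatment = rep(c("A", "B"), 2L),
    relapses = c(50L, 50L, 60L, 60L),
    person_years = 100), reference = "A")
}

# chain network A-B, B-C, C-D
chain_net <- function() {
  evidence_network(make_arms(
    study_id = rep(c("AB", "BC", "CD"), each = 2L),
    treatment = c("A", "B", "B", "C", "C", "D"),
    relapses = c(40L, 30L, 35L, 28L, 30L, 27L),
    person_years = 100), reference = "A")
}

write_net_csv <- function(arms, path = tempfile(fileext = ".csv")) {
  write.csv(arms, path, row.names = FALSE)
  path
}

# brute-force oracle: within-study treatment pairs + graph traversal
oracle_edges <- function(arms) {
  pairs <- unique(do.call(rbind, lapply(split(arms$treatment, arms$study_id),
                                        function(tr) {
    t(apply(utils::combn(sort(unique(tr)), 2L), 2L, sort))
  })))
  pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
}

oracle_components <- function(arms) {
  treatments <- unique(arms$treatment)
  edges <- oracle_edges(arms)
  comp <- setNames(seq_along(treatments), treatments)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1L]; b <- edges[i, 2L]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}

# a fake posterior with prescribed d draws (and sigma), for unit-testing
# posterior operations in isolation from the sampler
fake_posterior <- function(d_draws, sigma = 0, treatments = NULL,
                           effects_mode = "random") {
  d_draws <- as.matrix(d_draws)
  if (is.null(treatments)) {
    treatments <- c("ref", paste0("T", seq_len(ncol(d_draws))))
  }
  colnames(d_draws) <- sprintf("d[%s]", treatments[-1L])
  draws <- cbind(d_draws, sigma = rep_len(sigma, nrow(d_draws)))
  colnames(draws)[ncol(draws)] <- "sigma"
  structure(list(draws = draws, chains = list(draws),
                 treatments = treatments, reference = treatments[1L],
                 effects_mode = effects_mode, study_ids = character(),
                 diagnostics = NULL, warnings = character(),
                 config = NULL, network = NULL),
            class = "nma_posterior")
}
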