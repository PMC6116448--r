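#' @useDynLib nmaplan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif sd var optimize setNames
#' @importFrom utils read.csv write.csv head
NULL

ARM_COLUMNS <- c("study_id", "source", "treatment", "n_subjects",
                 "relapses", "person_years")

canonical_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

#' Canonicalise treatment labels
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs and
#' case-folds for matching; the returned label uses the first-seen spelling of
#' each distinct (case-folded) label so display output stays readable.
#' "Rebif 22" and "Rebif 44" remain distinct treatments: no dose merging is
#' attempted.
#'
#' @param x character vector of raw treatment labels.
#' @return character vector of canonical labels, same length as `x`.
#' @examples
#' canonicalise_treatments(c(" Placebo", "placebo", "Rebif  44"))
#' @export
canonicalise_treatments <- function(x) {
  squished <- gsub("\\s+", " ", trimws(as.character(x)))
  key <- tolower(squished)
  first <- squished[!duplicated(key)]
  names(first) <- key[!duplicated(key)]
  unname(first[key])
}

validate_arms <- function(arms, context = "study table") {
  missing_cols <- setdiff(ARM_COLUMNS, names(arms))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s is missing required column(s): %s", context,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!"edss" %in% names(arms)) arms$edss <- NA_real_

  arms$study_id <- as.character(arms$study_id)
  arms$source <- toupper(trimws(as.character(arms$source)))
  bad_source <- which(!arms$source %in% c("RCT", "RWE"))
  if (length(bad_source) > 0L) {
    stop(sprintf("invalid evidence source %s in row %d (must be RCT or RWE)",
                 dQuote(arms$source[bad_source[1L]]), bad_source[1L]),
         call. = FALSE)
  }
  arms$treatment <- canonicalise_treatments(arms$treatment)

  num <- suppressWarnings(as.numeric(arms$relapses))
  bad <- which(is.na(num) | num < 0 | abs(num - round(num)) > 1e-8)
  if (length(bad) > 0L) {
    stop(sprintf("relapse count %s in row %d is not a non-negative integer",
                 dQuote(as.character(arms$relapses[bad[1L]])), bad[1L]),
         call. = FALSE)
  }
  arms$relapses <- as.integer(round(num))

  nsub <- suppressWarnings(as.numeric(arms$n_subjects))
  bad <- which(is.na(nsub) | nsub < 1 | abs(nsub - round(nsub)) > 1e-8)
  if (length(bad) > 0L) {
    stop(sprintf("n_subjects must be an integer >= 1; offending row %d",
                 bad[1L]), call. = FALSE)
  }
  arms$n_subjects <- as.integer(round(nsub))

  py <- suppressWarnings(as.numeric(arms$person_years))
  bad <- which(is.na(py) | py <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("person_years must be a positive number; offending row %d",
                 bad[1L]), call. = FALSE)
  }
  arms$person_years <- py
  arms$edss <- suppressWarnings(as.numeric(arms$edss))

  # studies need >= 2 arms with distinct treatments
  by_study <- split(arms$treatment, arms$study_id)
  n_distinct <- vapply(by_study, function(tr) length(unique(tr)), integer(1))
  if (any(n_distinct < 2L)) {
    stop(sprintf("study %s has fewer than 2 arms with distinct treatments",
                 dQuote(names(by_study)[which(n_distinct < 2L)[1L]])),
         call. = FALSE)
  }
  dup <- vapply(by_study, function(tr) anyDuplicated(tr) > 0L, logical(1))
  if (any(dup)) {
    stop(sprintf("study %s lists the same treatment in more than one arm",
                 dQuote(names(by_study)[which(dup)[1L]])), call. = FALSE)
  }
  rownames(arms) <- NULL
  arms[c(ARM_COLUMNS, "edss")]
}

#' Construct an evidence network from study-arm records
#'
#' An evidence network is the package's central container: one row per study
#' arm (study identifier, evidence source, treatment, number of subjects,
#' relapse count, person-years of follow-up, optional EDSS carried as
#' metadata), together with the undirected treatment-comparison graph induced
#' by within-study treatment pairs.
#'
#' @param arms data.frame with columns `study_id`, `source` (`"RCT"` or
#'   `"RWE"`), `treatment`, `n_subjects`, `relapses`, `person_years` and
#'   optionally `edss`.
#' @param reference reference treatment label; defaults to `"Placebo"` when
#'   present, otherwise the first treatment encountered.
#' @return an object of class `evidence_network` with elements `arms`,
#'   `treatments` (reference first) and `reference`.
#' @seealso [read_study_table()], [network_summary()], [network_edges()]
#' @export
evidence_network <- function(arms, reference = NULL) {
  arms <- as.data.frame(arms, stringsAsFactors = FALSE)
  if (nrow(arms) == 0L) {
    empty <- data.frame(study_id = character(), source = character(),
                        treatment = character(), n_subjects = integer(),
                        relapses = integer(), person_years = numeric(),
                        edss = numeric())
    return(structure(list(arms = empty, treatments = character(),
                          reference = NA_character_),
                     class = "evidence_network"))
  }
  arms <- validate_arms(arms)
  treatments <- unique(arms$treatment)
  if (is.null(reference)) {
    reference <- if ("placebo" %in% canonical_label(treatments)) {
      treatments[canonical_label(treatments) == "placebo"][1L]
    } else {
      treatments[1L]
    }
  } else {
    reference <- canonicalise_treatments(c(arms$treatment, reference))[length(arms$treatment) + 1L]
    if (!reference %in% treatments) {
      stop(sprintf("reference treatment %s is not in the network",
                   dQuote(reference)), call. = FALSE)
    }
  }
  treatments <- c(reference, setdiff(treatments, reference))
  structure(list(arms = arms, treatments = treatments, reference = reference),
            class = "evidence_network")
}

#' Read a study-arm evidence table
#'
#' Reads a comma-delimited text file with one row per study arm and a header
#' naming at least `study_id`, `treatment`, `n_subjects`, `relapses` and
#' `person_years`. A `source` column tags each arm `RCT` or `RWE`; when the
#' column is absent every row gets `source_default`. Rows are grouped by
#' `study_id`, treatment labels are canonicalised, and single-arm studies are
#' rejected. Disconnected networks are accepted here (so partial evidence can
#' be inspected) and rejected only at NMA-fit time.
#'
#' @param path path to a delimited text file.
#' @param source_default evidence source used when the file has no `source`
#'   column: `"RCT"` or `"RWE"`.
#' @param reference optional reference treatment label.
#' @return an [evidence_network()].
#' @export
read_study_table <- function(path, source_default = c("RCT", "RWE"),
                             reference = NULL) {
  source_default <- match.arg(source_default)
  tab <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  if (!"source" %in% names(tab)) tab$source <- source_default
  evidence_network(tab, reference = reference)
}

#' Write an evidence network back to the tabular dialect
#'
#' The written file round-trips: re-reading it with [read_study_table()]
#' yields a network with identical studies, arms and values.
#'
#' @param net an [evidence_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(net, path) {
  stopifnot(inherits(net, "evidence_network"))
  write.csv(net$arms, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Annualised relapse rate of a study arm
#'
#' The ARR is the number of relapses divided by the person-years of follow-up,
#' i.e. the mean number of relapses per person-year.
#'
#' @param relapses non-negative relapse count(s), or a data.frame of arms with
#'   `relapses` and `person_years` columns (e.g. `net$arms`).
#' @param person_years positive person-years of follow-up; ignored when
#'   `relapses` is a data.frame.
#' @return numeric vector of relapses per person-year.
#' @examples
#' arm_arr(10, 42)
#' @export
arm_arr <- function(relapses, person_years = NULL) {
  if (is.data.frame(relapses)) {
    person_years <- relapses$person_years
    relapses <- relapses$relapses
  }
  if (any(person_years <= 0)) {
    stop("person_years must be > 0 to form an annualised relapse rate",
         call. = FALSE)
  }
  relapses / person_years
}

#' Treatment-comparison edges of a network
#'
#' The edge set is exactly the union over studies of within-study treatment
#' pairs, each tagged with the evidence sources contributing it. Pairs are
#' unordered; each is reported once with treatments in network order.
#'
#' @param net an [evidence_network()].
#' @return data.frame with columns `treatment_a`, `treatment_b`, `sources`
#'   (comma-separated tags) and `n_studies`.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "evidence_network"))
  ord <- match(net$arms$treatment, net$treatments)
  pieces <- lapply(split(seq_len(nrow(net$arms)), net$arms$study_id),
                   function(idx) {
    tr <- net$arms$treatment[idx][order(ord[idx])]
    if (length(tr) < 2L) return(NULL)
    cmb <- utils::combn(tr, 2L)
    data.frame(treatment_a = cmb[1L, ], treatment_b = cmb[2L, ],
               source = net$arms$source[idx][1L],
               stringsAsFactors = FALSE)
  })
  all_pairs <- do.call(rbind, pieces)
  if (is.null(all_pairs) || nrow(all_pairs) == 0L) {
    return(data.frame(treatment_a = character(), treatment_b = character(),
                      sources = character(), n_studies = integer()))
  }
  key <- paste(all_pairs$treatment_a, all_pairs$treatment_b, sep = " || ")
  agg <- lapply(split(all_pairs, key), function(d) {
    data.frame(treatment_a = d$treatment_a[1L], treatment_b = d$treatment_b[1L],
               sources = paste(sort(unique(d$source)), collapse = ","),
               n_studies = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(match(out$treatment_a, net$treatments),
            match(out$treatment_b, net$treatments)), , drop = FALSE]
}

network_graph <- function(net) {
  edges <- network_edges(net)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$treatments), name = net$treatments)
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, rbind(edges$treatment_a, edges$treatment_b))
  }
  g
}

#' Connected components of the comparison graph
#'
#' @param net an [evidence_network()].
#' @return list of character vectors, one per component, the component holding
#'   the reference treatment first.
#' @export
network_components <- function(net) {
  g <- network_graph(net)
  comp <- igraph::components(g)
  groups <- split(igraph::V(g)$name, comp$membership)
  names(groups) <- NULL
  ref_first <- order(!vapply(groups, function(x) net$reference %in% x,
                             logical(1)))
  groups[ref_first]
}

#' Is the network connected relative to its reference treatment?
#'
#' @param net an [evidence_network()].
#' @return `TRUE` when every treatment is reachable from the reference via
#'   head-to-head comparisons, `NA` for an empty network.
#' @export
is_connected <- function(net) {
  if (nrow(net$arms) == 0L) return(NA)
  length(network_components(net)) == 1L
}

#' Summarise an evidence network
#'
#' @param net an [evidence_network()].
#' @return a `network_summary` object: study count, counts by evidence source,
#'   treatment count, edge list and connectivity flag.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "evidence_network"))
  studies <- unique(net$arms$study_id)
  src <- vapply(split(net$arms$source, net$arms$study_id),
                function(s) s[1L], character(1))
  structure(list(
    n_studies = length(studies),
    n_rct = sum(src == "RCT"),
    n_rwe = sum(src == "RWE"),
    n_treatments = length(net$treatments),
    n_arms = nrow(net$arms),
    edges = network_edges(net),
    connected = is_connected(net),
    reference = net$reference
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Evidence network summary\n")
  cat(sprintf("  studies:    %d (RCT %d, RWE %d)\n", x$n_studies, x$n_rct,
              x$n_rwe))
  cat(sprintf("  treatments: %d (reference: %s)\n", x$n_treatments,
              x$reference))
  cat(sprintf("  arms:       %d\n", x$n_arms))
  cat(sprintf("  edges:      %d\n", nrow(x$edges)))
  conn <- if (is.na(x$connected)) "not applicable (empty network)"
          else if (x$connected) "connected" else "NOT connected"
  cat(sprintf("  comparison graph: %s\n", conn))
  invisible(x)
}

#' @export
print.evidence_network <- function(x, ...) {
  cat(sprintf("<evidence_network: %d studies, %d arms, %d treatments, ref %s>\n",
              length(unique(x$arms$study_id)), nrow(x$arms),
              length(x$treatments), dQuote(x$reference)))
  invisible(x)
}
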