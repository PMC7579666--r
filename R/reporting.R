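# Reporting layer: one call per experiment, writing the canonical numeric
# outputs (matrix CSVs, JSON summaries, graph exports). A thin command-line
# wrapper over these functions ships in inst/scripts/cascadyn.R.

summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

pairs_to_list <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    list(from = df$from[i], to = df$to[i], m = df$m_value[i]))
}

#' Run the idealized-topology experiment and write its outputs
#'
#' For each topology: adjacency and interaction CSVs plus a JSON summary of
#' emergent and amplified cells.
#'
#' @param out_dir Output directory (created if missing).
#' @param specs Topology specs (default: the 24-spec packaged preset).
#' @param p One-step probability (default 0.1).
#' @param tau_max Truncation depth (default 10).
#' @return The suite record list, invisibly.
#' @export
run_topology_analysis <- function(out_dir, specs = topology_preset(),
                                  p = 0.1, tau_max = 10L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- run_topology_suite(specs, p = p, tau_max = tau_max)
  summary <- lapply(records, function(r) {
    write_matrix_csv(r$adjacency,
                     file.path(out_dir, paste0(r$spec$name, "-A.csv")))
    write_matrix_csv(r$interaction,
                     file.path(out_dir, paste0(r$spec$name, "-M.csv")))
    list(name = r$spec$name, size = r$spec$size,
         n_edges = sum(unclass(r$adjacency) > 0),
         emergent = pairs_to_list(r$emergent),
         amplified = pairs_to_list(r$amplified))
  })
  summary_json(list(config = list(p = p, tau_max = tau_max,
                                  n_topologies = length(records)),
                    topologies = summary),
               file.path(out_dir, "topology-summary.json"))
  invisible(records)
}

#' Run the historical-encoding experiment and write its analysis bundle
#'
#' Builds the empirical adjacency from a case file, computes the
#' interaction matrix, centralities, and emergent/amplified summaries, and
#' writes matrix CSVs, a JSON report, and a GraphML export.
#'
#' @param out_dir Output directory.
#' @param cases_path Case file (default: packaged transcription).
#' @param registry A `peril_registry`.
#' @param p One-step probability (default 0.1).
#' @param tau_max Truncation depth (default 3).
#' @param method `"truncated"` or `"closed_form"`.
#' @param exclude_edges Optional `"SRC>TGT"` tokens to drop from the
#'   empirical matrix.
#' @param compare Also compute the other method and report the maximum
#'   absolute difference between the two interaction matrices.
#' @return List with `adjacency`, `interaction`, `centrality`, `emergent`,
#'   `amplified`, `statistics`, invisibly.
#' @export
run_historical_analysis <- function(out_dir, cases_path = NULL,
                                    registry = load_taxonomy(), p = 0.1,
                                    tau_max = 3L,
                                    method = c("truncated", "closed_form"),
                                    exclude_edges = NULL, compare = FALSE) {
  method <- match.arg(method)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cases <- parse_case_file(cases_path, registry = registry)
  a <- build_empirical_adjacency(cases, registry, p = p,
                                 exclude_edges = exclude_edges)
  m <- switch(method,
              truncated = interaction_matrix_truncated(a, tau_max = tau_max),
              closed_form = interaction_matrix_closed(a))
  rep <- centrality_report(a, registry = registry)
  stats <- case_statistics(cases)
  write_matrix_csv(a, file.path(out_dir, "historical-A.csv"))
  write_matrix_csv(m, file.path(out_dir, "historical-M.csv"))
  utils::write.table(rep$table, file.path(out_dir, "centrality.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  export_graph(a, file.path(out_dir, "historical-graph.graphml"),
               format = "graphml", registry = registry)
  out <- list(config = list(p = p, tau_max = tau_max, method = method,
                            exclude_edges = exclude_edges),
              statistics = list(n_cases = stats$n_cases,
                                n_pairs = stats$n_pairs,
                                n_distinct_pairs = stats$n_distinct_pairs),
              top_centralities = rep$top,
              emergent = pairs_to_list(emergent_pairs(a, m)),
              amplified = pairs_to_list(amplified_pairs(m, p)))
  if (compare) {
    other <- if (method == "truncated") interaction_matrix_closed(a)
             else interaction_matrix_truncated(a, tau_max = tau_max)
    out$method_comparison <- list(
      other_method = attr(other, "method"),
      max_abs_difference = max(abs(unclass(m) - unclass(other))))
  }
  summary_json(out, file.path(out_dir, "historical-summary.json"))
  invisible(list(adjacency = a, interaction = m, centrality = rep,
                 emergent = emergent_pairs(a, m),
                 amplified = amplified_pairs(m, p), statistics = stats))
}

#' Monte Carlo validation of the analytic visit counts
#'
#' Runs the chain simulator on small fixture matrices (2-cycle, diagonal,
#' 3-chain) and reports the deltas between Monte Carlo visit-count
#' estimates and the fundamental-matrix rows, in units of standard errors.
#'
#' @param out_dir Output directory (or `NULL` to skip writing).
#' @param n_chains Chains per fixture (default 10000).
#' @param seed Integer seed.
#' @return Data frame of per-entry deltas, invisibly.
#' @export
run_simulation_check <- function(out_dir = NULL, n_chains = 10000L,
                                 seed = 1L) {
  fixtures <- list(
    `2-cycle` = reduced_adjacency(matrix(c(0, 0.1, 0.1, 0), 2, 2,
                                         byrow = TRUE),
                                  labels = c("EQ", "FL")),
    diagonal = reduced_adjacency(diag(0.1, 3),
                                 labels = c("EQ", "FL", "NF")),
    `3-chain` = reduced_adjacency(matrix(c(0, 0.1, 0, 0, 0, 0.1, 0, 0, 0),
                                         3, 3, byrow = TRUE),
                                  labels = c("EQ", "FL", "NF"))
  )
  rows <- list()
  for (nm in names(fixtures)) {
    a <- fixtures[[nm]]
    nmat <- fundamental_matrix(a)
    for (start in rownames(a)) {
      est <- mc_expected_visits(a, start, n_chains = n_chains, seed = seed)
      seed <- seed + 1L
      analytic <- unclass(nmat)[start, est$peril]
      rows[[length(rows) + 1L]] <- data.frame(
        fixture = nm, start = start, peril = est$peril,
        analytic = as.numeric(analytic), mc = est$mean_visits, se = est$se,
        delta_se = ifelse(est$se > 0,
                          abs(est$mean_visits - analytic) / est$se,
                          abs(est$mean_visits - analytic)))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(out, file.path(out_dir, "mc-validation.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(out)
}

#' Validate the packaged inputs
#'
#' Checks the taxonomy and case-file invariants (peril count and ordering,
#' token resolution, non-empty pair lists) and returns the case statistics.
#' Any violation is an error.
#'
#' @param cases_path Case file (default: packaged transcription).
#' @param registry A `peril_registry`.
#' @return [case_statistics()] of the parsed cases, invisibly.
#' @export
validate_inputs <- function(cases_path = NULL, registry = load_taxonomy()) {
  if (registry$canonical && registry$n_perils != 19L) {
    stop("canonical registry must have 19 perils", call. = FALSE)
  }
  cases <- parse_case_file(cases_path, registry = registry)
  stats <- case_statistics(cases)
  message("perils: ", registry$n_perils,
          if (registry$canonical) " (canonical)",
          "; cases: ", stats$n_cases,
          "; pair tokens: ", stats$n_pairs,
          "; distinct pairs: ", stats$n_distinct_pairs)
  invisible(stats)
}
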