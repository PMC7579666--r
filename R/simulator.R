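# Chain simulator: samples finite chains-of-events from the absorbing
# chain. Doubles as the independent Monte Carlo oracle for the
# fundamental-matrix visit counts and as the synthetic-catalogue generator
# feeding the encoding pipeline.

MAX_STEPS_DEFAULT <- 10000L  # hitting this cap signals a near-stochastic row

#' Sample one chain-of-events
#'
#' Starting from a real peril, draws each step from the current row's
#' categorical distribution of the full (row-stochastic) adjacency until
#' the outflow state absorbs the cascade.
#'
#' @param a_full A `full_adjacency` from [to_full()].
#' @param start Starting peril id (a real peril, not the outflow).
#' @param seed Optional integer seed for reproducibility.
#' @param max_steps Guard on chain length; exceeding it is an error, since
#'   with bounded row sums absorption is virtually certain long before.
#' @return An `event_chain`: list with `states` (peril ids ending with the
#'   outflow label), `length` (number of real-peril occupancies), and the
#'   `seed` used (or `NA`).
#' @export
sample_chain <- function(a_full, start, seed = NULL,
                         max_steps = MAX_STEPS_DEFAULT) {
  stopifnot(inherits(a_full, "full_adjacency"))
  if (!is.null(seed)) set.seed(seed)
  labels <- rownames(a_full)
  nfull <- nrow(a_full)
  s <- match(start, labels)
  if (is.na(s) || s == nfull) {
    stop("start must be a real peril of the matrix, not '", start, "'",
         call. = FALSE)
  }
  states <- integer(0)
  cur <- s
  for (step in seq_len(max_steps)) {
    states <- c(states, cur)
    cur <- sample.int(nfull, 1L, prob = a_full[cur, ])
    if (cur == nfull) break
    if (step == max_steps) {
      stop("chain did not reach the outflow state within ", max_steps,
           " steps; check row sums of the adjacency", call. = FALSE)
    }
  }
  structure(list(states = c(labels[states], labels[nfull]),
                 length = length(states),
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "event_chain")
}

#' @export
print.event_chain <- function(x, ...) {
  cat(paste(x$states, collapse = " -> "), "\n")
  invisible(x)
}

# Vectorized batch sampler: simulates n_chains chains at once, grouping
# active chains by current state so each step is one categorical draw per
# distinct state. Returns the n_chains x n matrix of per-peril visit
# counts (initial occupancy included).
simulate_visit_counts <- function(a, start, n_chains, seed = NULL,
                                  max_steps = MAX_STEPS_DEFAULT) {
  stopifnot(inherits(a, "reduced_adjacency"))
  if (!is.null(seed)) set.seed(seed)
  full <- to_full(a)
  n <- nrow(a)
  s <- match(start, rownames(a))
  if (is.na(s)) stop("unknown start peril '", start, "'", call. = FALSE)
  visits <- matrix(0L, n_chains, n, dimnames = list(NULL, rownames(a)))
  cur <- rep.int(s, n_chains)
  active <- seq_len(n_chains)
  for (step in seq_len(max_steps)) {
    ij <- cbind(active, cur)
    visits[ij] <- visits[ij] + 1L
    nxt <- integer(length(active))
    for (st in unique(cur)) {
      sel <- which(cur == st)
      nxt[sel] <- sample.int(n + 1L, length(sel), replace = TRUE,
                             prob = full[st, ])
    }
    alive <- nxt <= n
    active <- active[alive]
    cur <- nxt[alive]
    if (length(active) == 0L) return(visits)
  }
  stop(length(active), " chains did not reach the outflow state within ",
       max_steps, " steps; check row sums of the adjacency", call. = FALSE)
}

#' Monte Carlo estimate of expected visit counts
#'
#' Samples `n_chains` chains from `start` and averages the per-peril visit
#' counts (the initial occupancy is counted, so the estimate targets the
#' corresponding row of the fundamental matrix, whose diagonal is at least
#' 1; subtract 1 from the start entry to compare with the interaction
#' matrix).
#'
#' @param a A `reduced_adjacency`.
#' @param start Starting peril id.
#' @param n_chains Number of chains to sample.
#' @param seed Optional integer seed.
#' @return Data frame with columns `peril`, `mean_visits`, `se` (standard
#'   error of the mean), `n_chains`; attribute `seed` records the seed.
#' @export
mc_expected_visits <- function(a, start, n_chains = 10000L, seed = NULL) {
  if (n_chains < 1L) stop("n_chains must be >= 1", call. = FALSE)
  visits <- simulate_visit_counts(a, start, n_chains, seed = seed)
  mu <- colMeans(visits)
  se <- apply(visits, 2L, stats::sd) / sqrt(n_chains)
  structure(data.frame(peril = colnames(visits), mean_visits = mu,
                       se = se, n_chains = n_chains, row.names = NULL),
            seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Generate a synthetic catastrophe catalogue
#'
#' Samples one chain-of-events per case from a known ("truth") adjacency
#' and records it as the list of consecutive real-peril pairs, the same
#' record structure the historical encoding pipeline consumes. Chains that
#' flow out immediately are retained with zero pairs and flagged, mirroring
#' single-event catastrophes.
#'
#' @param truth A `reduced_adjacency` (the generating matrix).
#' @param n_cases Number of synthetic catastrophes.
#' @param seed Optional integer seed.
#' @param trigger_policy `"round_robin"` cycles deterministically over the
#'   perils with at least one outgoing edge; `"uniform"` draws the trigger
#'   uniformly from those perils.
#' @return List of `catastrophe_case` objects (cases with no observed pair
#'   carry attribute `pairless = TRUE` and an empty pair matrix — such
#'   cases are dropped by [build_empirical_adjacency()] since they witness
#'   no interaction).
#' @export
generate_catalogue <- function(truth, n_cases, seed = NULL,
                               trigger_policy = c("round_robin", "uniform")) {
  stopifnot(inherits(truth, "reduced_adjacency"))
  trigger_policy <- match.arg(trigger_policy)
  if (!is.null(seed)) set.seed(seed)
  full <- to_full(truth)
  labels <- rownames(truth)
  sources <- labels[rowSums(truth) > 0]
  if (length(sources) == 0L) sources <- labels
  triggers <- switch(trigger_policy,
    round_robin = rep_len(sources, n_cases),
    uniform = sample(sources, n_cases, replace = TRUE))
  lapply(seq_len(n_cases), function(k) {
    chain <- sample_chain(full, triggers[k])
    real <- chain$states[-length(chain$states)]
    pairs <- if (length(real) >= 2L) {
      cbind(from = real[-length(real)], to = real[-1L])
    } else {
      matrix(character(), ncol = 2L, dimnames = list(NULL, c("from", "to")))
    }
    structure(list(case_id = sprintf("synthetic-%04d", k),
                   name = sprintf("synthetic case %d", k),
                   country = "", trigger = triggers[k], pairs = pairs),
              class = "catastrophe_case",
              pairless = nrow(pairs) == 0L)
  })
}
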