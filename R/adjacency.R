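# Absorbing-Markov machinery: reduced/full adjacency matrices, the
# interaction matrix by truncated power series and by the closed-form
# fundamental matrix, and the emergent/amplified cell readouts.

ROW_SUM_TOL <- 1e-9        # inputs are products of decimal fractions
SPECTRAL_TOL <- 1e-9       # spectral radius must stay below 1 - SPECTRAL_TOL

#' Outflow (absorbing state) label used in full adjacency matrices
#' @export
OUTFLOW_LABEL <- "OUT"

#' Construct a reduced adjacency matrix of one-to-one trigger probabilities
#'
#' The reduced matrix holds, for each ordered peril pair (i, j), the
#' conditional probability that an event of class i triggers an event of
#' class j in one step. Rows may sum to less than 1; the residual mass is
#' the probability that the cascade dies off (see [to_full()]).
#'
#' @param entries Square numeric matrix with entries in \[0, 1\] and row
#'   sums at most 1 (substochastic).
#' @param labels Character vector of unique peril ids, one per row/column;
#'   defaults to `rownames(entries)`.
#' @return A `reduced_adjacency` object (numeric matrix with id dimnames).
#' @examples
#' a <- reduced_adjacency(matrix(c(0, 0.1, 0.1, 0), 2, 2),
#'                        labels = c("EQ", "FL"))
#' to_full(a)
#' @export
reduced_adjacency <- function(entries, labels = rownames(entries)) {
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries)) {
    stop("reduced adjacency must be square", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- sprintf("N%02d", seq_len(nrow(entries)))
  }
  if (length(labels) != nrow(entries) || anyDuplicated(labels)) {
    stop("labels must be unique and match the matrix dimension",
         call. = FALSE)
  }
  if (any(!is.finite(entries)) || any(entries < 0) || any(entries > 1)) {
    stop("adjacency entries must be probabilities in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(entries)
  if (any(rs > 1 + ROW_SUM_TOL)) {
    bad <- labels[rs > 1 + ROW_SUM_TOL]
    stop("row sum exceeds 1 for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dimnames(entries) <- list(labels, labels)
  class(entries) <- c("reduced_adjacency", "matrix", "array")
  entries
}

#' @export
print.reduced_adjacency <- function(x, ...) {
  cat("Reduced adjacency matrix (", nrow(x), "x", ncol(x), "), ",
      sum(x > 0), " non-zero cells\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Append the outflow absorbing state
#'
#' Extends a reduced adjacency matrix with an outflow state receiving the
#' residual probability of each row, so that every row is a proper
#' categorical distribution. The outflow row is the unit vector on itself:
#' once a cascade flows out it never re-enters, i.e. the outflow is an
#' absorbing state and every catastrophe dies off in finite expected time.
#'
#' @param a A `reduced_adjacency`.
#' @return A `full_adjacency`: an (n+1) x (n+1) row-stochastic matrix whose
#'   last row/column is labelled [OUTFLOW_LABEL].
#' @export
to_full <- function(a) {
  stopifnot(inherits(a, "reduced_adjacency"))
  n <- nrow(a)
  labels <- rownames(a)
  if (OUTFLOW_LABEL %in% labels) {
    stop("label '", OUTFLOW_LABEL, "' is reserved for the outflow state",
         call. = FALSE)
  }
  full <- matrix(0, n + 1L, n + 1L,
                 dimnames = list(c(labels, OUTFLOW_LABEL),
                                 c(labels, OUTFLOW_LABEL)))
  full[seq_len(n), seq_len(n)] <- unclass(a)
  full[seq_len(n), n + 1L] <- 1 - rowSums(a)
  full[n + 1L, n + 1L] <- 1
  class(full) <- c("full_adjacency", "matrix", "array")
  full
}

#' Interaction matrix by truncated power series
#'
#' Sums the matrix powers of the reduced adjacency from step 1 up to
#' `tau_max`. Entry (i, j) is the expected number of times a cascade
#' starting at i visits j within `tau_max` steps, excluding the step-0
#' occupancy of i itself. Pairs positive here but zero in the adjacency are
#' the emergent multi-step interactions.
#'
#' @param a A `reduced_adjacency`.
#' @param tau_max Positive integer truncation depth.
#' @return An `interaction_matrix` with attributes `tau_max` and
#'   `method = "truncated"`.
#' @export
interaction_matrix_truncated <- function(a, tau_max = 10L) {
  stopifnot(inherits(a, "reduced_adjacency"))
  tau_max <- as.integer(tau_max)
  if (length(tau_max) != 1L || is.na(tau_max) || tau_max < 1L) {
    stop("tau_max must be a positive integer", call. = FALSE)
  }
  am <- unclass(a)
  acc <- am
  pw <- am
  for (tau in seq_len(tau_max - 1L)) {
    pw <- pw %*% am
    acc <- acc + pw
  }
  new_interaction_matrix(acc, rownames(a), tau_max = tau_max,
                         method = "truncated")
}

new_interaction_matrix <- function(entries, labels, tau_max, method) {
  dimnames(entries) <- list(labels, labels)
  structure(entries, tau_max = tau_max, method = method,
            class = c("interaction_matrix", "matrix", "array"))
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("Interaction matrix (", nrow(x), "x", ncol(x), "), method = ",
      attr(x, "method"), ", tau_max = ", format(attr(x, "tau_max")),
      "\n", sep = "")
  print(matrix(unclass(x), nrow(x), dimnames = dimnames(x)), ...)
  invisible(x)
}

#' Fundamental matrix of the absorbing chain
#'
#' Solves (I - A) N = I for the reduced adjacency A. Entry (i, j) is the
#' expected number of visits to peril j in a cascade triggered by peril i,
#' counting the initial occupancy (so the diagonal is at least 1). Requires
#' the spectral radius of A to be strictly below 1, which is guaranteed
#' whenever every row sum is bounded away from 1.
#'
#' @param a A `reduced_adjacency`.
#' @return A `fundamental_matrix` (numeric matrix with id dimnames).
#' @export
fundamental_matrix <- function(a) {
  stopifnot(inherits(a, "reduced_adjacency"))
  am <- unclass(a)
  rho <- max(Mod(eigen(am, only.values = TRUE)$values))
  if (rho >= 1 - SPECTRAL_TOL) {
    stop("spectral radius ", format(rho), " too close to 1: the visit-count",
         " series does not converge; use interaction_matrix_truncated()",
         call. = FALSE)
  }
  n <- nrow(am)
  nm <- tryCatch(solve(diag(n) - am, diag(n)),
                 error = function(e) {
                   stop("(I - A) is numerically singular; ",
                        "use interaction_matrix_truncated()", call. = FALSE)
                 })
  dimnames(nm) <- dimnames(a)
  class(nm) <- c("fundamental_matrix", "matrix", "array")
  nm
}

#' Interaction matrix in closed form
#'
#' The fundamental matrix minus the identity: expected visit counts with
#' the step-0 self-occupancy removed, i.e. the limit of the truncated power
#' series.
#'
#' @inheritParams fundamental_matrix
#' @return An `interaction_matrix` with `method = "closed_form"`.
#' @export
interaction_matrix_closed <- function(a) {
  nm <- fundamental_matrix(a)
  new_interaction_matrix(unclass(nm) - diag(nrow(nm)), rownames(nm),
                         tau_max = Inf, method = "closed_form")
}

#' Emergent interaction pairs
#'
#' Ordered pairs reachable only through intermediary events: positive in
#' the interaction matrix but absent from the one-step adjacency. These are
#' the expansion of the space of possibilities created by chaining.
#'
#' @param a A `reduced_adjacency`.
#' @param m An `interaction_matrix` computed from `a` (labels must match).
#' @return Data frame with columns `from`, `to` (peril ids) and `m_value`.
#' @export
emergent_pairs <- function(a, m) {
  stopifnot(inherits(a, "reduced_adjacency"),
            inherits(m, "interaction_matrix"))
  if (!identical(rownames(a), rownames(m))) {
    stop("adjacency and interaction matrix labels differ", call. = FALSE)
  }
  idx <- which(unclass(m) > 0 & unclass(a) == 0, arr.ind = TRUE)
  pairs_df(rownames(a), idx, unclass(m)[idx])
}

#' Amplified interaction pairs
#'
#' Ordered pairs whose expected multi-step visit count strictly exceeds the
#' one-step probability `p` — feedback loops or multiple converging paths
#' making event j recur more often than a single direct trigger would.
#' Ties (exactly `p`, e.g. a pair reachable by a single one-step path only)
#' are classed as expansion, not amplification.
#'
#' @param m An `interaction_matrix`.
#' @param p One-step probability threshold in (0, 1).
#' @return Data frame with columns `from`, `to`, `m_value`.
#' @export
amplified_pairs <- function(m, p = 0.1) {
  stopifnot(inherits(m, "interaction_matrix"))
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
    stop("p must be a single probability in (0, 1)", call. = FALSE)
  }
  idx <- which(unclass(m) > p, arr.ind = TRUE)
  pairs_df(rownames(m), idx, unclass(m)[idx])
}

pairs_df <- function(labels, idx, values) {
  if (length(values) == 0L) {
    return(data.frame(from = character(), to = character(),
                      m_value = numeric()))
  }
  out <- data.frame(from = labels[idx[, 1L]], to = labels[idx[, 2L]],
                    m_value = values)
  out[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Write / read an adjacency or interaction matrix as CSV
#'
#' CSV dialect with a header row and a leading column of peril ids; the
#' outflow column of a full matrix is labelled `OUT`.
#'
#' @param x Matrix with id dimnames (`reduced_adjacency`, `full_adjacency`,
#'   or `interaction_matrix`).
#' @param path File path.
#' @return `write_matrix_csv` returns `path` invisibly; `read_adjacency_csv`
#'   returns a `reduced_adjacency`.
#' @export
write_matrix_csv <- function(x, path) {
  df <- data.frame(id = rownames(x),
                   matrix(unclass(x), nrow(x), dimnames = list(NULL, colnames(x))),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_adjacency_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  reduced_adjacency(m, labels = df[[1L]])
}
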