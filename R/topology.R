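# Topology lab: idealized one-to-one interaction patterns on a small square
# matrix, used to study how the interaction matrix expands and amplifies
# the one-step adjacency as patterns grow in complexity.

#' Define an interaction topology
#'
#' A topology is an edge set on an n x n grid of ordered peril-index pairs,
#' given either explicitly (`edges`) or through a named generator family.
#' Generator families follow the progression used in the topology
#' experiments: self-loops only, a single trigger row (1-to-n), a single
#' triggered column (n-to-1), several rows/columns, chains, cycles,
#' converging paths, dense triangular and random patterns. Gaps (edges
#' removed from a pattern) are explicit, never implicit.
#'
#' @param name Spec name (used in reports and error messages).
#' @param size Matrix side length n (default 10).
#' @param generator One of `"mask"`, `"empty"`, `"diagonal"`, `"single_row"`,
#'   `"single_col"`, `"rows"`, `"cols"`, `"cross"`, `"chain"`, `"cycle"`,
#'   `"band"`, `"converging"`, `"upper_triangle"`, `"random"`, `"full"`.
#' @param edges For `generator = "mask"`: integer matrix with two columns
#'   (row index, column index), 1-based.
#' @param rows,cols Row/column indices for the row/column families.
#' @param offset Super-diagonal offset for `"band"` (default 1 = chain).
#' @param density Edge probability for `"random"` (default 0.2).
#' @param self_loops Add the full diagonal on top of the pattern.
#' @param gaps Integer matrix of (row, col) pairs removed from the pattern.
#' @param seed Integer seed (required for `"random"`).
#' @return A `topology_spec` list.
#' @export
topology_spec <- function(name, size = 10L, generator = "mask", edges = NULL,
                          rows = NULL, cols = NULL, offset = 1L,
                          density = 0.2, self_loops = FALSE, gaps = NULL,
                          seed = NULL) {
  size <- as.integer(size)
  stopifnot(length(size) == 1L, size >= 1L)
  generator <- match.arg(generator, c(
    "mask", "empty", "diagonal", "single_row", "single_col", "rows", "cols",
    "cross", "chain", "cycle", "band", "converging", "upper_triangle",
    "random", "full"))
  if (generator == "random" && is.null(seed)) {
    stop("random topology '", name, "' needs a seed", call. = FALSE)
  }
  structure(list(name = name, size = size, generator = generator,
                 edges = edges, rows = rows, cols = cols, offset = offset,
                 density = density, self_loops = self_loops, gaps = gaps,
                 seed = seed),
            class = "topology_spec")
}

topology_edges <- function(spec) {
  n <- spec$size
  es <- switch(spec$generator,
    mask = {
      if (is.null(spec$edges)) stop("mask topology '", spec$name,
                                    "' needs an edges matrix", call. = FALSE)
      matrix(as.integer(spec$edges), ncol = 2L)
    },
    empty = matrix(integer(), ncol = 2L),
    diagonal = cbind(seq_len(n), seq_len(n)),
    single_row = {
      r <- spec$rows[1L]
      cbind(r, setdiff(seq_len(n), r))
    },
    single_col = {
      cc <- spec$cols[1L]
      cbind(setdiff(seq_len(n), cc), cc)
    },
    rows = do.call(rbind, lapply(spec$rows, function(r)
      cbind(r, setdiff(seq_len(n), r)))),
    cols = do.call(rbind, lapply(spec$cols, function(cc)
      cbind(setdiff(seq_len(n), cc), cc))),
    cross = rbind(cbind(spec$rows[1L], setdiff(seq_len(n), spec$rows[1L])),
                  cbind(setdiff(seq_len(n), spec$cols[1L]), spec$cols[1L])),
    chain = cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L),
    cycle = rbind(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L),
                  c(n, 1L)),
    band = {
      k <- spec$offset
      cbind(seq_len(n - k), seq_len(n - k) + k)
    },
    converging = {
      # diamond motifs s -> s+1, s -> s+2, s+1 -> s+3, s+2 -> s+3,
      # tiled along the index range: two converging paths per motif.
      starts <- seq(1L, n - 3L, by = 4L)
      do.call(rbind, lapply(starts, function(s)
        rbind(c(s, s + 1L), c(s, s + 2L), c(s + 1L, s + 3L),
              c(s + 2L, s + 3L))))
    },
    upper_triangle = {
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      unname(idx)
    },
    random = {
      set.seed(spec$seed)
      mask <- matrix(stats::runif(n * n) < spec$density, n, n)
      which(mask, arr.ind = TRUE)
    },
    full = as.matrix(expand.grid(seq_len(n), seq_len(n)))
  )
  es <- matrix(as.integer(es), ncol = 2L)
  if (isTRUE(spec$self_loops)) {
    es <- rbind(es, cbind(seq_len(n), seq_len(n)))
  }
  if (nrow(es) > 0 && (any(es < 1L) || any(es > n))) {
    stop("topology '", spec$name, "': edge index outside [1, ", n, "]",
         call. = FALSE)
  }
  es <- unique(es)
  if (!is.null(spec$gaps)) {
    gaps <- matrix(as.integer(spec$gaps), ncol = 2L)
    keep <- !(paste(es[, 1L], es[, 2L]) %in% paste(gaps[, 1L], gaps[, 2L]))
    es <- es[keep, , drop = FALSE]
  }
  es
}

#' Build the reduced adjacency of a topology
#'
#' Places the constant one-step probability `p` on every edge of the spec
#' and 0 elsewhere.
#'
#' @param spec A `topology_spec`.
#' @param p One-step trigger probability in (0, 1\].
#' @return A `reduced_adjacency` with generic labels `N01..Nnn`.
#' @export
build_topology <- function(spec, p = 0.1) {
  stopifnot(inherits(spec, "topology_spec"))
  n <- spec$size
  es <- topology_edges(spec)
  m <- matrix(0, n, n)
  if (nrow(es) > 0) m[es] <- p
  tryCatch(reduced_adjacency(m, labels = sprintf("N%02d", seq_len(n))),
           error = function(e) {
             stop("topology '", spec$name, "': ", conditionMessage(e),
                  call. = FALSE)
           })
}

#' The packaged suite of 24 idealized topologies
#'
#' Twenty-four named 10 x 10 configurations in increasing pattern
#' complexity: self-loops, single trigger row / triggered column (with and
#' without self-loops), two rows / two columns (with explicit gaps), a
#' row-column cross, chains, cycles, converging paths, a relay band, an
#' acyclic triangular pattern, two seeded random patterns (density 0.2),
#' and near-full / full matrices.
#'
#' @return List of 24 `topology_spec` objects.
#' @export
topology_preset <- function() {
  g2 <- rbind(c(1L, 4L), c(6L, 8L))
  g3 <- rbind(c(3L, 5L), c(7L, 10L))
  list(
    topology_spec("01-diagonal", generator = "diagonal"),
    topology_spec("02-single-trigger-row", generator = "single_row", rows = 1L),
    topology_spec("03-single-trigger-row-self-loops", generator = "single_row",
                  rows = 1L, self_loops = TRUE),
    topology_spec("04-single-target-column", generator = "single_col",
                  cols = 10L),
    topology_spec("05-single-target-column-self-loops",
                  generator = "single_col", cols = 10L, self_loops = TRUE),
    topology_spec("06-two-trigger-rows", generator = "rows", rows = c(1L, 6L)),
    topology_spec("07-two-trigger-rows-gapped", generator = "rows",
                  rows = c(1L, 6L), gaps = g2),
    topology_spec("08-two-trigger-rows-self-loops", generator = "rows",
                  rows = c(1L, 6L), self_loops = TRUE),
    topology_spec("09-two-target-columns", generator = "cols",
                  cols = c(5L, 10L)),
    topology_spec("10-two-target-columns-gapped", generator = "cols",
                  cols = c(5L, 10L), gaps = g3),
    topology_spec("11-two-target-columns-self-loops", generator = "cols",
                  cols = c(5L, 10L), self_loops = TRUE),
    topology_spec("12-row-column-cross", generator = "cross", rows = 1L,
                  cols = 10L),
    topology_spec("13-row-column-cross-gapped", generator = "cross",
                  rows = 1L, cols = 10L, gaps = rbind(c(1L, 6L), c(4L, 10L))),
    topology_spec("14-forward-chain", generator = "chain"),
    topology_spec("15-forward-chain-self-loops", generator = "chain",
                  self_loops = TRUE),
    topology_spec("16-cycle", generator = "cycle"),
    topology_spec("17-converging-paths", generator = "converging"),
    topology_spec("18-cycle-self-loops", generator = "cycle",
                  self_loops = TRUE),
    topology_spec("19-relay-band", generator = "band", offset = 3L),
    topology_spec("20-upper-triangular", generator = "upper_triangle"),
    topology_spec("21-random-a", generator = "random", seed = 101L),
    topology_spec("22-random-b", generator = "random", seed = 202L),
    topology_spec("23-near-full", generator = "full",
                  gaps = cbind(seq_len(10L), seq_len(10L))),
    topology_spec("24-full", generator = "full")
  )
}

#' Run the adjacency-to-interaction experiment over a suite of topologies
#'
#' For each spec: build the reduced adjacency at probability `p`, compute
#' the truncated interaction matrix at depth `tau_max`, and classify cells
#' into emergent (multi-step only) and amplified (above `p`) pairs.
#'
#' @param specs List of `topology_spec` objects (default: the 24-spec
#'   packaged preset).
#' @param p One-step probability (default 0.1).
#' @param tau_max Truncation depth (default 10).
#' @return List of records, each with elements `spec`, `adjacency`,
#'   `interaction`, `emergent`, `amplified`.
#' @export
run_topology_suite <- function(specs = topology_preset(), p = 0.1,
                               tau_max = 10L) {
  if (length(specs) == 0L) stop("empty topology suite", call. = FALSE)
  lapply(specs, function(spec) {
    a <- build_topology(spec, p = p)
    m <- interaction_matrix_truncated(a, tau_max = tau_max)
    list(spec = spec, adjacency = a, interaction = m,
         emergent = emergent_pairs(a, m), amplified = amplified_pairs(m, p))
  })
}

#' Read a topology suite from a YAML or JSON file
#'
#' Each entry is a list of `topology_spec()` arguments.
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return List of `topology_spec` objects.
#' @export
read_topology_suite <- function(path) {
  entries <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML suites requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  lapply(entries, function(e) {
    for (f in c("edges", "gaps")) {
      if (!is.null(e[[f]])) e[[f]] <- matrix(as.integer(unlist(e[[f]])),
                                             ncol = 2L, byrow = TRUE)
    }
    do.call(topology_spec, e)
  })
}
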