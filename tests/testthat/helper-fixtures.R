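# Shared fixtures and independent oracles used across the suite.

# 2-cycle A<->B at probability p: fundamental matrix known symbolically,
# N = 1/(1-p^2) * [[1, p], [p, 1]].
two_cycle <- function(p = 0.1, labels = c("EQ", "FL")) {
  reduced_adjacency(matrix(c(0, p, p, 0), 2, 2, byrow = TRUE),
                    labels = labels)
}

# self-loops only: visit counts geometric, m_ii = p/(1-p)
diagonal_matrix <- function(p = 0.1, n = 3,
                            labels = c("EQ", "FL", "NF")[seq_len(n)]) {
  reduced_adjacency(diag(p, n), labels = labels)
}

# nilpotent chain A -> B -> C
chain3 <- function(p = 0.1, labels = c("EQ", "FL", "NF")) {
  reduced_adjacency(matrix(c(0, p, 0,
                             0, 0, p,
                             0, 0, 0), 3, 3, byrow = TRUE),
                    labels = labels)
}

# random substochastic matrix with row sums drawn below `max_row_sum`
random_substochastic <- function(n = 10, max_row_sum = 0.9) {
  m <- matrix(stats::runif(n * n), n, n)
  m / rowSums(m) * stats::runif(n, 0, max_row_sum)
}

# random binary-mask matrix in the style of the random topology family:
# each cell an edge with probability `density`, entries equal to p, rows
# capped at floor(0.9/p) edges so row sums stay at or below 0.9
random_mask_matrix <- function(n = 10, p = 0.1, density = 0.2) {
  cap <- floor(0.9 / p)
  mask <- matrix(stats::runif(n * n) < density, n, n)
  for (i in seq_len(n)) {
    extra <- sum(mask[i, ]) - cap
    if (extra > 0) {
      on <- which(mask[i, ])
      mask[i, sample(on, extra)] <- FALSE
    }
  }
  reduced_adjacency(mask * p)
}

# ---- brute-force graph oracles (exhaustive, for n <= 6) ----

# all-pairs shortest-path distances by breadth-first search on a logical
# adjacency matrix (self-loops ignored)
bf_distances <- function(adj) {
  n <- nrow(adj)
  diag(adj) <- FALSE
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ]))))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

bf_harmonic_closeness <- function(adj) {
  d <- bf_distances(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(s) {
    sum(1 / d[s, -s]) / (n - 1)
  }, numeric(1))
}

# fractional betweenness by exhaustive enumeration of simple paths: for
# each ordered pair (s, t) find all shortest simple paths, credit each
# interior vertex 1/sigma_st per path
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  diag(adj) <- FALSE
  b <- numeric(n)
  all_paths <- function(s, t) {
    found <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        found[[length(found) + 1]] <<- path
        return()
      }
      for (w in which(adj[v, ])) if (!w %in% path) walk(c(path, w))
    }
    walk(s)
    found
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- all_paths(s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    for (pth in shortest) {
      interior <- pth[-c(1, length(pth))]
      b[interior] <- b[interior] + 1 / length(shortest)
    }
  }
  b
}
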