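test_that("to_full appends a conserving outflow state", {
  # no interactions: everything flows out in one step
  z <- reduced_adjacency(matrix(0, 2, 2), labels = c("EQ", "FL"))
  fz <- to_full(z)
  expect_identical(dim(fz), c(3L, 3L))
  expect_equal(unclass(fz)[, 3],
               c(EQ = 1, FL = 1, OUT = 1))

  a <- two_cycle(0.1)
  f <- to_full(a)
  expect_equal(unname(unclass(f)[1:2, 3]), c(0.9, 0.9))
  expect_equal(unname(unclass(f)[3, ]), c(0, 0, 1))
  expect_identical(colnames(f)[3], OUTFLOW_LABEL)

  # validation errors name the offending row
  expect_error(reduced_adjacency(matrix(c(0.6, 0.6, 0, 0), 2, 2,
                                        byrow = TRUE),
                                 labels = c("EQ", "FL")),
               "EQ")
  expect_error(reduced_adjacency(matrix(c(0, 1.2, 0, 0), 2, 2),
                                 labels = c("EQ", "FL")),
               "probabilities")
})

test_that("full-matrix rows sum to one within 1e-12 for arbitrary valid inputs", {
  set.seed(7)
  for (k in 1:20) {
    a <- reduced_adjacency(random_substochastic(8, max_row_sum = 1))
    rs <- rowSums(to_full(a))
    expect_true(all(abs(rs - 1) <= 1e-12))
  }
})

test_that("truncated interaction matrix matches hand-computed series", {
  # zero matrix stays zero
  z <- reduced_adjacency(matrix(0, 3, 3))
  expect_true(all(unclass(interaction_matrix_truncated(z, 5)) == 0))

  # nilpotent 3-chain: one two-step emergent entry of p^2
  a <- chain3(0.1)
  m <- interaction_matrix_truncated(a, 10)
  expect_identical(attr(m, "method"), "truncated")
  exp_m <- matrix(c(0, 0.1, 0.01,
                    0, 0,   0.1,
                    0, 0,   0), 3, 3, byrow = TRUE,
                  dimnames = list(rownames(a), rownames(a)))
  expect_equal(unclass(m), exp_m, tolerance = 1e-15, ignore_attr = TRUE)

  # diagonal: geometric partial sum (0.1 - 0.1^11) / 0.9
  d <- diagonal_matrix(0.1, n = 10, labels = sprintf("N%02d", 1:10))
  md <- interaction_matrix_truncated(d, 10)
  geo <- (0.1 - 0.1^11) / 0.9
  expect_equal(unname(diag(unclass(md))), rep(geo, 10), tolerance = 1e-15)
  expect_true(all(unclass(md)[upper.tri(md) | lower.tri(md)] == 0))

  expect_error(interaction_matrix_truncated(a, 0), "positive integer")
})

test_that("fundamental matrix solves the 2-cycle symbolically and rejects divergent chains", {
  a <- two_cycle(0.1)
  nm <- fundamental_matrix(a)
  # symbolic 2x2 inversion: N = 1/(1-p^2) [[1, p], [p, 1]]
  expect_equal(unclass(nm),
               matrix(c(1, 0.1, 0.1, 1) / 0.99, 2, 2,
                      dimnames = list(c("EQ", "FL"), c("EQ", "FL"))),
               tolerance = 1e-14)
  expect_true(all(diag(unclass(nm)) >= 1))

  # zero matrix: identity
  z <- reduced_adjacency(matrix(0, 2, 2), labels = c("EQ", "FL"))
  expect_equal(unname(unclass(fundamental_matrix(z))), diag(2))

  # absorbing never reached: series diverges
  loop <- reduced_adjacency(matrix(1, 1, 1), labels = "NF")
  expect_error(fundamental_matrix(loop), "truncated")
})

test_that("closed-form interaction matrix is N minus I and agrees with the terminating series", {
  a <- two_cycle(0.1)
  m <- interaction_matrix_closed(a)
  expect_identical(attr(m, "method"), "closed_form")
  expect_equal(unclass(m)[1, 1], 0.01 / 0.99, tolerance = 1e-14)
  expect_equal(unclass(m)[1, 2], 0.1 / 0.99, tolerance = 1e-14)

  # nilpotent chain: series terminates, closed form equals truncation >= 2
  ch <- chain3(0.1)
  expect_equal(unclass(interaction_matrix_closed(ch)),
               unclass(interaction_matrix_truncated(ch, 2)),
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("emergent pairs are the multi-step-only cells", {
  ch <- chain3(0.1)
  m <- interaction_matrix_truncated(ch, 10)
  em <- emergent_pairs(ch, m)
  expect_identical(em$from, "EQ")
  expect_identical(em$to, "NF")

  d <- diagonal_matrix(0.1)
  expect_identical(nrow(emergent_pairs(d, interaction_matrix_closed(d))), 0L)

  b <- two_cycle(0.1, labels = c("A", "B"))
  expect_error(emergent_pairs(b, m), "labels differ")
})

test_that("amplified pairs use a strict threshold with ties classed as expansion", {
  # chain: m_12 = p exactly (single one-step path) -> not amplified
  ch <- chain3(0.1)
  expect_identical(nrow(amplified_pairs(interaction_matrix_truncated(ch, 10),
                                        0.1)), 0L)

  # 2-cycle feedback pushes both off-diagonals above p
  # (diagonal entries 0.01/0.99 stay below the threshold)
  cyc <- interaction_matrix_closed(two_cycle(0.1))
  amp <- amplified_pairs(cyc, 0.1)
  expect_setequal(paste(amp$from, amp$to), c("EQ FL", "FL EQ"))
  expect_equal(amp$m_value, rep(0.1 / 0.99, 2), tolerance = 1e-14)

  # self-loops amplify the diagonal: p/(1-p) > p
  d <- diagonal_matrix(0.1)
  ad <- amplified_pairs(interaction_matrix_closed(d), 0.1)
  expect_identical(ad$from, ad$to)
  expect_identical(nrow(ad), 3L)
  expect_equal(ad$m_value, rep(0.1 / 0.9, 3), tolerance = 1e-14)

  expect_error(amplified_pairs(cyc, 1.5), "probability")
})

test_that("truncated series is entrywise monotone in depth and contains the adjacency support", {
  set.seed(11)
  for (k in 1:10) {
    a <- random_mask_matrix(8, p = 0.1, density = 0.3)
    prev <- matrix(0, 8, 8)
    for (tau in c(1, 2, 5, 10)) {
      m <- unclass(interaction_matrix_truncated(a, tau))
      expect_true(all(m - prev >= -1e-15))
      prev <- m
    }
    expect_true(all(prev[unclass(a) > 0] > 0))  # support growth
  }
})

test_that("truncation error obeys the geometric tail bound for row sums up to 0.9", {
  set.seed(23)
  bound <- 0.9^51 / (1 - 0.9)
  for (k in 1:25) {
    a <- reduced_adjacency(random_substochastic(10, max_row_sum = 0.9))
    d <- max(abs(unclass(interaction_matrix_closed(a)) -
                   unclass(interaction_matrix_truncated(a, 50))))
    expect_lt(d, bound + 1e-10)
  }
})

test_that("matrix CSV round-trips through the id-labelled dialect", {
  a <- two_cycle(0.25, labels = c("NF", "BI"))
  path <- tempfile(fileext = ".csv")
  write_matrix_csv(a, path)
  back <- read_adjacency_csv(path)
  expect_equal(unclass(back), unclass(a))
  # full matrices carry the OUT column label
  pf <- tempfile(fileext = ".csv")
  write_matrix_csv(to_full(a), pf)
  expect_identical(utils::read.csv(pf, check.names = FALSE)$id[3], "OUT")
})
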