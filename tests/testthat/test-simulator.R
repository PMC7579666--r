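test_that("sample_chain terminates at the outflow and is seed-deterministic", {
  z <- to_full(reduced_adjacency(matrix(0, 2, 2), labels = c("EQ", "FL")))
  ch <- sample_chain(z, "EQ", seed = 1)
  expect_identical(ch$states, c("EQ", "OUT"))
  expect_identical(ch$length, 1L)

  a <- to_full(two_cycle(0.4))
  c1 <- sample_chain(a, "EQ", seed = 123)
  c2 <- sample_chain(a, "EQ", seed = 123)
  expect_identical(c1$states, c2$states)
  expect_identical(tail(c1$states, 1), "OUT")
  # every consecutive real-pair transition is a true edge
  real <- c1$states[-length(c1$states)]
  if (length(real) >= 2) {
    idx <- cbind(real[-length(real)], real[-1])
    expect_true(all(a[idx] > 0))
  }

  expect_error(sample_chain(a, "OUT"), "real peril")
  expect_error(sample_chain(a, "ZZ"), "real peril")
})

test_that("near-stochastic rows trip the non-termination guard", {
  sticky <- to_full(reduced_adjacency(matrix(0.999999, 1, 1),
                                      labels = c("NF")))
  expect_error(sample_chain(sticky, "NF", seed = 4, max_steps = 50),
               "outflow")
})

test_that("Monte Carlo visit counts hit the analytic expectations", {
  # single self-loop at q = 0.5: visits geometric with mean 1/(1-q) = 2
  a1 <- reduced_adjacency(matrix(0.5, 1, 1), labels = "NF")
  est <- mc_expected_visits(a1, "NF", n_chains = 20000, seed = 8)
  expect_equal(est$mean_visits, 2, tolerance = 0.05)

  # zero matrix: the start is visited exactly once, deterministically
  z <- reduced_adjacency(matrix(0, 2, 2), labels = c("EQ", "FL"))
  ez <- mc_expected_visits(z, "EQ", n_chains = 100, seed = 9)
  expect_equal(ez$mean_visits, c(1, 0))
  expect_equal(ez$se, c(0, 0))

  # 2-cycle at p = 0.1: compare to the symbolic fundamental matrix row
  cyc <- two_cycle(0.1)
  ec <- mc_expected_visits(cyc, "EQ", n_chains = 50000, seed = 10)
  expect_lt(abs(ec$mean_visits[1] - 1 / 0.99), 3 * ec$se[1])
  expect_lt(abs(ec$mean_visits[2] - 0.1 / 0.99), 3 * ec$se[2])
})

test_that("chain lengths for a single self-loop follow the geometric law", {
  q <- 0.5
  a <- reduced_adjacency(matrix(q, 1, 1), labels = "NF")
  visits <- cascadyn:::simulate_visit_counts(a, "NF", 100000, seed = 77)[, 1]
  # visits - 1 ~ Geometric(1 - q); chi-square GOF on binned counts
  kmax <- 9
  obs <- tabulate(pmin(visits, kmax + 1), nbins = kmax + 1)
  probs <- c(stats::dgeom(0:(kmax - 1), 1 - q),
             1 - stats::pgeom(kmax - 1, 1 - q))
  gof <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.001)
})

test_that("synthetic catalogues are sound and recover the generating support", {
  # truth support is never violated, on any random run
  set.seed(31)
  for (k in 1:5) {
    truth <- random_mask_matrix(6, p = 0.3, density = 0.3)
    cat <- generate_catalogue(truth, 50, seed = sample.int(1e6, 1))
    for (cs in cat) {
      if (nrow(cs$pairs) > 0) {
        expect_true(all(unclass(truth)[cs$pairs] > 0))
      }
    }
  }

  # high-probability chain: support recovered exactly (fixed seed)
  chain <- reduced_adjacency(matrix(c(0, 0.9, 0,
                                      0, 0, 0.9,
                                      0, 0, 0), 3, 3, byrow = TRUE),
                             labels = c("EQ", "FL", "NF"))
  cat <- generate_catalogue(chain, 500, seed = 2020,
                            trigger_policy = "round_robin")
  expect_length(cat, 500L)
  pairs <- unique(do.call(rbind, lapply(cat, `[[`, "pairs")))
  expect_setequal(paste(pairs[, 1], pairs[, 2]), c("EQ FL", "FL NF"))

  # round-robin cycles only over perils with outgoing edges
  triggers <- vapply(cat, `[[`, character(1), "trigger")
  expect_setequal(unique(triggers), c("EQ", "FL"))

  # zero truth: all cases flagged pair-less
  zcat <- generate_catalogue(reduced_adjacency(matrix(0, 2, 2),
                                               labels = c("EQ", "FL")),
                             5, seed = 1)
  expect_true(all(vapply(zcat, attr, logical(1), "pairless")))
})

test_that("generated catalogues flow through the encoding pipeline unchanged", {
  regy <- load_taxonomy()
  ids <- peril_ids(regy)
  truth <- build_empirical_adjacency(
    suppressWarnings(parse_case_file(registry = regy)), regy, p = 0.1)
  cat <- generate_catalogue(truth, 200, seed = 55)
  with_pairs <- Filter(function(cs) nrow(cs$pairs) > 0, cat)
  path <- tempfile(fileext = ".tsv")
  write_case_file(with_pairs, path)
  back <- parse_case_file(path, registry = regy)
  rec <- build_empirical_adjacency(back, regy, p = 0.1)
  # recovered support is a subset of the truth support
  expect_true(all(unclass(truth)[unclass(rec) > 0] > 0))
})
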