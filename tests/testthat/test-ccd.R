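ref <- default_reference()

test_that("ccd is the Euclidean distance between correlation vectors", {
  expect_equal(ccd(ref, ref), 0)
  expect_equal(ccd(rep(0.5, 66), rep(0.4, 66)), 0.1 * sqrt(66))
  expect_equal(0.1 * sqrt(66), 0.8124, tolerance = 1e-4)
  one_off <- ref$rho
  one_off[10] <- one_off[10] + 0.5
  expect_equal(ccd(one_off, ref), 0.5)
  expect_error(ccd(rep(0, 10), ref), "length")
  swapped <- ref$rho
  names(swapped)[1:2] <- names(swapped)[2:1]
  expect_error(ccd(swapped, ref$rho), "pair order")
})

test_that("exact permutation p-values follow (b+1)/(m+1)", {
  expect_equal(exact_perm_p(0, 1000), 1 / 1001)
  expect_equal(exact_perm_p(1000, 1000), 1)
  expect_equal(exact_perm_p(4, 1000), 5 / 1001)
  expect_error(exact_perm_p(5, 4), "b <= m")
  expect_error(exact_perm_p(-1, 4), "b <= m")
  expect_error(exact_perm_p(0, 0), "b <= m")
})

test_that("ccd_test recovers a normally progressing clock and is reproducible", {
  sim <- simulate_clock(sim_config(n_samples = 60, seed = 21))
  res <- ccd_test(sim$expr, ref, m = 500, seed = 42)
  expect_equal(res$p_value, 1 / 501)  # closer to reference than any null draw
  expect_length(res$null_ccds, 500L)
  expect_gte(res$p_value, 1 / (res$n_null + 1))
  expect_lte(res$p_value, 1)
  # fixed seed: bit-identical outputs
  res2 <- ccd_test(sim$expr, ref, m = 500, seed = 42)
  expect_identical(res$null_ccds, res2$null_ccds)
  expect_identical(res$p_value, res2$p_value)
  # different seed: different null draws
  res3 <- ccd_test(sim$expr, ref, m = 500, seed = 43)
  expect_false(identical(res$null_ccds, res3$null_ccds))
})

test_that("ccd_test p-value formula matches its own null draws", {
  sim <- simulate_clock(sim_config(n_samples = 30, condition = "arrhythmic",
                                   seed = 5))
  res <- ccd_test(sim$expr, ref, m = 200, seed = 7)
  b <- sum(res$null_ccds <= res$ccd)
  expect_equal(res$p_value, (b + 1) / (200 + 1))
  expect_gt(res$p_value, 0.05)  # arrhythmic clock is not closer than chance
})

test_that("ccd_test validates inputs and warns on a thin background", {
  sim <- simulate_clock(sim_config(n_samples = 30, n_background = 20,
                                   seed = 6))
  expect_warning(ccd_test(sim$expr, ref, m = 10, seed = 1),
                 "poorly resolved")
  small <- sim$expr[1:12, ]
  expect_error(suppressWarnings(ccd_test(small, ref, m = 10, seed = 1)),
               "more measured genes")
  expect_error(suppressWarnings(ccd_test(sim$expr, ref, m = 0, seed = 1)),
               "at least 1")
})

test_that("ccd_test is invariant under monotone transforms and sample order", {
  sim <- simulate_clock(sim_config(n_samples = 40, seed = 31))
  base <- ccd_test(sim$expr, ref, m = 100, seed = 9)
  mono <- ccd_test(2^sim$expr, ref, m = 100, seed = 9)
  expect_identical(base$ccd, mono$ccd)
  expect_identical(base$null_ccds, mono$null_ccds)
  expect_identical(base$p_value, mono$p_value)
  perm <- sample(ncol(sim$expr))
  reord <- ccd_test(sim$expr[, perm], ref, m = 100, seed = 9)
  expect_equal(base$ccd, reord$ccd)
  expect_equal(base$null_ccds, reord$null_ccds)
})

test_that("delta_ccd_test separates a disrupted from a normal clock", {
  d <- make_two_group(40, 40, condition_b = "arrhythmic", seed = 17)
  res <- delta_ccd_test(d$expr, d$labels, ref, m = 200, seed = 3,
                        group_a = "a", group_b = "b")
  expect_equal(res$delta, res$ccd_b - res$ccd_a)
  expect_gt(res$delta, 0)
  expect_lte(res$p_value, 0.01)
  b <- sum(res$null_deltas >= res$delta)
  expect_equal(res$p_value, (b + 1) / 201)
  # swapping the groups negates delta exactly
  swap <- delta_ccd_test(d$expr, d$labels, ref, m = 200, seed = 3,
                         group_a = "b", group_b = "a")
  expect_equal(swap$delta, -res$delta)
  expect_equal(swap$ccd_a, res$ccd_b)
})

test_that("delta_ccd_test is deterministic and monotone-invariant", {
  d <- make_two_group(20, 20, seed = 23)
  r1 <- delta_ccd_test(d$expr, d$labels, ref, m = 100, seed = 5)
  r2 <- delta_ccd_test(d$expr, d$labels, ref, m = 100, seed = 5)
  expect_identical(r1$null_deltas, r2$null_deltas)
  expect_identical(r1$p_value, r2$p_value)
  r3 <- delta_ccd_test(2^d$expr, d$labels, ref, m = 100, seed = 5)
  expect_identical(r1$delta, r3$delta)
  expect_identical(r1$null_deltas, r3$null_deltas)
})

test_that("delta_ccd_test p-values are roughly uniform under the null", {
  ps <- numeric(40)
  deltas <- numeric(40)
  for (i in seq_len(40)) {
    d <- make_null_two_group(15, 15, seed = 1000 + i, n_background = 0)
    res <- delta_ccd_test(d$expr, d$labels, ref, m = 99, seed = i)
    ps[i] <- res$p_value
    deltas[i] <- res$delta
  }
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_lt(abs(mean(deltas)), 0.15)  # deltas centred near zero
  expect_true(all(ps >= 1 / 100 & ps <= 1))
})

test_that("delta_ccd_test validates groups and labels", {
  d <- make_two_group(10, 10, seed = 2, n_background = 0)
  labs3 <- d$labels
  labs3[1:3] <- "c"
  expect_error(delta_ccd_test(d$expr, labs3, ref, m = 10), "pairwise")
  expect_error(delta_ccd_test(d$expr, d$labels[-1], ref, m = 10),
               "one condition per sample")
  tiny <- c(rep("a", 2), rep("b", 18))
  expect_error(delta_ccd_test(d$expr, tiny, ref, m = 10), "at least 3")
  expect_error(delta_ccd_test(d$expr, d$labels, ref, m = 10, group_a = "a"),
               "both group_a and group_b")
})

test_that("RNG state of the session is left untouched", {
  set.seed(99)
  before <- .Random.seed
  sim <- simulate_clock(sim_config(n_samples = 20, seed = 1))
  invisible(ccd_test(sim$expr, ref, m = 10, seed = 2))
  expect_identical(.Random.seed, before)
})
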