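test_that("noiseless sinusoid geometry gives exact arm correlations", {
  # random (tie-free) times: an even grid creates rank ties at the level of
  # floating-point noise because cos is symmetric about its peak
  sim <- simulate_clock(sim_config(n_samples = 240, noise_sd = 0,
                                   n_background = 0, seed = 27))
  cv <- correlation_vector(sim$expr)
  # same phase within the positive arm
  expect_equal(cv$rho[["Arntl|Npas2"]], 1)
  expect_equal(cv$rho[["Npas2|Clock"]], 1)
  # same phase within the negative arm
  expect_equal(cv$rho[["Nr1d1|Per1"]], 1)
  expect_equal(cv$rho[["Dbp|Tef"]], 1)
  # positive vs negative arm: 12 h offset, exact mirror
  expect_equal(cv$rho[["Arntl|Nr1d1"]], -1)
  expect_equal(cv$rho[["Clock|Per2"]], -1)
  # Cry1 sits between the arms: intermediate correlation magnitude
  expect_lt(abs(cv$rho[["Arntl|Cry1"]]), 1)
})

test_that("simulation is bit-reproducible from its config", {
  cfg <- sim_config(n_samples = 25, seed = 99)
  a <- simulate_clock(cfg)
  b <- simulate_clock(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth, b$truth)
  c <- simulate_clock(sim_config(n_samples = 25, seed = 100))
  expect_false(identical(a$expr, c$expr))
})

test_that("truth slot regenerates the signal deterministically", {
  cfg <- sim_config(n_samples = 15, noise_sd = 0, n_background = 0, seed = 3)
  sim <- simulate_clock(cfg)
  tr <- sim$truth
  manual <- outer(seq_along(tr$phases), seq_len(15), function(g, s) {
    tr$baselines[g] + tr$amplitudes[g] * cos(2 * pi * (tr$times[s] - tr$phases[g]) / 24)
  })
  expect_equal(unname(sim$expr), manual)
})

test_that("condition modes alter the generative truth as documented", {
  base <- sim_config(n_samples = 10, seed = 5)
  arr <- simulate_clock(sim_config(n_samples = 10, seed = 5,
                                   condition = "arrhythmic"))
  expect_true(all(arr$truth$amplitudes == 0))
  scr <- simulate_clock(sim_config(n_samples = 10, seed = 5,
                                   condition = "phase_scrambled"))
  expect_false(identical(scr$truth$phases, simulate_clock(base)$truth$phases))
  ko <- simulate_clock(sim_config(n_samples = 10, seed = 5,
                                  condition = "knockout",
                                  knockout_genes = c("Arntl", "Per2")))
  expect_equal(unname(ko$truth$amplitudes[c("Arntl", "Per2")]), c(0, 0))
  expect_true(all(ko$truth$amplitudes[c("Clock", "Dbp")] > 0))
  expect_equal(unname(ko$truth$baselines[["Arntl"]]), 8 - 2)
})

test_that("arrhythmic expression decorrelates the signature genes", {
  sim <- simulate_clock(sim_config(n_samples = 200, condition = "arrhythmic",
                                   n_background = 0, seed = 41))
  cv <- correlation_vector(sim$expr)
  expect_true(all(abs(cv$rho) < 0.3))
})

test_that("config validation catches inconsistent settings", {
  expect_error(sim_config(phases = rep(25, 12)), "\\[0, 24\\)")
  expect_error(sim_config(amplitudes = -1), "nonnegative")
  expect_error(sim_config(noise_sd = -0.1), ">= 0")
  expect_error(sim_config(sample_times = 1:5, n_samples = 4), "length")
  expect_error(sim_config(time_range = c(8, 2)), "increasing")
  expect_error(sim_config(condition = "knockout"), "knockout_genes")
  expect_error(sim_config(condition = "knockout", knockout_genes = "Nope"),
               "knockout_genes")
})

test_that("reference panels are independent draws from one truth", {
  panel <- simulate_reference_panel(4, n_samples = 20, seed = 7)
  expect_length(panel, 4L)
  for (i in 2:4) expect_false(identical(panel[[1]]$expr, panel[[i]]$expr))
  # shared truth: same phase architecture in every dataset
  expect_identical(panel[[1]]$truth$phases, panel[[2]]$truth$phases)
  expect_error(simulate_reference_panel(1), "at least 2")
})

test_that("correlated background blocks induce within-block correlation", {
  sim <- simulate_clock(sim_config(n_samples = 150, n_background = 40,
                                   background_blocks = 2, block_size = 10,
                                   block_cor = 0.8, seed = 13))
  bg <- sim$expr[grep("^Bkg", rownames(sim$expr)), ]
  within <- cor(bg["Bkg0001", ], bg["Bkg0002", ], method = "spearman")
  across <- cor(bg["Bkg0001", ], bg["Bkg0031", ], method = "spearman")
  expect_gt(within, 0.5)
  expect_lt(abs(across), 0.3)
})

test_that("per-sample phase jitter desynchronizes recorded and used times", {
  crisp <- simulate_clock(sim_config(n_samples = 100, n_background = 0,
                                     seed = 19))
  fuzzy <- simulate_clock(sim_config(n_samples = 100, n_background = 0,
                                     phase_jitter_sd = 2, seed = 19))
  expect_identical(crisp$truth$times, crisp$times)
  expect_false(identical(fuzzy$truth$times, fuzzy$times))
  # with uniform sampling over the full cycle the co-expression pattern is
  # preserved: jitter shifts whole samples, not gene-to-gene phase relations
  r_fuzzy <- correlation_vector(fuzzy$expr)$rho[["Arntl|Npas2"]]
  expect_gt(r_fuzzy, 0.5)
})

test_that("double knockouts perturb co-expression more than single ones", {
  ref <- default_reference()
  deltas <- sapply(list("Arntl", "Per2", c("Arntl", "Per2")), function(ko) {
    mean(sapply(1:3, function(s) {
      d <- make_two_group(60, 60, condition_b = "knockout", seed = 500 + s,
                          knockout_genes = ko, n_background = 0)
      delta_ccd_test(d$expr, d$labels, ref, m = 1, seed = s)$delta
    }))
  })
  expect_gt(deltas[3], deltas[1])
  expect_gt(deltas[3], deltas[2])
})
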