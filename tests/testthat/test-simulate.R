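test_that("cluster placement is uniform, reproducible, and validates input", {
  expect_equal(nrow(place_clusters(50000, 0, seed = 3)), 0)
  a <- place_clusters(50000, 5, seed = 1)
  b <- place_clusters(50000, 5, seed = 1)
  expect_equal(a, b)
  expect_error(place_clusters(50000, -1), "n_clusters")
  expect_error(place_clusters(0, 5), "molecule_length_nt")

  big <- place_clusters(50000, 2000, seed = 7)
  expect_true(all(big$position_nt >= 0 & big$position_nt <= 50000))
  ks <- suppressWarnings(ks.test(big$position_nt / 50000, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("trajectory simulation matches its sampling model", {
  preset <- motor_preset("rad51", p_coloc = 0)
  expect_equal(nrow(simulate_trajectories(preset, 0)), 0)

  # exponential run lengths: mean = halflife / ln 2; sampled on a long
  # molecule so boundary clipping is negligible
  tr <- simulate_trajectories(preset, 10000, molecule_length_nt = 1e7,
                              recording_s = 1e7, seed = 11)
  target <- preset$halflife_knt * 1000 / log(2)
  expect_lt(abs(mean(tr$run_nt) / target - 1), 0.02)

  # velocity floor and truncated-Gaussian mean
  expect_true(all(tr$v_nt_s >= preset$v_min_nt_s))
  rpa <- simulate_trajectories(motor_preset("rpa"), 10000,
                               molecule_length_nt = 1e7, recording_s = 1e7,
                               seed = 12)
  # for this condition the truncation at 5 nt/s shifts the mean up by a
  # known amount: E[max-truncated] = mu + sd * dnorm(a)/(1 - pnorm(a))
  a <- (5 - 47) / 37
  expected <- 47 + 37 * dnorm(a) / (1 - pnorm(a))
  expect_lt(abs(mean(rpa$v_nt_s) - expected), 3 * 37 / sqrt(10000) + 0.5)

  # empirical survival at one half-life is 1/2 within binomial error
  s <- mean(tr$run_nt >= preset$halflife_knt * 1000)
  expect_lt(abs(s - 0.5), 4 * sqrt(0.25 / 10000))

  # seed determinism
  expect_equal(tr, simulate_trajectories(preset, 10000,
                                         molecule_length_nt = 1e7,
                                         recording_s = 1e7, seed = 11))
})

test_that("translocation-incompetent events are static and persistent", {
  tr <- simulate_trajectories(motor_preset("dmc1"), 500, seed = 5,
                              recording_s = 1200)
  expect_true(all(tr$run_nt == 0))
  expect_true(all(tr$v_nt_s == 0))
  expect_true(all(tr$t_end_s == 1200))
})

test_that("binding sites follow the cluster landscape", {
  cl <- place_clusters(150000, 5, seed = 2)
  preset <- motor_preset("rad51", p_coloc = 1)
  tr <- simulate_trajectories(preset, 200, clusters = cl, seed = 3)
  expect_true(all(tr$x0_nt %in% cl$position_nt))
  expect_true(all(tr$coloc))
  # missing clusters with p_coloc > 0 warn and fall back to uniform
  expect_warning(
    tr2 <- simulate_trajectories(preset, 50, clusters = NULL, seed = 3),
    "uniform")
  expect_false(any(tr2$coloc))
})

test_that("simulated curtains draw Poisson event counts per molecule", {
  cur <- simulate_curtain(motor_preset("rad51"), n_molecules = 300, seed = 9)
  counts <- table(factor(cur$trajectories$molecule_id,
                         levels = seq_len(300)))
  expect_equal(length(counts), 300)
  expect_lt(abs(mean(counts) - 3), 4 * sqrt(3 / 300))
})

test_that("ATPase time courses follow the closed form", {
  t100 <- simulate_atpase(256, 1e-9, 2e-3, times_s = 100)
  expect_equal(t100$frac_hydrolyzed, 256 * 1e-9 * 100 / 2e-3) # = 0.0128
  flat <- simulate_atpase(0, 1e-9, 2e-3, times_s = c(10, 100, 1000))
  expect_true(all(flat$frac_hydrolyzed == 0))
  # linearity in enzyme concentration (early regime)
  a <- simulate_atpase(256, 1e-9, 2e-3, times_s = c(10, 20, 30))
  b <- simulate_atpase(256, 2e-9, 2e-3, times_s = c(10, 20, 30))
  expect_equal(b$frac_hydrolyzed, 2 * a$frac_hydrolyzed)
  # saturation and rejection
  expect_true(all(simulate_atpase(256, 1e-6, 2e-3, 1e6)$frac_hydrolyzed == 1))
  expect_error(simulate_atpase(256, 1e-9, 0, 100), "atp_conc")
})
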