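test_that("spot detection finds nothing in blank frames and localises to sub-pixel", {
  acq <- quiet_acq()
  blank <- new_kymograph(list(green = matrix(0, acq$n_frames, acq$n_pixels)), acq)
  expect_equal(nrow(detect_spots(blank, "green")), 0)

  # noise-free Gaussian spot centred at 10.30 px -> position within 0.1 px
  ky <- render_kymograph(one_event(10300, 0, 0, recording_s = 1e6), acq,
                         mode = "dmc1", noise = FALSE)
  sp <- detect_spots(ky, "green")
  expect_equal(nrow(sp), acq$n_frames)
  expect_true(all(abs(sp$position_px - 10.30) < 0.1))

  # two spots five PSF widths apart are both found
  two <- dplyr::bind_rows(one_event(10000, 0, 0, recording_s = 1e6),
                          one_event(15000, 0, 0, recording_s = 1e6))
  ky2 <- render_kymograph(two, acq, mode = "dmc1", noise = FALSE)
  sp2 <- detect_spots(ky2, "green")
  expect_equal(nrow(sp2), 2 * acq$n_frames)
  expect_setequal(round(sp2$position_px[sp2$frame == 0]), c(10, 15))
})

test_that("linking builds single, gap-bridged, non-crossing trajectories", {
  # one spot per frame at constant position -> exactly one 20-spot trajectory
  sp <- spot_table(0:19, rep(12, 20))
  lk <- link_spots(sp)
  expect_equal(length(unique(lk$traj_id)), 1)
  expect_equal(nrow(lk), 20)

  # a single missing frame is bridged when max_gap_frames = 1
  gap <- spot_table(setdiff(0:10, 5), rep(7, 10))
  expect_equal(length(unique(link_spots(gap, max_gap_frames = 1)$traj_id)), 1)
  expect_equal(length(unique(link_spots(gap, max_gap_frames = 0)$traj_id)), 2)

  # two parallel tracks 10 px apart never cross-link at max_jump 3
  par2 <- dplyr::bind_rows(spot_table(0:9, rep(5, 10)),
                           spot_table(0:9, rep(15, 10)))
  lk2 <- link_spots(par2, max_jump_px = 3)
  expect_equal(length(unique(lk2$traj_id)), 2)
  by_traj <- split(lk2$position_px, lk2$traj_id)
  expect_true(all(vapply(by_traj, function(p) diff(range(p)) == 0, logical(1))))

  # no spot is assigned twice and short tracks are discarded
  expect_lte(max(table(paste(lk2$frame, lk2$traj_id))), 1)
  expect_equal(nrow(link_spots(spot_table(0:1, c(3, 3)))), 0) # < min_frames
})

test_that("trajectory measurement applies the nt conversion and classifies direction", {
  acq <- acquisition_params()
  # net displacement 5 px over 100 s at 1000 nt/px -> 5000 nt at 50 nt/s
  sp <- spot_table(0:10, seq(20, 15, length.out = 11))
  meas <- measure_trajectories(link_spots(sp), acq)
  expect_equal(meas$run_length_nt, 5000)
  expect_equal(meas$duration_s, 100)
  expect_equal(meas$velocity_nt_s, 50)
  expect_equal(meas$direction_sign, -1)
  expect_true(meas$translocating)

  # zero net displacement -> run 0, velocity 0, non-translocating
  still <- measure_trajectories(link_spots(spot_table(0:5, rep(9, 6))), acq)
  expect_equal(still$run_length_nt, 0)
  expect_equal(still$velocity_nt_s, 0)
  expect_false(still$translocating)
})

test_that("tracking is invariant under uniform intensity scaling", {
  acq <- quiet_acq()
  ky <- render_kymograph(one_event(30000, 30, 9000), acq, mode = "rpa",
                         noise = FALSE, coat_photons = 0)
  scaled <- new_kymograph(list(green = ky$channels$green * 7), acq)
  m1 <- measure_trajectories(link_spots(detect_spots(ky, "green")), acq)
  m2 <- measure_trajectories(link_spots(detect_spots(scaled, "green")), acq)
  expect_equal(m1$run_length_nt, m2$run_length_nt, tolerance = 1e-10)
  expect_equal(m1$velocity_nt_s, m2$velocity_nt_s, tolerance = 1e-10)
})

test_that("noise-free tracking recovers simulated kinematics to quantization error", {
  acq <- quiet_acq(n_frames = 40, n_pixels = 60)
  # known velocity 30 nt/s over 6 knt starting at 50 knt
  ev <- one_event(50000, 30, 6000)
  ky <- render_kymograph(ev, acq, mode = "rpa", noise = FALSE,
                         coat_photons = 0)
  meas <- measure_trajectories(link_spots(detect_spots(ky, "green")), acq)
  expect_equal(nrow(meas), 1)
  # velocity within one pixel-quantization of truth
  expect_lt(abs(meas$velocity_nt_s - 30), 1000 / meas$duration_s)
  expect_lt(abs(meas$x_start_nt - 50000), 1000)
  expect_lt(abs(meas$x_end_nt - 44000), 1000)

  # the regression-slope alternative agrees within 10 %
  lk <- link_spots(detect_spots(ky, "green"))
  slope <- measure_trajectories_slope(lk, acq)
  expect_lt(abs(slope$velocity_slope_nt_s / meas$velocity_nt_s - 1), 0.1)
})

test_that("ground-truth recovery holds across a noise-free batch", {
  acq <- quiet_acq(n_frames = 80, n_pixels = 100)
  preset <- motor_preset("k191r", p_coloc = 0)
  gt <- simulate_trajectories(preset, 12, molecule_length_nt = 99000,
                              recording_s = 790, seed = 21)
  ok <- 0
  for (i in seq_len(nrow(gt))) {
    ky <- render_kymograph(gt[i, ], acq, mode = "rad51", noise = FALSE,
                           tract_photons = 0)
    meas <- measure_trajectories(link_spots(detect_spots(ky, "green")), acq)
    dur_frames <- (gt$t_end_s[i] - gt$t0_s[i]) / acq$frame_interval_s
    if (dur_frames < 3) next # below the detection floor by design
    expect_equal(nrow(meas), 1)
    expect_lt(abs(meas$x_start_nt - gt$x0_nt[i]), 1000)
    expect_lt(abs(meas$x_end_nt - (gt$x0_nt[i] - gt$run_nt[i])), 1500)
    ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("binding events are classified against the cluster landscape", {
  cl <- place_clusters(150000, 3, seed = 6)
  traj <- tibble::tibble(molecule_id = 1L,
                         x_start_nt = c(cl$position_nt[1], cl$position_nt[2] + 10000),
                         t_start_s = c(0, 10),
                         translocating = c(TRUE, FALSE))
  ev <- classify_events(traj, cl, coloc_threshold_nt = 1000)
  expect_true(ev$colocalized[1])
  # an event 10 knt from the nearest cluster is not colocalized unless a
  # different cluster happens to lie closer
  dmin <- min(abs(cl$position_nt - traj$x_start_nt[2]))
  expect_equal(ev$colocalized[2], dmin <= 1000)
  # empty cluster set -> nothing colocalizes
  ev0 <- classify_events(traj, cl[0, ])
  expect_false(any(ev0$colocalized))
})

test_that("the colocalized fraction of a simulated condition is recovered", {
  # ground-truth events at p_coloc = 0.79, n = 342, classified back against
  # the same landscape; recovery within the binomial 95% band around 0.79
  # (plus the small chance-overlap inflation from uniform events near
  # clusters)
  cl <- place_clusters(150000, 9, seed = 31)
  preset <- motor_preset("rad51")
  tr <- simulate_trajectories(preset, 342, clusters = cl, seed = 31)
  traj <- tibble::tibble(molecule_id = 1L, x_start_nt = tr$x0_nt,
                         t_start_s = tr$t0_s, translocating = TRUE)
  ev <- classify_events(traj, cl, coloc_threshold_nt = 1000)
  res <- coloc_fraction(ev, n_boot = 200, seed = 1)
  expect_gt(res$fraction, 0.79 - 1.96 * sqrt(0.79 * 0.21 / 342))
  expect_lt(res$fraction, 0.79 + 0.05 + 1.96 * sqrt(0.79 * 0.21 / 342))
})
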