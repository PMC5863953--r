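test_that("multi-sine target matches direct evaluation and its invariants", {
  # frozen waveform coefficients
  comp <- target_components()
  expect_equal(comp$amplitude, c(-7.8, 1.6, 9.4, -10.6))
  expect_equal(comp$frequency, c(0.12, 0.28, 0.37, 0.64))

  # all sine terms vanish at tau = 0
  tr0 <- generate_target(phase_offset = 0)
  expect_equal(tr0$position[1], 0)

  # phase_offset = 5 at t = 10 equals direct evaluation at tau = 15
  tr5 <- generate_target(phase_offset = 5, dt = 0.005)
  i10 <- which(abs(tr5$times - 10) < 1e-9)
  expect_equal(tr5$position[i10], eval_multisine(15), tolerance = 1e-12)

  # amplitude bound and length invariant
  expect_true(max(abs(tr5$position)) <= 7.8 + 1.6 + 9.4 + 10.6)
  expect_equal(length(tr5$position), length(tr5$times))

  # velocity is the analytic derivative (central-difference check)
  v_num <- diff(tr5$position[c(i10 - 1, i10 + 1)]) / (2 * 0.005)
  expect_equal(tr5$velocity[i10], v_num, tolerance = 1e-4)

  # deterministic: equal arguments give bit-identical trajectories
  expect_identical(generate_target(phase_offset = 3)$position,
                   generate_target(phase_offset = 3)$position)

  expect_error(generate_target(duration = -1), "duration")
  expect_error(generate_target(dt = 0), "dt")
  expect_error(generate_target(phase_offset = 31), "phase_offset")
})

test_that("target spectrum has power only at the four component frequencies", {
  tr <- generate_target(duration = 400, dt = 0.05, phase_offset = 0)
  x <- tr$position
  n <- length(x)
  sp <- Mod(stats::fft(x))^2
  freq_rad <- 2 * pi * (seq_len(n) - 1) / (n * 0.05)
  keep <- freq_rad > 0.01 & freq_rad < 2
  peaks <- freq_rad[keep][sp[keep] > max(sp[keep]) / 100]
  for (f in c(0.12, 0.28, 0.37, 0.64)) {
    expect_true(any(abs(peaks - f) < 2 * pi / (n * 0.05) * 2))
  }
  # nothing far from the four components
  expect_true(all(vapply(peaks, function(p) {
    min(abs(p - c(0.12, 0.28, 0.37, 0.64))) < 0.05
  }, logical(1))))
})

test_that("spot cloud has the display geometry and calibrated spread", {
  tr <- generate_target(duration = 40, phase_offset = 0)
  cl <- render_cloud(tr, spread = 2, seed = 1)
  expect_equal(nrow(cl$spots), 100)  # 40 s at one frame per 0.4 s
  expect_equal(ncol(cl$spots), 10)

  # near-degenerate spread: spots collapse onto the target
  cl0 <- render_cloud(tr, spread = 1e-9, seed = 1)
  centres <- tr$position[pmin(length(tr$times),
                              floor(cl0$frame_times / tr$dt) + 1L)]
  expect_equal(as.vector(cl0$spots), rep(centres, 10), tolerance = 1e-6)

  # Monte-Carlo: empirical spot variance around the target ~ spread^2
  cl_big <- render_cloud(tr, spread = 3, spot_count = 200, seed = 2)
  dev <- sweep(cl_big$spots, 1, tr$position[pmin(length(tr$times),
               floor(cl_big$frame_times / tr$dt) + 1L)])
  expect_equal(stats::var(as.vector(dev)), 9, tolerance = 0.05 * 9)

  expect_error(render_cloud(tr, spread = 0), "spread")
})

test_that("trial schedule has the block structure and fair coin", {
  s <- build_schedule(seed = 7)
  expect_equal(nrow(s), 45)
  expect_equal(as.vector(table(s$block)), rep(15L, 3))
  expect_equal(s$level[1], "medium")
  expect_setequal(unique(s$level), c("hard", "medium", "soft"))
  expect_equal(unique(s$stiffness[s$level == "hard"]), 17.2)
  expect_equal(unique(s$stiffness[s$level == "soft"]), 0.3)

  # reproducible under a fixed seed
  expect_identical(build_schedule(seed = 7), build_schedule(seed = 7))

  # connected trials are Bernoulli(1/2): total count over many schedules
  # inside the 99% binomial band
  n_sched <- 200
  total <- sum(vapply(seq_len(n_sched), function(i) {
    sum(build_schedule(seed = i)$connected)
  }, numeric(1)))
  n <- 45 * n_sched
  band <- stats::qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(total, band[1])
  expect_lte(total, band[2])

  # forced orders
  expect_equal(attr(build_schedule("medium-hard-soft"), "order"), 1L)
  expect_equal(attr(build_schedule("medium-soft-hard"), "order"), 0L)
})

test_that("trajectory and schedule exports round-trip", {
  tr <- short_traj()
  f1 <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f1)
  back <- utils::read.csv(f1)
  expect_equal(back$target_deg, tr$position, tolerance = 1e-9)

  s <- build_schedule(seed = 1)
  f2 <- tempfile(fileext = ".json")
  write_schedule_json(s, f2)
  obj <- jsonlite::read_json(f2, simplifyVector = TRUE)
  expect_equal(obj$order, attr(s, "order"))
  expect_equal(nrow(obj$trials), 45)
  unlink(c(f1, f2))
})
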