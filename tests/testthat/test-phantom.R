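test_that("systolic waveform is a half-sine over the ejection window", {
  wf <- list(onset = 100, t_sys = 300)
  expect_equal(jet_waveform(100 + 150, wf), 1.0)
  expect_equal(jet_waveform(100, wf), 0.0)
  expect_equal(jet_waveform(100 + 75, wf), sin(pi / 4))
  expect_equal(jet_waveform(50, wf), 0.0)        # before onset
  expect_equal(jet_waveform(500, wf), 0.0)       # diastole
  expect_equal(jet_waveform(500, c(wf, regurg_frac = 0.2)), -0.2)
  expect_error(jet_waveform(0, list(onset = 0, t_sys = 0)), "t_sys")
})

test_that("aligned jet puts all velocity through-plane", {
  f <- aligned_jet_field(peak = 300, tilt = 0, nf = 16)
  wmax <- max(jet_waveform((0:15) * 40, list(onset = 0, t_sys = 300)))
  expect_equal(max(f$vz), 300 * wmax, tolerance = 1e-12)
  expect_equal(max(abs(f$vx)), 0)
  expect_equal(max(abs(f$vy)), 0)
})

test_that("tilted jet projects by cos/sin and preserves speed", {
  f <- aligned_jet_field(peak = 200, tilt = 30, azimuth = 35, nf = 16)
  wmax <- max(jet_waveform((0:15) * 40, list(onset = 0, t_sys = 300)))
  expect_equal(max(f$vz), 200 * cos(pi / 6) * wmax, tolerance = 1e-10)
  speed <- sqrt(f$vx^2 + f$vy^2 + f$vz^2)
  expect_equal(max(speed), 200 * wmax, tolerance = 1e-10)
  # speed invariance across tilt (jet core is a sampled pixel)
  for (th in c(0, 10, 25, 40)) {
    fth <- aligned_jet_field(peak = 200, tilt = th, azimuth = 35, nf = 16)
    sp <- sqrt(fth$vx^2 + fth$vy^2 + fth$vz^2)
    expect_equal(max(sp), 200 * wmax, tolerance = 0.01)
  }
})

test_that("empty configuration yields an all-zero field", {
  f <- make_velocity_field(small_plane(32, 8), list(),
                           base_flow = list(peak_speed = 0))
  expect_equal(max(abs(f$vx) + abs(f$vy) + abs(f$vz)), 0)
})

test_that("velocities vanish outside the lumen and jets must sit inside it", {
  f <- aligned_jet_field(peak = 300, sigma = 14)
  out <- !f$lumen_mask
  for (fr in 1:4) {
    expect_equal(max(abs(f$vz[fr, , ][out])), 0)
    expect_equal(max(abs(f$vx[fr, , ][out])), 0)
  }
  expect_error(
    make_velocity_field(small_plane(32, 8),
                        list(jet_spec(center_xy = c(20, 0))),
                        lumen_radius = 15),
    "jet 1")
})

test_that("ground-truth flux matches the closed-form parabolic integral", {
  vp <- 100; r_mm <- 12; nf <- 16; dt <- 40
  pl <- plane_spec(96, 96, pixel_size = 0.4, n_frames = nf, frame_dt = dt)
  f <- make_velocity_field(pl, list(),
                           base_flow = list(peak_speed = vp,
                                            waveform = list(onset = 0, t_sys = 300)),
                           lumen_radius = r_mm)
  tr <- ground_truth_summary(f)
  w <- jet_waveform((0:(nf - 1)) * dt, list(onset = 0, t_sys = 300))
  analytic <- (vp / 2) * pi * (r_mm / 10)^2 * sum(w) * dt / 1000
  expect_equal(tr$true_sv, analytic, tolerance = 0.01)
  # independent oracle: fine-grid Riemann sum of the same profile
  h <- 0.02  # cm
  g <- seq(-r_mm / 10, r_mm / 10, by = h)
  rr <- outer(g^2, g^2, "+")
  fine_flux <- sum(ifelse(rr <= (r_mm / 10)^2, vp * (1 - rr / (r_mm / 10)^2), 0)) * h^2
  expect_equal((vp / 2) * pi * (r_mm / 10)^2, fine_flux, tolerance = 0.005)
})

test_that("uniform flow integrates with the rectangle rule", {
  # 10 cm/s over a known lumen area for 1 s of frames
  f <- uniform_vz_field(10, n = 20, nf = 10)
  f$plane$frame_dt <- 100  # 10 frames x 100 ms = 1 s
  area_cm2 <- 400 * (1.95 / 10)^2
  expect_equal(ground_truth_summary(f)$true_sv, 10 * area_cm2 * 1)
  z <- uniform_vz_field(0, n = 20, nf = 10)
  expect_equal(ground_truth_summary(z)$true_sv, 0)
})

test_that("subjects are severity-graded, plane-ordered, and reproducible", {
  planes <- default_planes(grid_n = 48, n_frames = 16)
  sev <- make_subject("severe", planes = planes, seed = 11)
  pk <- sev$truth$true_peak_speed_per_plane
  expect_gt(max(pk), 400)
  expect_gt(pk[["0"]], pk[["2"]])   # jet decays with distance above the valve
  expect_equal(pk[["0"]], pk[["1"]])
  none <- make_subject("none", planes = planes, seed = 11)
  expect_lt(max(none$truth$true_peak_speed_per_plane), 200)
  again <- make_subject("severe", planes = planes, seed = 11)
  expect_identical(sev$fields[[2]]$vz, again$fields[[2]]$vz)
  expect_error(make_subject("critical", planes = planes, seed = 1), "severity")
})

test_that("LVOT flux is matched to the aortic flux by construction", {
  s <- make_subject("moderate", planes = default_planes(grid_n = 64, n_frames = 16),
                    seed = 5)
  sv <- s$truth$true_sv_per_plane
  expect_equal(unname(sv[["-1"]]), unname(sv[["0"]]), tolerance = 0.02)
})

test_that("Doppler simulation obeys the beam-projection law", {
  f <- aligned_jet_field(peak = 300, tilt = 0, nf = 16)
  tr <- ground_truth_summary(f)
  truth_peak <- max(tr$true_peak_speed_per_plane)
  m <- simulate_tte(list(f), tr, beam_windows = list(c(0, 0, 1)))
  expect_equal(m$vpeak_ms, truth_peak / 100, tolerance = 1e-10)

  f30 <- aligned_jet_field(peak = 300, tilt = 30, azimuth = 70, nf = 16)
  tr30 <- ground_truth_summary(f30)
  tp30 <- max(tr30$true_peak_speed_per_plane)
  # misaligned beam only: projection loss of cos(30 deg)
  m_normal <- simulate_tte(list(f30), tr30, beam_windows = list(c(0, 0, 1)))
  expect_equal(m_normal$vpeak_ms, tp30 * cos(pi / 6) / 100, tolerance = 1e-10)
  # a window parallel to the jet axis recovers the full speed
  th <- 30 * pi / 180; ph <- 70 * pi / 180
  axis <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  m_best <- simulate_tte(list(f30), tr30,
                         beam_windows = list(c(0, 0, 1), axis))
  expect_equal(m_best$vpeak_ms, tp30 / 100, tolerance = 1e-10)
  expect_error(simulate_tte(list(f30), tr30, beam_windows = list()), "non-empty")
  expect_error(simulate_tte(list(f30), tr30, beam_windows = list(c(1, 1, 0))),
               "unit-norm")
})
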