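test_that("speed map is the pixel-wise vector magnitude", {
  expect_equal(speed_map(list(vx = 0.3, vy = 0.4, vz = 1.2)), 1.3)
  expect_equal(speed_map(list(vx = 0, vy = 0, vz = -2)), 2)
  expect_equal(speed_map(list(vx = 0, vy = 0, vz = 0)), 0)
  a <- array(3, c(2, 4, 4)); b <- array(4, c(2, 4, 4)); z <- array(0, c(2, 4, 4))
  expect_equal(speed_map(list(vx = a, vy = b, vz = z)), array(5, c(2, 4, 4)))
})

test_that("thresholds keep the flowing blood pool and drop the rest", {
  f <- aligned_jet_field(peak = 250, n = 32, nf = 16, sigma = 10)
  m <- decode_velocities(encode_four_point(f, venc = 300), alias_cfg = NULL)
  mask <- threshold_mask(m, mode = "3Dir")
  expect_false(any(mask & !f$lumen_mask))    # background excluded
  core <- which(f$lumen_mask & apply(speed_map(m), c(2, 3), mean) >= 0.05 * 300)
  expect_true(all(mask[core]))
  # a lumen pixel with zero flow in all frames is dropped by the flow floor
  m2 <- m
  m2$vx[, 16, 20] <- 0; m2$vy[, 16, 20] <- 0; m2$vz[, 16, 20] <- 0
  expect_false(threshold_mask(m2, mode = "3Dir")[16, 20])
  # nothing survives in a still phantom
  still <- decode_velocities(encode_four_point(uniform_vz_field(0), venc = 200),
                             alias_cfg = NULL)
  expect_error(threshold_mask(still, mode = "3Dir"), "no pixels survive")
})

test_that("peak-velocity curve tracks the jet waveform per mode", {
  f <- aligned_jet_field(peak = 300, tilt = 0, n = 48, nf = 16)
  m <- decode_velocities(encode_four_point(f, venc = 350), alias_cfg = NULL)
  mask <- threshold_mask(m, mode = "3Dir", roi = f$lumen_mask)
  cv <- peak_velocity_curve(m, mask, mode = "3Dir")
  w <- jet_waveform((0:15) * 40, list(onset = 0, t_sys = 300))
  expect_equal(cv$v, 300 * w, tolerance = 1e-6)

  f30 <- aligned_jet_field(peak = 300, tilt = 30, azimuth = 120, n = 48, nf = 16)
  m30 <- decode_velocities(encode_four_point(f30, venc = 350), alias_cfg = NULL)
  mask30 <- threshold_mask(m30, mode = "3Dir", roi = f30$lumen_mask)
  c1 <- peak_velocity_curve(m30, mask30, mode = "1Dir")
  c3 <- peak_velocity_curve(m30, mask30, mode = "3Dir")
  expect_equal(max(c1$v) / max(c3$v), cos(pi / 6), tolerance = 1e-6)

  zero <- uniform_vz_field(0, n = 16, nf = 8)
  mz <- decode_velocities(encode_four_point(zero, venc = 200), alias_cfg = NULL)
  cz <- peak_velocity_curve(mz, matrix(TRUE, 16, 16), mode = "3Dir")
  expect_equal(max(cz$v), 0)
})

test_that("plane selection takes the highest peak, ties to the lowest index", {
  mk <- function(peak, idx) peak_curve(c(0, 40, 80), c(0, peak, 0), idx)
  expect_equal(select_plane(list(mk(300, 0L), mk(320, 1L), mk(290, 2L))), 1L)
  expect_equal(select_plane(list(mk(300, 0L), mk(300, 1L), mk(300, 2L))), 0L)
  expect_equal(select_plane(list(mk(250, 2L))), 2L)
  # order of the list must not matter for the tie-break
  expect_equal(select_plane(list(mk(300, 2L), mk(300, 0L))), 0L)
})

test_that("mean velocity honours its averaging window", {
  const <- peak_curve(seq(0, 400, by = 40), rep(200, 11), 0L)
  expect_equal(v_mean(const, "ejection"), 2)
  expect_equal(v_mean(const, "full_cycle"), 2)
  hs <- dense_half_sine(vp = 300)
  # a curve spanning exactly the systole: full-curve mean is the ejection mean
  expect_equal(v_mean(hs, "full_cycle"), (2 / pi) * 3, tolerance = 0.01)
  # Riemann oracle over the same frames the ejection window retains
  sel <- hs$v > 0.05 * max(hs$v)
  expect_equal(v_mean(hs, "ejection"), mean(hs$v[sel]) / 100)
  expect_equal(v_mean(peak_curve(0:5, rep(0, 6), 0L)), 0)
})

test_that("Bernoulli gradients follow 4 V^2 and its time average", {
  expect_equal(bernoulli_gradient(3), 36)
  expect_equal(bernoulli_gradient(1), 4)
  expect_equal(bernoulli_gradient(0), 0)
  expect_error(bernoulli_gradient(-1), ">= 0")
  hs <- dense_half_sine(vp = 400)
  # mean of sin^2 over the half period is 1/2: MG -> 4 * 16 * 0.5 = 32 mmHg
  expect_equal(mean_gradient(hs, "full_cycle"), 32, tolerance = 0.01)
  # Riemann oracle on the ejection window
  sel <- hs$v > 0.05 * max(hs$v)
  expect_equal(mean_gradient(hs, "ejection"), mean(4 * (hs$v[sel] / 100)^2))
  # MG never exceeds PG
  expect_lte(mean_gradient(hs), bernoulli_gradient(max(hs$v) / 100))
})

test_that("VTI integrates the curve in cm and scales linearly", {
  const <- peak_curve(seq(0, 300, length.out = 31), rep(100, 31), 0L)
  expect_equal(vti(const), 30)
  hs <- dense_half_sine(vp = 300, t_sys = 300)
  expect_equal(vti(hs), (2 / pi) * 300 * 0.3, tolerance = 0.001)
  hs2 <- hs; hs2$v <- 2.5 * hs2$v
  expect_equal(vti(hs2), 2.5 * vti(hs), tolerance = 1e-12)
  expect_equal(vti(peak_curve(0:10, rep(0, 11), 0L)), 0)
})

test_that("PC stroke volume integrates through-plane flux", {
  f <- uniform_vz_field(10, n = 20, nf = 10)
  f$plane$frame_dt <- 100
  m <- decode_velocities(encode_four_point(f, venc = 100), alias_cfg = NULL)
  roi <- matrix(TRUE, 20, 20)
  expect_equal(stroke_volume_pc(m, roi), 10 * 400 * (1.95 / 10)^2 * 1,
               tolerance = 1e-9)
  mz <- decode_velocities(encode_four_point(uniform_vz_field(0, 20, 10), venc = 100),
                          alias_cfg = NULL)
  expect_equal(stroke_volume_pc(mz, roi), 0)
  # phantom oracle: decoded flux matches ground truth with no noise
  fj <- aligned_jet_field(peak = 250, n = 48, nf = 16)
  mj <- decode_velocities(encode_four_point(fj, venc = 300), alias_cfg = NULL)
  expect_equal(stroke_volume_pc(mj, fj$lumen_mask),
               ground_truth_summary(fj)$true_sv, tolerance = 0.02)
})

test_that("valve-area formulas and their identity limits hold", {
  expect_equal(lvot_area(2.0), pi)
  expect_equal(lvot_area(0), 0)
  expect_equal(lvot_area(2.4), 1.44 * pi)
  expect_error(lvot_area(-1), ">= 0")
  expect_equal(ava_continuity(3.0, 20, 60), 1.0)
  expect_equal(ava_continuity(2.5, 37, 37), 2.5)   # VTI ratio of 1
  expect_equal(ava_cine(60, 100), 0.6)
  expect_equal(ava_flow(60, 100), 0.6)
  expect_error(ava_continuity(3, 20, 0), "vti_av")
  expect_error(ava_cine(60, -2), "vti_av")
})

test_that("subject quantification recovers phantom truth per mode", {
  planes <- lapply(0:2, function(i) small_plane(48, 16, idx = i))
  jet <- function(pk, tilt) list(jet_spec(peak_speed = pk, tilt_polar = tilt,
                                          tilt_azimuth = 40, sigma = 5))
  fields <- lapply(seq_along(planes), function(i)
    make_velocity_field(planes[[i]], jet(c(430, 430, 380)[i], 25),
                        lumen_radius = 15))
  tr <- ground_truth_summary(fields)
  maps <- lapply(fields, function(f)
    decode_velocities(encode_four_point(f, venc = 500)))
  rois <- lapply(fields, function(f) f$lumen_mask)

  r3 <- quantify_subject(maps, rois = rois, mode = "3Dir", sv_cine = 80)
  r1 <- quantify_subject(maps, rois = rois, mode = "1Dir", sv_cine = 80)
  truth_peak <- max(tr$true_peak_speed_per_plane) / 100
  expect_equal(r3$vpeak_ms, truth_peak, tolerance = 0.01)
  expect_equal(r1$vpeak_ms, truth_peak * cos(25 * pi / 180), tolerance = 0.01)
  expect_equal(r3$pg_mmhg, 4 * r3$vpeak_ms^2, tolerance = 1e-9)
  expect_gte(r3$vpeak_ms, r3$vmean_ms)
  expect_equal(r3$selected_plane, 0L)
  expect_equal(r3$ava_cine_cm2, 80 / r3$vti_cm)
  # aligned jet: both modes coincide
  fal <- aligned_jet_field(peak = 300, n = 48, nf = 16)
  mal <- decode_velocities(encode_four_point(fal, venc = 350))
  q3 <- quantify_subject(list(mal), rois = list(fal$lumen_mask), mode = "3Dir")
  q1 <- quantify_subject(list(mal), rois = list(fal$lumen_mask), mode = "1Dir")
  expect_equal(q3$vpeak_ms, q1$vpeak_ms, tolerance = 1e-9)
})

test_that("subjects with unsalvageable aliasing are excluded with a reason", {
  venc <- 200
  f <- uniform_vz_field(1.5 * venc, n = 16, nf = 8)
  m <- decode_velocities(encode_four_point(f, venc))
  m$aliased_flag[["z"]] <- TRUE   # force the salvage path
  r <- quantify_subject(list(m), rois = list(matrix(TRUE, 16, 16)),
                        mode = "3Dir")
  expect_true(r$excluded)
  expect_match(r$exclusion_reason, "salvage failed")
  expect_true(is.na(r$vpeak_ms))
})
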