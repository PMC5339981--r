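#' Acquisition-plane geometry
#'
#' Describes one 2D+time acquisition plane of the digital flow phantom: grid
#' size, pixel spacing, temporal sampling, and where the plane sits relative
#' to the aortic valve. Planes 0, 1 and 2 are contiguous slices just above
#' the valve tips; `plane_index = -1` denotes the LVOT plane just below the
#' annulus.
#'
#' @param grid_nx,grid_ny Grid dimensions in pixels (>= 16).
#' @param pixel_size In-plane pixel spacing in mm.
#' @param n_frames Number of cardiac frames (>= 8).
#' @param frame_dt Temporal resolution in ms.
#' @param plane_index Integer plane label: 0, 1, 2 above the valve, -1 = LVOT.
#' @param plane_offset Distance of the plane above the valve tips, mm.
#' @return An object of class `plane_spec`.
#' @examples
#' plane_spec(grid_nx = 64, grid_ny = 64, n_frames = 16)
#' @export
plane_spec <- function(grid_nx = 96, grid_ny = 96, pixel_size = 1.95,
                       n_frames = 20, frame_dt = 40,
                       plane_index = 0L, plane_offset = 0) {
  if (grid_nx < 16 || grid_ny < 16) stop("grid dimensions must be >= 16 pixels")
  if (pixel_size <= 0) stop("pixel_size must be positive (mm)")
  if (n_frames < 8) stop("n_frames must be >= 8")
  if (frame_dt <= 0) stop("frame_dt must be positive (ms)")
  structure(list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
                 pixel_size = pixel_size, n_frames = as.integer(n_frames),
                 frame_dt = frame_dt, plane_index = as.integer(plane_index),
                 plane_offset = plane_offset),
            class = "plane_spec")
}

#' Stenotic-jet description
#'
#' A jet is modelled as a Gaussian velocity profile in its own cross-section,
#' oriented along an axis tilted away from the plane normal by `tilt_polar`
#' degrees (azimuth `tilt_azimuth`), and modulated in time by a systolic
#' waveform. Multiple jets per subject are allowed (complex valve geometry
#' can split the outflow into two or more jets).
#'
#' @param center_xy Jet core position in the plane, mm (x, y), relative to
#'   the vessel centre.
#' @param sigma Gaussian radius of the jet core, mm (> 0).
#' @param peak_speed Peak speed along the jet axis, cm/s (>= 0).
#' @param tilt_polar Angle between the jet axis and the plane normal, degrees
#'   (0 <= tilt_polar < 90).
#' @param tilt_azimuth In-plane direction of the tilt, degrees.
#' @param waveform List with `onset` (ms), `t_sys` (systole duration, ms) and
#'   optionally `regurg_frac` (fraction of peak speed flowing backwards during
#'   diastole, default 0).
#' @return An object of class `jet_spec`.
#' @export
jet_spec <- function(center_xy = c(0, 0), sigma = 6, peak_speed = 300,
                     tilt_polar = 0, tilt_azimuth = 0,
                     waveform = list(onset = 0, t_sys = 300)) {
  if (sigma <= 0) stop("sigma must be positive (mm)")
  if (peak_speed < 0) stop("peak_speed must be >= 0 (cm/s)")
  if (tilt_polar < 0 || tilt_polar >= 90) stop("tilt_polar must be in [0, 90) degrees")
  if (is.null(waveform$onset)) waveform$onset <- 0
  if (is.null(waveform$regurg_frac)) waveform$regurg_frac <- 0
  structure(list(center_xy = center_xy, sigma = sigma, peak_speed = peak_speed,
                 tilt_polar = tilt_polar, tilt_azimuth = tilt_azimuth,
                 waveform = waveform),
            class = "jet_spec")
}

#' Systolic ejection waveform
#'
#' Half-sine speed multiplier over the systolic window: `sin(pi*(t - onset)/t_sys)`
#' for `t` inside `[onset, onset + t_sys]`, zero (or a constant negative
#' regurgitant fraction, if configured) outside.
#'
#' @param t Time(s) in ms; vectorised.
#' @param params List with `onset` (ms), `t_sys` (ms) and optional
#'   `regurg_frac` in `[0, 1)` (diastolic backflow as a fraction of peak).
#' @return Speed multiplier(s) in `[-regurg_frac, 1]`.
#' @examples
#' jet_waveform(150, list(onset = 0, t_sys = 300))  # 1 at mid-systole
#' @export
jet_waveform <- function(t, params) {
  onset <- if (is.null(params$onset)) 0 else params$onset
  t_sys <- params$t_sys
  if (is.null(t_sys) || t_sys <= 0) stop("waveform t_sys must be positive (ms)")
  regurg <- if (is.null(params$regurg_frac)) 0 else params$regurg_frac
  u <- (t - onset) / t_sys
  w <- ifelse(u >= 0 & u <= 1, sin(pi * pmin(pmax(u, 0), 1)), -regurg)
  w
}

# pixel-centre coordinates in mm; pixel (n/2 + 1) sits exactly at 0 so the
# vessel/jet centre falls on a sampled point regardless of tilt
.grid_coords <- function(n, pixel_size) (seq_len(n) - 1 - n %/% 2) * pixel_size

.frame_times <- function(plane) (seq_len(plane$n_frames) - 1) * plane$frame_dt

#' Generate a ground-truth velocity field at one plane
#'
#' Builds the three-component velocity field of a circular vessel carrying a
#' baseline parabolic through-plane flow plus one or more tilted Gaussian
#' jets. For a jet with instantaneous axial speed `s(t)` and tilt `theta`,
#' the through-plane contribution is `s(t)*cos(theta)` and the in-plane
#' components `s(t)*sin(theta)*(cos(phi), sin(phi))`; the Gaussian profile is
#' evaluated on the distance from the jet axis, so the in-plane footprint is
#' sheared by the tilt. Velocities are exactly zero outside the lumen.
#'
#' @param plane A [plane_spec()].
#' @param jets List of [jet_spec()] objects (may be empty).
#' @param base_flow List with `peak_speed` (cm/s, centreline speed),
#'   `waveform` (as in [jet_waveform()]) and optional `profile` (radial
#'   exponent n of `v = vp * (1 - (r/R)^n)`; n = 2, the default, is the
#'   parabolic profile, larger n a blunter, plug-like profile);
#'   `peak_speed = 0` disables baseline flow.
#' @param lumen_radius Vessel radius, mm.
#' @param magnitude Two-element list/vector: signal magnitude inside the
#'   lumen and in the background (relative units).
#' @param seed Unused source of randomness kept for interface symmetry; the
#'   field is fully deterministic.
#' @return An object of class `velocity_field`: arrays `vx`, `vy`, `vz`
#'   `[frame, y, x]` in cm/s, `lumen_mask` and `signal_magnitude` `[y, x]`,
#'   and the `plane`.
#' @export
make_velocity_field <- function(plane, jets = list(),
                                base_flow = list(peak_speed = 0,
                                                 waveform = list(onset = 0, t_sys = 300)),
                                lumen_radius = 15,
                                magnitude = c(lumen = 1, background = 0.05),
                                seed = NULL) {
  stopifnot(inherits(plane, "plane_spec"))
  if (inherits(jets, "jet_spec")) jets <- list(jets)
  nx <- plane$grid_nx; ny <- plane$grid_ny; nf <- plane$n_frames
  xs <- .grid_coords(nx, plane$pixel_size)
  ys <- .grid_coords(ny, plane$pixel_size)
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  R2 <- X^2 + Y^2
  lumen <- R2 <= lumen_radius^2

  for (k in seq_along(jets)) {
    j <- jets[[k]]
    if (sum(j$center_xy^2) > lumen_radius^2)
      stop(sprintf("jet %d centre (%.1f, %.1f) mm lies outside the lumen (radius %.1f mm)",
                   k, j$center_xy[1], j$center_xy[2], lumen_radius))
  }

  tt <- .frame_times(plane)
  dims <- c(nf, ny, nx)
  vx <- array(0, dims); vy <- array(0, dims); vz <- array(0, dims)

  base_peak <- if (is.null(base_flow$peak_speed)) 0 else base_flow$peak_speed
  if (base_peak != 0) {
    n_prof <- if (is.null(base_flow$profile)) 2 else base_flow$profile
    prof <- ifelse(lumen,
                   base_peak * (1 - (sqrt(R2) / lumen_radius)^n_prof), 0)
    wb <- jet_waveform(tt, base_flow$waveform)
    for (f in seq_len(nf)) vz[f, , ] <- vz[f, , ] + wb[f] * prof
  }

  for (j in jets) {
    th <- j$tilt_polar * pi / 180
    ph <- j$tilt_azimuth * pi / 180
    u <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))  # unit jet axis
    px <- X - j$center_xy[1]
    py <- Y - j$center_xy[2]
    # squared distance from the jet axis (p has no through-plane component)
    d2 <- px^2 + py^2 - (px * u[1] + py * u[2])^2
    G <- ifelse(lumen, exp(-d2 / (2 * j$sigma^2)), 0)
    w <- j$peak_speed * jet_waveform(tt, j$waveform)
    for (f in seq_len(nf)) {
      vx[f, , ] <- vx[f, , ] + w[f] * G * u[1]
      vy[f, , ] <- vy[f, , ] + w[f] * G * u[2]
      vz[f, , ] <- vz[f, , ] + w[f] * G * u[3]
    }
  }

  mask3 <- array(rep(lumen, each = nf), dims)
  vx[!mask3] <- 0; vy[!mask3] <- 0; vz[!mask3] <- 0

  sig <- ifelse(lumen, magnitude[[1]], magnitude[[2]])
  structure(list(vx = vx, vy = vy, vz = vz,
                 lumen_mask = lumen, signal_magnitude = sig, plane = plane),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  p <- x$plane
  cat(sprintf("<velocity_field> plane %d: %dx%d px @ %.2f mm, %d frames @ %.0f ms\n",
              p$plane_index, p$grid_nx, p$grid_ny, p$pixel_size, p$n_frames, p$frame_dt))
  cat(sprintf("  max speed %.1f cm/s, lumen %d px\n",
              max(sqrt(x$vx^2 + x$vy^2 + x$vz^2)), sum(x$lumen_mask)))
  invisible(x)
}

.field_speed <- function(field) sqrt(field$vx^2 + field$vy^2 + field$vz^2)

#' Ground-truth summary of phantom fields
#'
#' Direct integration of the configured fields, used as the oracle against
#' which the encode/decode/quantify pipeline is checked. Through-plane flux is
#' integrated with the rectangle rule in time (matching the quantification
#' stage), the peak-speed curve is the per-frame spatial maximum, and the
#' effective orifice area is total flux divided by the time integral of the
#' peak-speed curve at the plane with the highest peak.
#'
#' @param fields A `velocity_field` or list of them (one per plane).
#' @param lvot_diameter Optional LVOT diameter (cm) carried into the record.
#' @param severity_label Optional severity label carried into the record.
#' @return An object of class `subject_truth`: per-plane peak speeds (cm/s),
#'   per-plane stroke volumes (mL), `effective_orifice_area` (cm^2).
#' @export
ground_truth_summary <- function(fields, lvot_diameter = NA_real_,
                                 severity_label = NA_character_) {
  if (inherits(fields, "velocity_field")) fields <- list(fields)
  idx <- vapply(fields, function(f) f$plane$plane_index, integer(1))
  peaks <- numeric(length(fields)); svs <- numeric(length(fields))
  curves <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    sp <- .field_speed(f)
    peaks[i] <- max(sp)
    px_cm2 <- (f$plane$pixel_size / 10)^2
    dt_s <- f$plane$frame_dt / 1000
    svs[i] <- sum(f$vz) * px_cm2 * dt_s           # cm/s * cm^2 * s = mL
    curves[[i]] <- apply(sp, 1, max)              # cm/s per frame
  }
  aortic <- which(idx >= 0)
  sel <- if (length(aortic)) aortic[which.max(peaks[aortic])] else which.max(peaks)
  dt_s <- fields[[sel]]$plane$frame_dt / 1000
  stroke_dist <- sum(curves[[sel]]) * dt_s        # cm
  eoa <- if (stroke_dist > 0) svs[sel] / stroke_dist else NA_real_
  structure(list(true_peak_speed_per_plane = stats::setNames(peaks, idx),
                 true_sv_per_plane = stats::setNames(svs, idx),
                 true_sv = svs[sel],
                 effective_orifice_area = eoa,
                 selected_plane = idx[sel],
                 lvot_diameter = lvot_diameter,
                 severity_label = severity_label),
            class = "subject_truth")
}

# severity -> peak jet speed bands (m/s), conventional clinical grading
.severity_bands <- list(none = c(1.0, 1.7), mild = c(2.0, 2.9),
                        moderate = c(3.0, 3.9), severe = c(4.2, 5.0))

# severity -> jet core radius (mm); tighter orifice = higher grade, chosen so
# the effective orifice area (~2*pi*sigma^2) spans the clinical EOA bands
.severity_sigma <- list(none = c(6.5, 7.5), mild = c(5.0, 6.4),
                        moderate = c(4.0, 5.0), severe = c(3.2, 4.0))

#' Default phantom plane stack
#'
#' Three contiguous aortic planes (indices 0, 1, 2; 8 mm apart, matching the
#' slice thickness) plus the LVOT plane (index -1).
#' @param grid_n Grid size in pixels (square grid).
#' @param n_frames Frames per cardiac cycle.
#' @param frame_dt Temporal resolution, ms.
#' @param pixel_size Pixel spacing, mm.
#' @return List of [plane_spec()] objects.
#' @export
default_planes <- function(grid_n = 96, n_frames = 20, frame_dt = 40,
                           pixel_size = 1.95) {
  c(list(plane_spec(grid_n, grid_n, pixel_size, n_frames, frame_dt,
                    plane_index = -1L, plane_offset = -10)),
    lapply(0:2, function(i)
      plane_spec(grid_n, grid_n, pixel_size, n_frames, frame_dt,
                 plane_index = i, plane_offset = i * 8)))
}

#' Generate one synthetic subject
#'
#' Draws subject-level parameters from severity-specific distributions and
#' builds the velocity field at every requested plane. The peak jet speed is
#' drawn from conventional clinical grading bands (none < 2, mild 2-3,
#' moderate 3-4, severe > 4 m/s). The jet decays and broadens with distance
#' above the valve (planes 0 and 1 carry higher peaks than plane 2), and the
#' LVOT plane carries a pure parabolic flow whose centreline speed is solved
#' so its integrated flux matches the aortic (plane 0) flux — volume
#' conservation across the valve by construction.
#'
#' @param severity One of `"none"`, `"mild"`, `"moderate"`, `"severe"`.
#' @param planes List of [plane_spec()]; must include at least one aortic
#'   plane (index >= 0). Default [default_planes()].
#' @param seed Integer seed; identical (arguments, seed) give bit-identical
#'   fields.
#' @param params Optional overrides: `tilt_range` (deg, default c(5, 35)),
#'   `sigma_range` (mm; default severity-specific, tighter core for higher
#'   grade), `decay` (per-plane-index peak multipliers), `broaden`
#'   (per-plane-index sigma multipliers), `aortic_radius` (mm), `base_peak`
#'   (cm/s), `t_sys` (ms), `lvot_d_range` (cm), `lvot_profile` (radial
#'   exponent of the blunted LVOT profile), `n_jets`.
#' @return List with `fields` (one `velocity_field` per plane), `truth`
#'   (a `subject_truth`), and `jets`.
#' @export
make_subject <- function(severity, planes = default_planes(), seed = 1L,
                         params = list()) {
  if (!severity %in% names(.severity_bands))
    stop("unknown severity label: ", severity,
         " (expected none/mild/moderate/severe)")
  p <- utils::modifyList(list(
    tilt_range = c(5, 35), sigma_range = NULL,
    decay = c(`0` = 1.0, `1` = 1.0, `2` = 0.85),
    broaden = c(`0` = 1.0, `1` = 1.1, `2` = 1.25),
    aortic_radius = 15,
    base_peak = 50, t_sys = 300, lvot_d_range = c(2.3, 2.7),
    lvot_profile = 8, n_jets = 1L, regurg_frac = 0), params)

  set.seed(seed)
  band <- .severity_bands[[severity]]
  sig_band <- if (is.null(p$sigma_range)) .severity_sigma[[severity]] else p$sigma_range
  peak_ms <- stats::runif(1, band[1], band[2])
  tilt <- stats::runif(1, p$tilt_range[1], p$tilt_range[2])
  azim <- stats::runif(1, 0, 360)
  sigma <- stats::runif(1, sig_band[1], sig_band[2])
  lvot_d <- stats::runif(1, p$lvot_d_range[1], p$lvot_d_range[2])
  wf <- list(onset = 0, t_sys = p$t_sys, regurg_frac = p$regurg_frac)
  # jet amplitude chosen so the total centreline speed (jet + baseline flow)
  # peaks at the drawn severity-band value
  jet_amp <- max(peak_ms * 100 - p$base_peak, 0)

  jets <- list()
  centers <- if (p$n_jets == 1L) list(c(0, 0)) else {
    # secondary jets offset a few mm, each carrying a share of the peak
    lapply(seq_len(p$n_jets), function(k)
      c(4 * (k - 1) * cos(2 * pi * k / p$n_jets),
        4 * (k - 1) * sin(2 * pi * k / p$n_jets)))
  }
  for (k in seq_len(p$n_jets)) {
    jets[[k]] <- jet_spec(center_xy = centers[[k]], sigma = sigma,
                          peak_speed = jet_amp * ifelse(k == 1, 1, 0.7),
                          tilt_polar = tilt, tilt_azimuth = azim,
                          waveform = wf)
  }

  aortic_specs <- Filter(function(pl) pl$plane_index >= 0, planes)
  lvot_specs <- Filter(function(pl) pl$plane_index < 0, planes)
  if (!length(aortic_specs)) stop("at least one aortic plane (index >= 0) is required")

  fields <- list()
  for (pl in aortic_specs) {
    key <- as.character(pl$plane_index)
    dk <- if (key %in% names(p$decay)) p$decay[[key]] else 1
    bk <- if (key %in% names(p$broaden)) p$broaden[[key]] else 1
    jets_pl <- lapply(jets, function(j) {
      j$peak_speed <- j$peak_speed * dk; j$sigma <- j$sigma * bk; j
    })
    fields[[length(fields) + 1L]] <-
      make_velocity_field(pl, jets_pl,
                          base_flow = list(peak_speed = p$base_peak, waveform = wf),
                          lumen_radius = p$aortic_radius)
  }

  # target flux: plane-0 (or first aortic) integrated through-plane flow
  f0 <- fields[[1]]
  px_cm2 <- (f0$plane$pixel_size / 10)^2
  dt_s <- f0$plane$frame_dt / 1000
  target_sv <- sum(f0$vz) * px_cm2 * dt_s

  lvot_radius <- lvot_d * 10 / 2   # cm -> mm
  for (pl in lvot_specs) {
    # solve the centreline speed of the blunted LVOT profile for flux matching
    lv_flow <- list(peak_speed = 100, waveform = wf, profile = p$lvot_profile)
    trial <- make_velocity_field(pl, list(), base_flow = lv_flow,
                                 lumen_radius = lvot_radius)
    trial_sv <- sum(trial$vz) * (pl$pixel_size / 10)^2 * (pl$frame_dt / 1000)
    lv_flow$peak_speed <- if (trial_sv > 0) 100 * target_sv / trial_sv else 0
    fields <- c(list(make_velocity_field(pl, list(), base_flow = lv_flow,
                                         lumen_radius = lvot_radius)),
                fields)
  }

  truth <- ground_truth_summary(fields, lvot_diameter = lvot_d,
                                severity_label = severity)
  list(fields = fields, truth = truth, jets = jets, seed = seed)
}

#' Default Doppler acoustic windows
#'
#' Unit beam vectors emulating the echocardiographic windows interrogated
#' during a TTE exam: the plane normal plus rings of tilted beams. The
#' sonographer sweeps windows searching for alignment with the jet; a denser
#' ring set means better best-case alignment.
#' @param polars Polar angles of the rings, degrees.
#' @param n_azimuth Beams per ring.
#' @return List of unit 3-vectors.
#' @export
default_tte_windows <- function(polars = c(5, 15, 25, 35), n_azimuth = 8) {
  w <- list(c(0, 0, 1))
  for (th in polars * pi / 180) {
    for (ph in (seq_len(n_azimuth) - 1) * 2 * pi / n_azimuth) {
      w[[length(w) + 1L]] <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    }
  }
  w
}

#' Simulate a Doppler-TTE exam on the phantom
#'
#' Continuous-wave Doppler measures only the velocity component parallel to
#' the acoustic beam. For each candidate window the envelope is, per frame,
#' the maximum over lumen pixels and aortic planes of `|v . b|`; the window
#' with the highest envelope is kept for quantification. LVOT velocities are
#' interrogated through-plane at the LVOT plane (pulsed-wave convention) and
#' the valve area follows the continuity equation
#' `AVA = A_LVOT * VTI_LVOT / VTI_AV` with a circular LVOT.
#'
#' @param fields List of `velocity_field`s (aortic planes and, for the
#'   continuity equation, an LVOT plane with index < 0).
#' @param truth A `subject_truth` (supplies the LVOT diameter).
#' @param beam_windows List of unit beam vectors; default
#'   [default_tte_windows()].
#' @return One-row tibble of class `tte_measurement`: `vpeak_ms`, `vmean_ms`,
#'   `mg_mmhg`, `pg_mmhg`, `vti_cm`, `vti_lvot_cm`, `lvot_diameter_cm`,
#'   `ava_cm2`, `method = "TTE"`.
#' @export
simulate_tte <- function(fields, truth, beam_windows = default_tte_windows()) {
  if (inherits(fields, "velocity_field")) fields <- list(fields)
  if (!length(beam_windows)) stop("beam_windows must be non-empty")
  for (b in beam_windows)
    if (abs(sum(b^2) - 1) > 1e-8) stop("beam vectors must be unit-norm")
  aortic <- Filter(function(f) f$plane$plane_index >= 0, fields)
  lvot <- Filter(function(f) f$plane$plane_index < 0, fields)
  if (!length(aortic)) stop("no aortic plane in fields")
  nf <- aortic[[1]]$plane$n_frames

  best <- NULL; best_peak <- -Inf
  for (b in beam_windows) {
    env <- rep(0, nf)
    for (f in aortic) {
      proj <- abs(f$vx * b[1] + f$vy * b[2] + f$vz * b[3])
      env <- pmax(env, apply(proj, 1, max))
    }
    if (max(env) > best_peak) { best_peak <- max(env); best <- env }
  }
  curve <- peak_curve(.frame_times(aortic[[1]]$plane), best,
                      plane_index = NA_integer_)

  vpeak <- max(best) / 100
  vmean <- v_mean(curve)
  mg <- mean_gradient(curve)
  pg <- bernoulli_gradient(vpeak)
  vti_av <- vti(curve)

  vti_lv <- NA_real_; ava <- NA_real_
  if (length(lvot)) {
    fl <- lvot[[1]]
    env_l <- apply(abs(fl$vz), 1, max)
    curve_l <- peak_curve(.frame_times(fl$plane), env_l,
                          plane_index = fl$plane$plane_index)
    vti_lv <- vti(curve_l)
    if (!is.na(truth$lvot_diameter) && vti_av > 0)
      ava <- ava_continuity(lvot_area(truth$lvot_diameter), vti_lv, vti_av)
  }

  out <- tibble::tibble(method = "TTE",
                        vpeak_ms = vpeak, vmean_ms = vmean,
                        mg_mmhg = mg, pg_mmhg = pg,
                        vti_cm = vti_av, vti_lvot_cm = vti_lv,
                        lvot_diameter_cm = truth$lvot_diameter,
                        ava_cm2 = ava)
  class(out) <- c("tte_measurement", class(out))
  out
}
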