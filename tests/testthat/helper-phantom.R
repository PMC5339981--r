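# shared fixtures: small phantoms kept fast enough for repeated use

small_plane <- function(n = 48, nf = 16, dt = 40, idx = 0L) {
  plane_spec(grid_nx = n, grid_ny = n, pixel_size = 1.95, n_frames = nf,
             frame_dt = dt, plane_index = idx)
}

aligned_jet_field <- function(peak = 300, n = 48, nf = 16, sigma = 6,
                              tilt = 0, azimuth = 0) {
  make_velocity_field(
    small_plane(n, nf),
    list(jet_spec(peak_speed = peak, tilt_polar = tilt, tilt_azimuth = azimuth,
                  sigma = sigma, waveform = list(onset = 0, t_sys = 300))),
    lumen_radius = 15)
}

# a field whose lumen pixels carry arbitrary prescribed velocity vectors
# (used to exercise the encoder on exhaustive velocity sets)
raw_field <- function(vx, vy, vz, pixel_size = 1.95, frame_dt = 40) {
  stopifnot(all(dim(vx) == dim(vy)), all(dim(vx) == dim(vz)))
  nf <- dim(vx)[1]; ny <- dim(vx)[2]; nx <- dim(vx)[3]
  pl <- plane_spec(grid_nx = nx, grid_ny = ny, pixel_size = pixel_size,
                   n_frames = nf, frame_dt = frame_dt)
  structure(list(vx = vx, vy = vy, vz = vz,
                 lumen_mask = matrix(TRUE, ny, nx),
                 signal_magnitude = matrix(1, ny, nx), plane = pl),
            class = "velocity_field")
}

# uniform through-plane flow at a constant speed in every frame
uniform_vz_field <- function(v, n = 16, nf = 8) {
  z <- array(v, c(nf, n, n))
  raw_field(array(0, c(nf, n, n)), array(0, c(nf, n, n)), z)
}

dense_half_sine <- function(vp = 300, t_sys = 300, dt = 0.5) {
  t <- seq(0, t_sys, by = dt)
  peak_curve(t, vp * sin(pi * t / t_sys), plane_index = 0L)
}
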