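# Balanced four-point velocity encoding.
#
# The paper names the scheme but not its moment table; the conventional
# balanced Hadamard rows are used here, with moment normalization alpha = 1/4
# so that each *decoded* component wraps exactly at +/-Venc while individual
# encoding phases stay below pi for speeds up to 4*Venc.
.H4 <- rbind(c(-1, -1, -1),
             c(+1, +1, -1),
             c(+1, -1, +1),
             c(-1, +1, +1))

# phase-difference sign vectors: arg(prod_i z_i^{c_di}) isolates 4 * phase of
# one component and cancels any phase common to the four encodings
.C4 <- rbind(x = c(-1, +1, +1, -1),
             y = c(-1, +1, -1, +1),
             z = c(-1, -1, +1, +1))

#' Wrap phase into (-pi, pi]
#'
#' @param phi Phase(s) in radians; finite.
#' @return Values congruent to `phi` modulo 2*pi, in the half-open interval
#'   (-pi, pi].
#' @examples
#' wrap_phase(1.25 * pi)  # -0.75*pi
#' wrap_phase(-pi)        # +pi
#' @export
wrap_phase <- function(phi) {
  if (any(!is.finite(phi))) stop("phase must be finite")
  phi - 2 * pi * ceiling((phi - pi) / (2 * pi))
}

#' Simulate balanced four-point encoding
#'
#' Produces the four complex image series a scanner would acquire: encoding
#' `i` carries phase `phi_i = (pi / (4 * venc)) * (h_i . v) + background_phase`
#' on top of the anatomy's signal magnitude, plus independent complex
#' Gaussian noise. The same Venc applies to all three encoded directions.
#'
#' @param field A `velocity_field`.
#' @param venc Velocity-encoding limit, cm/s (> 0).
#' @param noise_sigma Standard deviation of the complex Gaussian noise
#'   (relative units; lumen magnitude is 1 by default).
#' @param background_phase Constant scalar or `[y, x]` map of spurious phase
#'   (radians) common to all encodings.
#' @param seed Integer seed for the noise draw.
#' @return Object of class `encoded_series`: `complex_images`
#'   `[encoding = 4, frame, y, x]`, plus `venc`, `noise_sigma`,
#'   `background_phase`, `seed`, `plane`.
#' @export
encode_four_point <- function(field, venc, noise_sigma = 0,
                              background_phase = 0, seed = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  if (venc <= 0) stop("venc must be positive (cm/s)")
  pl <- field$plane
  nf <- pl$n_frames; ny <- pl$grid_ny; nx <- pl$grid_nx
  dims <- c(4L, nf, ny, nx)
  imgs <- array(complex(real = 0, imaginary = 0), dims)
  bg <- if (length(background_phase) == 1) {
    array(background_phase, c(nf, ny, nx))
  } else {
    stopifnot(all(dim(background_phase) == c(ny, nx)))
    array(rep(background_phase, each = nf), c(nf, ny, nx))
  }
  mag <- array(rep(field$signal_magnitude, each = nf), c(nf, ny, nx))
  alpha <- pi / (4 * venc)
  for (i in 1:4) {
    phi <- alpha * (.H4[i, 1] * field$vx + .H4[i, 2] * field$vy +
                      .H4[i, 3] * field$vz) + bg
    imgs[i, , , ] <- mag * exp(1i * phi)
  }
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(imgs)
    imgs <- imgs + complex(real = stats::rnorm(n, 0, noise_sigma),
                           imaginary = stats::rnorm(n, 0, noise_sigma))
  }
  structure(list(complex_images = imgs, venc = venc,
                 noise_sigma = noise_sigma,
                 background_phase = background_phase,
                 seed = seed, plane = pl),
            class = "encoded_series")
}

#' Decode per-direction velocity maps from a four-point series
#'
#' Scanner-style phase-difference reconstruction: for direction `d` with sign
#' vector `c_d` over the four encodings, `v_d = (venc / pi) * arg(prod_i
#' z_i^{c_di})` (conjugating where `c_di = -1`). Working on complex products
#' rather than subtracting wrapped phases removes any order-of-wrapping
#' ambiguity; each decoded component wraps into (-venc, venc], and any phase
#' common to the four encodings (e.g. a background phase offset) cancels
#' identically — consistent with applying no background-offset correction
#' downstream. The magnitude image is the pixel-wise minimum of the four
#' encoding magnitudes.
#'
#' @param series An `encoded_series`.
#' @param alias_cfg Configuration list forwarded to [detect_aliasing()], or
#'   `NULL` to skip detection.
#' @return Object of class `velocity_maps`: `vx`, `vy`, `vz` `[frame, y, x]`
#'   (cm/s), `magnitude` `[frame, y, x]`, `venc`, `plane`, `aliased_flag`
#'   (named logical per direction), `alias_pixels`, and
#'   `n_zero_magnitude` (pixels with undefined phase decoded as 0).
#' @export
decode_velocities <- function(series, alias_cfg = list()) {
  stopifnot(inherits(series, "encoded_series"))
  z <- series$complex_images
  venc <- series$venc
  nf <- dim(z)[2]; ny <- dim(z)[3]; nx <- dim(z)[4]
  zl <- lapply(1:4, function(i) array(z[i, , , ], c(nf, ny, nx)))
  mags <- lapply(zl, Mod)
  magnitude <- pmin(mags[[1]], mags[[2]], mags[[3]], mags[[4]])

  decode_dir <- function(cs) {
    P <- array(complex(real = 1, imaginary = 0), c(nf, ny, nx))
    for (i in 1:4) P <- P * (if (cs[i] > 0) zl[[i]] else Conj(zl[[i]]))
    v <- (venc / pi) * Arg(P)
    zero <- Mod(P) == 0
    v[zero] <- 0
    list(v = v, n_zero = sum(zero))
  }
  dx <- decode_dir(.C4["x", ]); dy <- decode_dir(.C4["y", ]); dz <- decode_dir(.C4["z", ])
  n_zero <- dx$n_zero + dy$n_zero + dz$n_zero
  if (n_zero > 0)
    warning(sprintf("%d pixel(s) had zero magnitude; decoded as 0", n_zero))

  maps <- structure(list(vx = dx$v, vy = dy$v, vz = dz$v,
                         magnitude = magnitude, venc = venc,
                         plane = series$plane,
                         aliased_flag = c(x = FALSE, y = FALSE, z = FALSE),
                         alias_pixels = NULL,
                         n_zero_magnitude = n_zero),
                    class = "velocity_maps")
  if (!is.null(alias_cfg)) {
    det <- do.call(detect_aliasing, c(list(maps = maps), alias_cfg))
    maps$aliased_flag <- det$flags
    maps$alias_pixels <- det$pixel_map
  }
  maps
}

#' @export
print.velocity_maps <- function(x, ...) {
  cat(sprintf("<velocity_maps> venc %.0f cm/s, %d frames, %dx%d px; aliased: %s\n",
              x$venc, dim(x$vz)[1], dim(x$vz)[2], dim(x$vz)[3],
              paste(names(x$aliased_flag)[x$aliased_flag], collapse = ",")))
  invisible(x)
}

# vectorized median of 9 via a sorting network (19 min/max exchanges);
# avoids per-pixel apply() calls over the whole image stack
.median9 <- function(p) {
  xch <- function(a, b) list(pmin(p[[a]], p[[b]]), pmax(p[[a]], p[[b]]))
  ex <- function(a, b) { r <- xch(a, b); p[[a]] <<- r[[1]]; p[[b]] <<- r[[2]] }
  ex(2, 3); ex(5, 6); ex(8, 9)
  ex(1, 2); ex(4, 5); ex(7, 8)
  ex(2, 3); ex(5, 6); ex(8, 9)
  ex(1, 4); ex(6, 9); ex(5, 8)
  ex(4, 7); ex(2, 5); ex(3, 6)
  ex(5, 8); ex(5, 3); ex(7, 5); ex(5, 3)
  p[[5]]
}

# 3x3 spatial median of one frame, replicating unavailable neighbours
# (borders / outside-mask) with the centre value so they are sign-neutral
.spatial_median3 <- function(m, mask) {
  ny <- nrow(m); nx <- ncol(m)
  center <- m
  shifts <- list()
  k <- 0
  for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1
    s <- matrix(NA_real_, ny, nx)
    ys <- (1 + max(0, dy)):(ny + min(0, dy))
    xs <- (1 + max(0, dx)):(nx + min(0, dx))
    s[ys - dy, xs - dx] <- m[ys, xs]
    msk <- matrix(FALSE, ny, nx)
    msk[ys - dy, xs - dx] <- mask[ys, xs]
    s[!msk] <- center[!msk]
    shifts[[k]] <- s
  }
  .median9(shifts)
}

#' Detect velocity aliasing in decoded maps
#'
#' Two wrap signatures are checked per direction: (a) pixels whose decoded
#' velocity has the opposite sign to the local 3x3 spatial median inside the
#' analysis mask while that median exceeds half of Venc in magnitude, and
#' (b) frame-to-frame jumps exceeding Venc. A direction is flagged when at
#' least `min_pixels` pixel-frames show either signature.
#'
#' @param maps A `velocity_maps`.
#' @param mask Optional `[y, x]` logical analysis mask; defaults to pixels
#'   whose time-minimum magnitude reaches 50% of the maximum (blood pool).
#' @param median_frac Spatial-signature threshold on `|median| / venc`.
#' @param jump_frac Temporal-jump threshold as a fraction of Venc.
#' @param min_pixels Minimum flagged pixel-frames for a direction flag.
#' @return List: `flags` (named logical x/y/z), `pixel_map` (list of logical
#'   `[frame, y, x]` arrays per direction), `counts`.
#' @export
detect_aliasing <- function(maps, mask = NULL, median_frac = 0.5,
                            jump_frac = 1.0, min_pixels = 4L) {
  stopifnot(inherits(maps, "velocity_maps"))
  venc <- maps$venc
  nf <- dim(maps$vz)[1]
  if (is.null(mask)) {
    tmin <- apply(maps$magnitude, c(2, 3), min)
    mask <- tmin >= 0.5 * max(tmin)
  }
  out_flags <- c(x = FALSE, y = FALSE, z = FALSE)
  pixel_map <- list(); counts <- c(x = 0L, y = 0L, z = 0L)
  for (d in c("x", "y", "z")) {
    v <- maps[[paste0("v", d)]]
    flag <- array(FALSE, dim(v))
    # temporal jumps
    if (nf > 1) {
      dv <- abs(v[-1, , , drop = FALSE] - v[-nf, , , drop = FALSE])
      jump <- dv > jump_frac * venc
      flag[-1, , ][jump] <- TRUE
      flag[-nf, , ][jump] <- TRUE
    }
    # sign reversal against local spatial median
    for (f in seq_len(nf)) {
      m <- v[f, , ]
      med <- .spatial_median3(m, mask)
      sg <- (m * med < 0) & (abs(med) > median_frac * venc) & mask
      flag[f, , ] <- flag[f, , ] | sg
    }
    flag3 <- flag & array(rep(mask, each = nf), dim(v))
    counts[d] <- sum(flag3)
    out_flags[d] <- counts[d] >= min_pixels
    pixel_map[[d]] <- flag3
  }
  list(flags = out_flags, pixel_map = pixel_map, counts = counts)
}

#' Venc scout with escalation
#'
#' Emulates the scanner workflow: candidate Venc values are tried in
#' ascending order with a noise-free encode/decode, and the smallest
#' alias-free setting is kept. If every scout value shows aliasing, Venc is
#' escalated in steps until no aliasing is observed.
#'
#' @param field A `velocity_field`.
#' @param scout_vencs Ascending candidate Vencs, cm/s (default 200, 300, 400).
#' @param step Escalation step, cm/s (default 100).
#' @param max_venc Safety cap for the escalation loop.
#' @return Chosen Venc in cm/s.
#' @export
venc_scout <- function(field, scout_vencs = c(200, 300, 400), step = 100,
                       max_venc = 2000) {
  if (any(scout_vencs <= 0) || step <= 0)
    stop("scout Vencs and step must be positive")
  scout_vencs <- sort(scout_vencs)
  alias_free <- function(venc) {
    maps <- decode_velocities(encode_four_point(field, venc))
    !any(maps$aliased_flag)
  }
  for (v in scout_vencs) if (alias_free(v)) return(v)
  v <- max(scout_vencs)
  repeat {
    v <- v + step
    if (v > max_venc) stop("venc escalation exceeded max_venc = ", max_venc)
    if (alias_free(v)) return(v)
  }
}
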