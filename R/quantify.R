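#' Pixel-retention thresholds
#'
#' The two retention criteria applied before any velocity statistic: a
#' minimum on image magnitude (to reject background) and a floor on the
#' temporal-average flow magnitude (to reject stagnant or corrupted pixels).
#' Both are expressed as fractions so the same configuration applies across
#' Venc settings; they are learned once and applied uniformly to every
#' dataset.
#'
#' @param mag_frac Fraction of the maximum time-minimum magnitude (default
#'   0.15).
#' @param flow_frac Flow floor as a fraction of Venc applied to the temporal
#'   mean per-pixel speed (default 0.05).
#' @return Object of class `threshold_config`.
#' @export
threshold_config <- function(mag_frac = 0.15, flow_frac = 0.05) {
  if (mag_frac < 0 || mag_frac >= 1 || flow_frac < 0 || flow_frac >= 1)
    stop("threshold fractions must lie in [0, 1)")
  structure(list(mag_frac = mag_frac, flow_frac = flow_frac),
            class = "threshold_config")
}

#' Static pixel mask from magnitude and flow thresholds
#'
#' Retains pixels satisfying BOTH criteria: time-minimum magnitude at least
#' `mag_frac` of its maximum over the analysis region, AND temporal mean of
#' the per-pixel flow magnitude (|vz| in 1Dir mode, the full speed in 3Dir
#' mode) at least `flow_frac * venc`. The mask is static across frames.
#'
#' @param maps A `velocity_maps`.
#' @param mode `"3Dir"` (speed) or `"1Dir"` (through-plane only).
#' @param cfg A [threshold_config()].
#' @param roi Optional `[y, x]` logical region of interest (e.g. the manually
#'   contoured valve region); thresholds are applied within it.
#' @return Logical `[y, x]` mask.
#' @export
threshold_mask <- function(maps, mode = c("3Dir", "1Dir"),
                           cfg = threshold_config(), roi = NULL) {
  stopifnot(inherits(maps, "velocity_maps"))
  mode <- match.arg(mode)
  tmin <- apply(maps$magnitude, c(2, 3), min)
  if (is.null(roi)) roi <- array(TRUE, dim(tmin))
  magmax <- max(tmin[roi])
  crit_mag <- tmin >= cfg$mag_frac * magmax
  flow <- if (mode == "1Dir") abs(maps$vz) else speed_map(maps)
  tmean <- apply(flow, c(2, 3), mean)
  crit_flow <- tmean >= cfg$flow_frac * maps$venc
  mask <- crit_mag & crit_flow & roi
  if (!any(mask)) stop("no pixels survive thresholds")
  mask
}

#' Pixel-wise speed map
#'
#' `V = sqrt(Vx^2 + Vy^2 + Vz^2)`, element-wise over all frames — the
#' quantity that makes multi-directional acquisition insensitive to the
#' orientation of the stenotic jet.
#'
#' @param maps A `velocity_maps`, or a list with `vx`, `vy`, `vz` arrays.
#' @return Array `[frame, y, x]` in the input's velocity units.
#' @examples
#' speed_map(list(vx = 0.3, vy = 0.4, vz = 1.2))  # 1.3
#' @export
speed_map <- function(maps) sqrt(maps$vx^2 + maps$vy^2 + maps$vz^2)

#' Construct a peak-velocity curve
#'
#' @param t Frame times, ms.
#' @param v Per-frame peak velocities, cm/s (>= 0).
#' @param plane_index Plane the curve came from.
#' @return Tibble of class `peak_curve` with columns `t` (ms), `v` (cm/s).
#' @export
peak_curve <- function(t, v, plane_index = NA_integer_) {
  stopifnot(length(t) == length(v))
  out <- tibble::tibble(t = as.numeric(t), v = as.numeric(v))
  attr(out, "plane_index") <- plane_index
  class(out) <- c("peak_curve", class(out))
  out
}

#' Peak-velocity curve of one plane
#'
#' Per frame, the greatest velocity over retained pixels: |vz| in 1Dir mode,
#' the speed map in 3Dir mode.
#'
#' @param maps A `velocity_maps`.
#' @param mask Logical `[y, x]` retained-pixel mask (non-empty).
#' @param mode `"3Dir"` or `"1Dir"`.
#' @return A [peak_curve()].
#' @export
peak_velocity_curve <- function(maps, mask, mode = c("3Dir", "1Dir")) {
  mode <- match.arg(mode)
  if (!any(mask)) stop("mask must retain at least one pixel")
  flow <- if (mode == "1Dir") abs(maps$vz) else speed_map(maps)
  nf <- dim(flow)[1]
  v <- vapply(seq_len(nf), function(f) max(flow[f, , ][mask]), numeric(1))
  t <- (seq_len(nf) - 1) * maps$plane$frame_dt
  peak_curve(t, v, plane_index = maps$plane$plane_index)
}

#' Select the plane with the highest peak velocity
#'
#' @param curves List of [peak_curve()] objects (one per plane).
#' @return The `plane_index` of the curve with the highest maximum; ties go
#'   to the lowest plane index.
#' @export
select_plane <- function(curves) {
  if (inherits(curves, "peak_curve")) curves <- list(curves)
  if (!length(curves)) stop("at least one curve is required")
  idx <- vapply(curves, function(cv) as.integer(attr(cv, "plane_index")), integer(1))
  peaks <- vapply(curves, function(cv) max(cv$v), numeric(1))
  ord <- order(idx)
  idx[ord][which.max(peaks[ord])]
}

#' Mean velocity of a peak curve
#'
#' Average of the per-frame peak velocities. The default `"ejection"` window
#' averages frames whose velocity exceeds 5% of the curve maximum (the TTE
#' convention of averaging over the ejection envelope); `"full_cycle"`
#' averages every frame.
#'
#' @param curve A [peak_curve()] (cm/s).
#' @param window `"ejection"` or `"full_cycle"`.
#' @param floor_frac Ejection-window inclusion threshold (fraction of max).
#' @return Mean velocity in m/s.
#' @export
v_mean <- function(curve, window = c("ejection", "full_cycle"),
                   floor_frac = 0.05) {
  window <- match.arg(window)
  v <- curve$v
  if (!length(v) || max(v) == 0) return(0)
  sel <- if (window == "ejection") v > floor_frac * max(v) else rep(TRUE, length(v))
  mean(v[sel]) / 100
}

#' Modified Bernoulli pressure gradient
#'
#' `dP = 4 * V^2`, V in m/s, dP in mmHg.
#'
#' @param v Velocity in m/s (>= 0); vectorised.
#' @return Pressure gradient(s) in mmHg.
#' @examples
#' bernoulli_gradient(3)  # 36 mmHg
#' @export
bernoulli_gradient <- function(v) {
  if (any(v < 0)) stop("velocity must be >= 0 (m/s)")
  4 * v^2
}

#' Mean transvalvular gradient
#'
#' Time-average of the instantaneous Bernoulli gradient `4 * v(t)^2` over the
#' same window as [v_mean()]. Note MG is the average of `4 v^2`, not
#' `4 * (mean v)^2`.
#'
#' @inheritParams v_mean
#' @return Mean gradient in mmHg.
#' @export
mean_gradient <- function(curve, window = c("ejection", "full_cycle"),
                          floor_frac = 0.05) {
  window <- match.arg(window)
  v <- curve$v
  if (!length(v) || max(v) == 0) return(0)
  sel <- if (window == "ejection") v > floor_frac * max(v) else rep(TRUE, length(v))
  mean(4 * (v[sel] / 100)^2)
}

#' Velocity-time integral
#'
#' Trapezoidal integral of the peak-velocity curve over the full cycle:
#' cm/s x s = cm (the "stroke distance" of the jet).
#'
#' @param curve A [peak_curve()].
#' @return VTI in cm.
#' @export
vti <- function(curve) {
  if (nrow(curve) < 2) return(0)
  pracma::trapz(curve$t / 1000, curve$v)
}

#' Stroke volume by through-plane flux integration
#'
#' `SV = sum_frames sum_roi vz * pixel_area * frame_dt`, in mL. Volumetric
#' flux through a plane is the normal velocity component by definition, so
#' the through-plane component is integrated in both 1Dir and 3Dir modes.
#'
#' @param maps A `velocity_maps`.
#' @param roi Logical `[y, x]` region of interest (non-empty).
#' @return Stroke volume in mL.
#' @export
stroke_volume_pc <- function(maps, roi) {
  if (!any(roi)) stop("roi must retain at least one pixel")
  px_cm2 <- (maps$plane$pixel_size / 10)^2
  dt_s <- maps$plane$frame_dt / 1000
  nf <- dim(maps$vz)[1]
  sum(vapply(seq_len(nf), function(f) sum(maps$vz[f, , ][roi]), numeric(1))) *
    px_cm2 * dt_s
}

#' Circular LVOT area from its diameter
#'
#' `A = pi * (D/2)^2`, assuming a circular LVOT shape.
#'
#' @param d LVOT diameter in cm (>= 0).
#' @return Area in cm^2.
#' @examples
#' lvot_area(2)  # pi
#' @export
lvot_area <- function(d) {
  if (any(d < 0)) stop("diameter must be >= 0 (cm)")
  pi * (d / 2)^2
}

#' Aortic valve area estimators
#'
#' Continuity-equation valve area and its two CMR stroke-volume variants:
#' `ava_continuity = A_LVOT * VTI_LVOT / VTI_AV` (the TTE formula),
#' `ava_cine = SV_cine / VTI_AV` and `ava_flow = SV_PC / VTI_AV`
#' (mL / cm = cm^2).
#'
#' @param a_lvot LVOT area, cm^2.
#' @param vti_lvot,vti_av Velocity-time integrals at the LVOT and aortic
#'   valve, cm; `vti_av` must be positive.
#' @param sv_cine,sv_pc Stroke volume from cine imaging / PC flux, mL.
#' @return Valve area in cm^2.
#' @examples
#' ava_continuity(3, 20, 60)  # 1
#' ava_cine(60, 100)          # 0.6
#' @export
ava_continuity <- function(a_lvot, vti_lvot, vti_av) {
  if (vti_av <= 0) stop("vti_av must be positive (cm)")
  a_lvot * vti_lvot / vti_av
}

#' @rdname ava_continuity
#' @export
ava_cine <- function(sv_cine, vti_av) {
  if (vti_av <= 0) stop("vti_av must be positive (cm)")
  sv_cine / vti_av
}

#' @rdname ava_continuity
#' @export
ava_flow <- function(sv_pc, vti_av) {
  if (vti_av <= 0) stop("vti_av must be positive (cm)")
  sv_pc / vti_av
}

#' Full hemodynamic quantification of one subject
#'
#' Runs the complete post-processing chain over the decoded aortic planes:
#' threshold masking, aliasing salvage (phase unwrapping is attempted only
#' when aliasing is detected), peak-velocity curves, selection of the plane
#' with the highest peak, and derivation of Vpeak, Vmean, MG, PG, VTI, PC
#' stroke volume and the valve-area estimates. In `"1Dir"` mode only the
#' through-plane component enters the velocity measures; in `"3Dir"` mode
#' the full speed map does. Stroke volume integrates the through-plane
#' component in both modes.
#'
#' @param maps_list List of `velocity_maps`, one per aortic plane (indices
#'   >= 0; others ignored).
#' @param rois Optional list of `[y, x]` logical ROI masks parallel to
#'   `maps_list` (manual valve contours); `NULL` applies thresholds to the
#'   whole image.
#' @param mode `"3Dir"` or `"1Dir"`.
#' @param sv_cine Cine-derived stroke volume, mL (for `ava_cine`).
#' @param lvot_diameter LVOT diameter, cm (for the TTE-style valve area).
#' @param vti_lvot LVOT velocity-time integral, cm.
#' @param cfg A [threshold_config()].
#' @param window Averaging window for Vmean/MG, see [v_mean()].
#' @param unwrap_method Method for [unwrap_velocity()] when aliasing is
#'   flagged.
#' @return One-row tibble of class `hemodynamic_report` with columns
#'   `method`, `vpeak_ms`, `vmean_ms`, `mg_mmhg`, `pg_mmhg`, `vti_cm`,
#'   `sv_ml`, `sv_cine_ml`, `ava_cine_cm2`, `ava_flow_cm2`, `ava_tte_cm2`,
#'   `selected_plane`, `excluded`, `exclusion_reason`.
#' @export
quantify_subject <- function(maps_list, rois = NULL,
                             mode = c("3Dir", "1Dir"),
                             sv_cine = NA_real_, lvot_diameter = NA_real_,
                             vti_lvot = NA_real_,
                             cfg = threshold_config(),
                             window = "ejection",
                             unwrap_method = "temporal") {
  mode <- match.arg(mode)
  if (inherits(maps_list, "velocity_maps")) maps_list <- list(maps_list)
  keep <- vapply(maps_list, function(m) m$plane$plane_index >= 0, logical(1))
  maps_list <- maps_list[keep]
  if (!is.null(rois)) rois <- rois[keep]
  if (!length(maps_list)) stop("no aortic planes (plane_index >= 0) provided")

  excluded <- FALSE; reason <- NA_character_
  curves <- list(); masks <- list()
  for (i in seq_along(maps_list)) {
    maps <- maps_list[[i]]
    roi <- if (is.null(rois)) NULL else rois[[i]]
    if (any(maps$aliased_flag)) {
      uw <- unwrap_velocity(maps, method = unwrap_method, mask = roi)
      if (uw$report$salvage_failed) {
        excluded <- TRUE
        reason <- sprintf("salvage failed: unrecoverable aliasing at plane %d",
                          maps$plane$plane_index)
        break
      }
      maps <- uw$maps
      maps_list[[i]] <- maps
    }
    masks[[i]] <- threshold_mask(maps, mode = mode, cfg = cfg, roi = roi)
    curves[[i]] <- peak_velocity_curve(maps, masks[[i]], mode = mode)
  }

  if (excluded) {
    out <- tibble::tibble(method = mode, vpeak_ms = NA_real_, vmean_ms = NA_real_,
                          mg_mmhg = NA_real_, pg_mmhg = NA_real_, vti_cm = NA_real_,
                          sv_ml = NA_real_, sv_cine_ml = sv_cine,
                          ava_cine_cm2 = NA_real_, ava_flow_cm2 = NA_real_,
                          ava_tte_cm2 = NA_real_, selected_plane = NA_integer_,
                          excluded = TRUE, exclusion_reason = reason)
    class(out) <- c("hemodynamic_report", class(out))
    return(out)
  }

  sel_idx <- select_plane(curves)
  pos <- which(vapply(maps_list, function(m) m$plane$plane_index, integer(1)) == sel_idx)[1]
  curve <- curves[[pos]]

  vpeak <- max(curve$v) / 100
  vmean <- v_mean(curve, window = window)
  mg <- mean_gradient(curve, window = window)
  pg <- bernoulli_gradient(vpeak)
  vti_av <- vti(curve)
  sv_roi <- if (is.null(rois)) masks[[pos]] else rois[[pos]]
  sv_pc <- stroke_volume_pc(maps_list[[pos]], sv_roi)

  out <- tibble::tibble(
    method = mode,
    vpeak_ms = vpeak, vmean_ms = vmean, mg_mmhg = mg, pg_mmhg = pg,
    vti_cm = vti_av, sv_ml = sv_pc, sv_cine_ml = sv_cine,
    ava_cine_cm2 = if (!is.na(sv_cine) && vti_av > 0) ava_cine(sv_cine, vti_av) else NA_real_,
    ava_flow_cm2 = if (vti_av > 0) ava_flow(sv_pc, vti_av) else NA_real_,
    ava_tte_cm2 = if (!is.na(lvot_diameter) && !is.na(vti_lvot) && vti_av > 0)
      ava_continuity(lvot_area(lvot_diameter), vti_lvot, vti_av) else NA_real_,
    selected_plane = sel_idx,
    excluded = FALSE, exclusion_reason = NA_character_)
  class(out) <- c("hemodynamic_report", class(out))
  out
}
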