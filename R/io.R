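# Array export follows scanner conventions: image-like arrays go to NIfTI
# (frame as the 3rd dimension), metadata to JSON sidecars, tables to CSV.

# [frame, y, x] -> NIfTI-ordered [x, y, frame]
.to_nifti_order <- function(a) aperm(a, c(3, 2, 1))
.from_nifti_order <- function(a) {
  if (length(dim(a)) == 2) a <- array(a, c(dim(a), 1L))
  aperm(a, c(3, 2, 1))
}

#' Write decoded velocity maps as NIfTI volumes
#'
#' One file per velocity component plus the magnitude image, with a JSON
#' sidecar carrying Venc and plane geometry.
#'
#' @param maps A `velocity_maps`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_velocity_maps <- function(maps, dir, prefix = "maps") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (comp in c("vx", "vy", "vz", "magnitude")) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, comp))
    RNifti::writeNifti(.to_nifti_order(maps[[comp]]), p)
    paths <- c(paths, p)
  }
  side <- file.path(dir, sprintf("%s_meta.json", prefix))
  pl <- maps$plane
  jsonlite::write_json(list(venc = maps$venc,
                            pixel_size = pl$pixel_size,
                            frame_dt = pl$frame_dt,
                            plane_index = pl$plane_index,
                            plane_offset = pl$plane_offset,
                            aliased_flag = as.list(maps$aliased_flag)),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, side))
}

#' Read velocity maps written by [write_velocity_maps()]
#'
#' @param dir Directory holding the files.
#' @param prefix File-name prefix used at write time.
#' @return A `velocity_maps`.
#' @export
read_velocity_maps <- function(dir, prefix = "maps") {
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_meta.json", prefix)),
                              simplifyVector = TRUE)
  arr <- function(comp)
    .from_nifti_order(as.array(RNifti::readNifti(
      file.path(dir, sprintf("%s_%s.nii.gz", prefix, comp)))))
  vx <- arr("vx")
  nf <- dim(vx)[1]; ny <- dim(vx)[2]; nx <- dim(vx)[3]
  pl <- plane_spec(grid_nx = nx, grid_ny = ny, pixel_size = meta$pixel_size,
                   n_frames = nf, frame_dt = meta$frame_dt,
                   plane_index = meta$plane_index,
                   plane_offset = meta$plane_offset)
  structure(list(vx = vx, vy = arr("vy"), vz = arr("vz"),
                 magnitude = arr("magnitude"), venc = meta$venc, plane = pl,
                 aliased_flag = unlist(meta$aliased_flag),
                 alias_pixels = NULL, n_zero_magnitude = 0L),
            class = "velocity_maps")
}

#' Write an encoded series as paired magnitude/phase NIfTI stacks
#'
#' Phase is stored wrapped into (-pi, pi], one magnitude+phase pair per
#' encoding, with a JSON sidecar carrying Venc, seed and noise parameters.
#'
#' @param series An `encoded_series`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_encoded_series <- function(series, dir, prefix = "enc") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  z <- series$complex_images
  paths <- character(0)
  for (i in 1:4) {
    zi <- array(z[i, , , ], dim(z)[-1])
    pm <- file.path(dir, sprintf("%s_e%d_mag.nii.gz", prefix, i))
    pp <- file.path(dir, sprintf("%s_e%d_phase.nii.gz", prefix, i))
    RNifti::writeNifti(.to_nifti_order(Mod(zi)), pm)
    RNifti::writeNifti(.to_nifti_order(Arg(zi)), pp)
    paths <- c(paths, pm, pp)
  }
  side <- file.path(dir, sprintf("%s_meta.json", prefix))
  pl <- series$plane
  jsonlite::write_json(list(venc = series$venc,
                            noise_sigma = series$noise_sigma,
                            seed = series$seed,
                            pixel_size = pl$pixel_size, frame_dt = pl$frame_dt,
                            plane_index = pl$plane_index,
                            plane_offset = pl$plane_offset),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, side))
}

#' Read an encoded series written by [write_encoded_series()]
#'
#' @param dir Directory holding the files.
#' @param prefix File-name prefix used at write time.
#' @return An `encoded_series`.
#' @export
read_encoded_series <- function(dir, prefix = "enc") {
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_meta.json", prefix)),
                              simplifyVector = TRUE)
  first <- .from_nifti_order(as.array(RNifti::readNifti(
    file.path(dir, sprintf("%s_e1_mag.nii.gz", prefix)))))
  dims <- dim(first)
  z <- array(complex(real = 0, imaginary = 0), c(4L, dims))
  for (i in 1:4) {
    m <- .from_nifti_order(as.array(RNifti::readNifti(
      file.path(dir, sprintf("%s_e%d_mag.nii.gz", prefix, i)))))
    p <- .from_nifti_order(as.array(RNifti::readNifti(
      file.path(dir, sprintf("%s_e%d_phase.nii.gz", prefix, i)))))
    z[i, , , ] <- m * exp(1i * p)
  }
  pl <- plane_spec(grid_nx = dims[3], grid_ny = dims[2],
                   pixel_size = meta$pixel_size, n_frames = dims[1],
                   frame_dt = meta$frame_dt, plane_index = meta$plane_index,
                   plane_offset = meta$plane_offset)
  structure(list(complex_images = z, venc = meta$venc,
                 noise_sigma = meta$noise_sigma,
                 background_phase = NA_real_, seed = meta$seed, plane = pl),
            class = "encoded_series")
}

#' Write an ROI mask as NIfTI
#' @param roi Logical `[y, x]` matrix.
#' @param path Output `.nii.gz` path.
#' @export
write_roi <- function(roi, path) {
  RNifti::writeNifti(t(roi) * 1L, path)
  invisible(path)
}

#' Read an ROI mask written by [write_roi()]
#' @param path `.nii.gz` path.
#' @return Logical `[y, x]` matrix.
#' @export
read_roi <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  t(a) > 0.5
}

#' Quantify externally supplied velocity-map files
#'
#' Applies the post-processing chain to velocity maps stored on disk (one
#' NIfTI per component, frame as third dimension) with an ROI mask — the
#' entry point for data that did not come from the phantom. In 1Dir mode
#' only the through-plane component is used even if three components are
#' supplied.
#'
#' @param dir Directory holding maps written by [write_velocity_maps()] (or
#'   arranged the same way).
#' @param roi_file NIfTI ROI mask file.
#' @param mode `"3Dir"` or `"1Dir"`.
#' @param prefix File-name prefix.
#' @param out Optional path: write the report as JSON.
#' @param ... Passed to [quantify_subject()].
#' @return A `hemodynamic_report` tibble.
#' @export
quantify_files <- function(dir, roi_file, mode = c("3Dir", "1Dir"),
                           prefix = "maps", out = NULL, ...) {
  mode <- match.arg(mode)
  maps <- read_velocity_maps(dir, prefix)
  roi <- read_roi(roi_file)
  if (!all(dim(roi) == dim(maps$vz)[2:3]))
    stop("ROI dimensions ", paste(dim(roi), collapse = "x"),
         " do not match map dimensions ",
         paste(dim(maps$vz)[2:3], collapse = "x"))
  report <- quantify_subject(list(maps), rois = list(roi), mode = mode, ...)
  if (!is.null(out))
    jsonlite::write_json(as.list(report), out, auto_unbox = TRUE,
                         digits = NA, na = "null")
  report
}
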