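#' Salvage aliased velocity maps by phase unwrapping
#'
#' Decoded velocities wrap into (-venc, venc]; when the true flow exceeds
#' Venc the jet core wraps to the opposite sign. Temporal unwrapping exploits
#' the pulsatility of aortic flow: each pixel's time course is re-integrated
#' from its first low-flow frame (the anchor, where the measured value can be
#' trusted), adding multiples of `2 * venc` whenever a frame-to-frame jump
#' exceeds the jump threshold. Spatial unwrapping region-grows per frame from
#' a low-velocity seed inside the mask, applying the same correction across
#' neighbour differences. `"hybrid"` runs temporal then one spatial pass.
#'
#' A dataset is unrecoverable when a processed pixel has no anchor frame
#' (|v| never drops below `anchor_frac * venc`, e.g. velocity aliased in
#' every frame): the maps are returned unchanged with `salvage_failed = TRUE`
#' in the report, mirroring the exclusion of subjects whose aliasing cannot
#' be salvaged.
#'
#' @param maps A `velocity_maps`.
#' @param method `"temporal"` (default), `"spatial"`, or `"hybrid"`.
#' @param mask Optional `[y, x]` logical mask restricting processing;
#'   defaults to the blood pool (time-min magnitude >= 50% of maximum).
#' @param anchor_frac Anchor threshold as a fraction of Venc (default 0.5).
#' @param jump_frac Jump threshold as a fraction of Venc (default 1, i.e. a
#'   phase jump of pi).
#' @return List with `maps` (corrected `velocity_maps`) and `report`: per
#'   direction the number of corrected pixel-frames, plus `salvage_failed`.
#' @export
unwrap_velocity <- function(maps, method = c("temporal", "spatial", "hybrid"),
                            mask = NULL, anchor_frac = 0.5, jump_frac = 1.0) {
  stopifnot(inherits(maps, "velocity_maps"))
  method <- match.arg(method)
  venc <- maps$venc
  nf <- dim(maps$vz)[1]
  if (is.null(mask)) {
    tmin <- apply(maps$magnitude, c(2, 3), min)
    mask <- tmin >= 0.5 * max(tmin)
  }
  report <- list(corrected = c(x = 0L, y = 0L, z = 0L),
                 corrected_per_frame = list(),
                 salvage_failed = FALSE, method = method)
  out <- maps

  for (d in c("x", "y", "z")) {
    v <- maps[[paste0("v", d)]]
    vin <- v
    if (method %in% c("temporal", "hybrid")) {
      res <- .unwrap_temporal(v, mask, venc, anchor_frac, jump_frac)
      if (res$failed) {
        report$salvage_failed <- TRUE
        report$corrected <- c(x = 0L, y = 0L, z = 0L)
        return(list(maps = maps, report = report))
      }
      v <- res$v
    }
    if (method %in% c("spatial", "hybrid")) {
      v <- .unwrap_spatial(v, mask, venc, anchor_frac, jump_frac)
    }
    nc <- sum(abs(v - vin) > 1e-6)
    report$corrected[d] <- nc
    report$corrected_per_frame[[d]] <-
      vapply(seq_len(nf), function(f) sum(abs(v[f, , ] - vin[f, , ]) > 1e-6),
             integer(1))
    out[[paste0("v", d)]] <- v
  }
  out$aliased_flag[] <- FALSE
  det <- detect_aliasing(out, mask = mask)
  out$aliased_flag <- det$flags
  out$alias_pixels <- det$pixel_map
  list(maps = out, report = report)
}

# temporal unwrap of [frame, y, x] restricted to mask; anchored per pixel on
# the first frame with |v| < anchor_frac * venc
.unwrap_temporal <- function(v, mask, venc, anchor_frac, jump_frac) {
  nf <- dim(v)[1]
  V <- matrix(v, nf, prod(dim(v)[2:3]))        # frames x pixels
  pix <- which(as.vector(mask))
  if (!length(pix)) return(list(v = v, failed = FALSE))
  Vm <- V[, pix, drop = FALSE]

  # cumulative unwrap anchored provisionally at frame 1
  U <- Vm
  if (nf > 1) {
    for (f in 2:nf) {
      k <- round((U[f - 1, ] - Vm[f, ]) / (2 * venc))
      U[f, ] <- Vm[f, ] + 2 * venc * k
    }
  }
  # pixels that ever reach the anchor threshold are potentially aliased and
  # need at least one trustworthy low-flow frame; constant high readings
  # (e.g. velocity aliased in every frame) have no anchor and cannot be
  # salvaged
  low <- abs(Vm) < anchor_frac * venc
  has_anchor <- colSums(low) > 0
  considered <- apply(abs(Vm), 2, max) >= anchor_frac * venc
  if (any(considered & !has_anchor)) return(list(v = v, failed = TRUE))
  # re-anchor: keep the measured value at the first low-flow frame
  anchor <- max.col(t(low), ties.method = "first")
  idx <- cbind(anchor, seq_along(pix))
  m <- round((U[idx] - Vm[idx]) / (2 * venc))
  m[!has_anchor] <- 0
  U <- sweep(U, 2, 2 * venc * m, "-")
  V[, pix] <- U
  list(v = array(V, dim(v)), failed = FALSE)
}

# per-frame region growing from the lowest-|v| seed inside the mask
.unwrap_spatial <- function(v, mask, venc, anchor_frac, jump_frac) {
  nf <- dim(v)[1]; ny <- dim(v)[2]; nx <- dim(v)[3]
  pix_idx <- which(mask, arr.ind = TRUE)
  if (!nrow(pix_idx)) return(v)
  for (f in seq_len(nf)) {
    m <- v[f, , ]
    vals <- m[mask]
    seed <- pix_idx[which.min(abs(vals)), ]
    visited <- matrix(FALSE, ny, nx)
    qy <- integer(nrow(pix_idx)); qx <- integer(nrow(pix_idx))
    qy[1] <- seed[1]; qx[1] <- seed[2]
    visited[seed[1], seed[2]] <- TRUE
    head <- 1L; tail <- 1L
    while (head <= tail) {
      cy <- qy[head]; cx <- qx[head]; head <- head + 1L
      for (nb in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        yy <- cy + nb[1]; xx <- cx + nb[2]
        if (yy < 1 || yy > ny || xx < 1 || xx > nx) next
        if (!mask[yy, xx] || visited[yy, xx]) next
        diffv <- m[yy, xx] - m[cy, cx]
        if (abs(diffv) > jump_frac * venc) {
          m[yy, xx] <- m[yy, xx] - 2 * venc * round(diffv / (2 * venc))
        }
        visited[yy, xx] <- TRUE
        tail <- tail + 1L
        qy[tail] <- yy; qx[tail] <- xx
      }
    }
    v[f, , ] <- m
  }
  v
}
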