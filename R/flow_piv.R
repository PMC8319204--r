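# Track-based 3D particle imaging velocimetry.

#' Voxelized mean flow field from bead tracks
#'
#' Each consecutive pair of positions within a track contributes one
#' instantaneous velocity, assigned to the voxel containing the displacement
#' midpoint (unbiased for linear fields). Per voxel, the arithmetic mean
#' velocity over all assigned samples is retained; voxels without samples are
#' absent from the table, never zero-velocity.
#'
#' @param tracks data frame with columns `track`, `t` (s), `x`, `y`, `z`
#'   (um); time must advance uniformly within tracks.
#' @param spacing voxel edge lengths `c(dx, dy, dz)` in um (default 4, 4, 2).
#' @param origin voxel-grid origin in um (default `c(0, 0, 0)`); voxel
#'   `(0, 0, 0)` spans `[origin, origin + spacing)`.
#' @param per_bead_average average per-track first and pool track means
#'   second, instead of pooling all samples (default FALSE).
#' @return Object of class `flow_field`: data.table with `ix, iy, iz`
#'   (integer voxel indices), voxel centers `x, y, z` (um), mean `vx, vy,
#'   vz`, `speed` (um/s) and sample count `n`; attributes `spacing`,
#'   `origin`.
#' @export
build_flow_field <- function(tracks, spacing = c(4, 4, 2),
                             origin = c(0, 0, 0), per_bead_average = FALSE) {
  stopifnot(all(c("track", "t", "x", "y", "z") %in% names(tracks)),
            all(spacing > 0))
  dt_tab <- data.table::as.data.table(tracks)
  data.table::setorder(dt_tab, track, t)
  g <- dt_tab[, {
    if (.N >= 2) {
      dtv <- diff(t)
      list(mx = (x[-.N] + x[-1]) / 2, my = (y[-.N] + y[-1]) / 2,
           mz = (z[-.N] + z[-1]) / 2,
           vx = diff(x) / dtv, vy = diff(y) / dtv, vz = diff(z) / dtv)
    }
  }, by = track]
  if (!nrow(g)) stop("empty flow field: no velocity samples")
  g[, `:=`(ix = as.integer(floor((mx - origin[1]) / spacing[1])),
           iy = as.integer(floor((my - origin[2]) / spacing[2])),
           iz = as.integer(floor((mz - origin[3]) / spacing[3])))]
  if (per_bead_average) {
    g <- g[, .(vx = mean(vx), vy = mean(vy), vz = mean(vz)),
           by = .(track, ix, iy, iz)]
  }
  field <- g[, .(vx = mean(vx), vy = mean(vy), vz = mean(vz), n = .N),
             by = .(ix, iy, iz)]
  field[, `:=`(x = origin[1] + (ix + 0.5) * spacing[1],
               y = origin[2] + (iy + 0.5) * spacing[2],
               z = origin[3] + (iz + 0.5) * spacing[3],
               speed = sqrt(vx^2 + vy^2 + vz^2))]
  data.table::setcolorder(field, c("ix", "iy", "iz", "x", "y", "z",
                                   "vx", "vy", "vz", "speed", "n"))
  data.table::setattr(field, "spacing", spacing)
  data.table::setattr(field, "origin", origin)
  data.table::setattr(field, "class", c("flow_field", class(field)))
  field[]
}

#' Glass-plane z-coordinate from nonmoving beads
#'
#' A track is classified nonmoving when its positional standard deviation
#' over the whole track stays below a multiple of the expected Brownian step
#' on every axis (a diffusing bead wanders by many steps over a track, a
#' stuck bead only by its localization noise); the glass z is the mean of
#' the nonmoving tracks' time-averaged z-positions.
#'
#' @param tracks data frame with `track`, `t`, `x`, `y`, `z` (um).
#' @param sigma_step_um expected per-axis Brownian step sd (um), e.g.
#'   `diffusion_model(...)$sigma_step_um`.
#' @param factor classification threshold multiplier (default 3).
#' @return Glass z (um), with attribute `n_nonmoving`.
#' @export
estimate_glass_z <- function(tracks, sigma_step_um, factor = 3) {
  per <- lapply(split(tracks, tracks$track), function(tr) {
    tr <- tr[order(tr$t), ]
    n <- nrow(tr)
    if (n < 4) return(NULL)
    disp <- vapply(c("x", "y", "z"), function(a) stats::sd(tr[[a]]),
                   numeric(1))
    data.frame(moving = any(disp > factor * sigma_step_um),
               z_mean = mean(tr$z))
  })
  per <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
  nm <- per[!per$moving, , drop = FALSE]
  if (!nrow(nm)) stop("no nonmoving beads found")
  structure(mean(nm$z_mean), n_nonmoving = nrow(nm))
}

#' Project a 3D flow field to 2D
#'
#' Per (x, y) column, the count-weighted mean of the voxel velocities across
#' z; speeds are recomputed from the projected vectors.
#'
#' @param field a [build_flow_field()] result.
#' @return data.table with `ix, iy, x, y, vx, vy, vz, speed, n`.
#' @export
project_flow_2d <- function(field) {
  stopifnot(inherits(field, "flow_field"), nrow(field) >= 1)
  proj <- field[, .(x = x[1], y = y[1],
                    vx = sum(vx * n) / sum(n), vy = sum(vy * n) / sum(n),
                    vz = sum(vz * n) / sum(n), n = sum(n)),
                by = .(ix, iy)]
  proj[, speed := sqrt(vx^2 + vy^2 + vz^2)]
  proj[]
}
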