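#' Column profile of a per-cell field
#'
#' Averages a field over cells sharing the same integer coordinate along the
#' wave axis: the column index on chains and rectangular hexagonal patches,
#' or the rounded radial distance when `axis = "radial"` on discs.
#'
#' @param values Numeric per-cell vector.
#' @param lattice A `cell_lattice`.
#' @param cells Optional subset of cell indices to restrict to.
#' @param axis `"col"` (default) or `"radial"`.
#' @return Data frame with columns `coord` (sorted) and `value`.
#' @export
column_profile <- function(values, lattice, cells = NULL, axis = "col") {
  stopifnot(inherits(lattice, "cell_lattice"))
  if (length(values) != lattice$n_cells)
    stop("column_profile: field length does not match lattice size")
  coord <- if (axis == "radial") {
    if (is.null(lattice$radius)) stop("column_profile: lattice has no radii")
    round(lattice$radius)
  } else lattice$col
  if (!is.null(cells)) {
    values <- values[cells]
    coord <- coord[cells]
  }
  agg <- tapply(values, coord, mean)
  data.frame(coord = as.numeric(names(agg)), value = as.numeric(agg))
}

# furthest downstream crossing of `level` in an ordered profile,
# linearly interpolated; -Inf when the profile never reaches the level
profile_crossing <- function(coord, value, level) {
  above <- value >= level
  if (!any(above)) return(-Inf)
  q <- max(which(above))
  if (q == length(coord)) return(coord[q])
  # interpolate between the last above-level column and the next one
  coord[q] + (value[q] - level) / (value[q] - value[q + 1]) *
    (coord[q + 1] - coord[q])
}

#' Wavefront position along the wave axis
#'
#' The furthest coordinate at which the transition indicator crosses 0.5,
#' linearly interpolated between cell columns. For the integrated model the
#' indicator is the cell-state variable Omega; for the E-only model it is
#' `phi_E` normalised by `reference` (by default the spatial maximum, i.e.
#' the invaded plateau). Returns `-Inf` when no crossing exists.
#'
#' @param state A `tissue_state`.
#' @param lattice A `cell_lattice`.
#' @param field `"omega"`, `"phi_E"`, or `NULL` to choose automatically
#'   (Omega when it is anywhere above 0.5, otherwise `phi_E`).
#' @param reference Normalisation level for `phi_E` (e.g. the upper stable
#'   root); defaults to the spatial maximum.
#' @param cells Optional cell subset (e.g. a clone band).
#' @param axis `"col"` or `"radial"`.
#' @return Numeric front position (or `-Inf`).
#' @export
wavefront_position <- function(state, lattice, field = NULL,
                               reference = NULL, cells = NULL,
                               axis = "col") {
  if (!length(state$phi_E)) stop("wavefront_position: empty state")
  if (is.null(field))
    field <- if (max(state$omega) >= 0.5) "omega" else "phi_E"
  v <- state[[field]]
  if (field == "phi_E") {
    ref <- reference %||% max(v)
    if (ref <= 0) return(-Inf)
    v <- v / ref
  }
  pr <- column_profile(v, lattice, cells = cells, axis = axis)
  profile_crossing(pr$coord, pr$value, 0.5)
}

#' Wave speed from a trajectory
#'
#' Least-squares slope of the wavefront position against time over a fitting
#' window (by default the trajectory with its first 20% dropped, excluding
#' the initiation transient).
#'
#' @param traj A `pn_trajectory`.
#' @param window Length-2 time interval; default `c(0.2, 1) * max(times)`.
#' @param ... Passed to [wavefront_position()].
#' @return List with `speed`, `r2`, and `front` (data frame of time and
#'   position).
#' @export
wave_speed <- function(traj, window = NULL, ...) {
  stopifnot(inherits(traj, "pn_trajectory"))
  tmax <- max(traj$times)
  if (is.null(window)) window <- c(0.2 * tmax, tmax)
  pos <- vapply(traj$states, wavefront_position, numeric(1),
                lattice = traj$lattice, ...)
  keep <- is.finite(pos) & traj$times >= window[1] & traj$times <= window[2]
  if (sum(keep) < 3L)
    stop("wave_speed: fewer than 3 recorded states with a front in window")
  t <- traj$times[keep]; p <- pos[keep]
  fit <- stats::lm(p ~ t)
  tss <- sum((p - mean(p))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  list(speed = unname(stats::coef(fit)[2]), r2 = r2,
       front = data.frame(time = traj$times, position = pos))
}

# interpolated half-maximum extent of an ordered profile
half_max_extent <- function(coord, value) {
  M <- max(value)
  if (M <= 0) return(NA_real_)
  lev <- M / 2
  above <- which(value >= lev)
  l <- min(above); r <- max(above)
  left <- if (l == 1L) coord[1] - 0.5 else
    coord[l] - (value[l] - lev) / (value[l] - value[l - 1]) *
      (coord[l] - coord[l - 1])
  right <- if (r == length(coord)) coord[r] + 0.5 else
    coord[r] + (value[r] - lev) / (value[r] - value[r + 1]) *
      (coord[r + 1] - coord[r])
  right - left
}

#' Width of the transition zone
#'
#' The transition zone is the moving band of proneural (L'sc) expression, so
#' the width is measured on `phi_L`: per snapshot, the interpolated spatial
#' extent along the wave axis where the column profile of `phi_L` is at
#' least half of its instantaneous maximum; averaged over the steady
#' propagation window (central 60% of the run by default).
#'
#' @param traj A `pn_trajectory` (E+L or integrated variant).
#' @param window Length-2 fraction-of-duration interval, default
#'   `c(0.2, 0.8)`.
#' @param axis `"col"` or `"radial"`.
#' @return Mean width in cell units, or `NA` if `phi_L` never rises.
#' @export
transition_zone_width <- function(traj, window = c(0.2, 0.8), axis = "col") {
  stopifnot(inherits(traj, "pn_trajectory"))
  tmax <- max(traj$times)
  keep <- which(traj$times >= window[1] * tmax &
                  traj$times <= window[2] * tmax)
  widths <- vapply(keep, function(i) {
    pr <- column_profile(traj$states[[i]]$phi_L, traj$lattice, axis = axis)
    if (max(pr$value) < 1e-9) return(NA_real_)
    half_max_extent(pr$coord, pr$value)
  }, numeric(1))
  if (all(is.na(widths))) return(NA_real_)
  mean(widths, na.rm = TRUE)
}

#' Detect the Notch pre-peak ahead of the transition zone
#'
#' In the integrated model the drop in Notch at the transition zone is
#' preceded by a pulse of Notch signalling just ahead of it, caused by
#' trans-activation from the high-Delta zone cells. This detector locates
#' the zone centre (column of maximal `phi_L`), searches for a local maximum
#' of the Notch column profile ahead of it, and reports a pre-peak when that
#' maximum exceeds both the neuroepithelial plateau further ahead and the
#' Notch level at the zone centre by a relative `margin`.
#'
#' Because the discrete front advances cell by cell, instantaneous profiles
#' "lurch" within each cell-crossing period; a time-averaging `window`
#' (centred on `time`, in time units) smooths this out and makes the
#' detection insensitive to the sampling phase.
#'
#' @param traj A `pn_trajectory` (integrated variant).
#' @param time Snapshot time (nearest recorded state).
#' @param margin Relative detection margin (default 0.02).
#' @param window Half-width of the profile averaging window (0 = single
#'   snapshot). Profiles are averaged in the co-moving frame of the
#'   zone centre.
#' @return List with `prepeak` (logical) and `offset` (cells ahead of the
#'   zone centre, `NA` when absent); both `NA` if there is no wave.
#' @export
notch_prepeak <- function(traj, time = max(traj$times), margin = 0.02,
                          window = 0) {
  stopifnot(inherits(traj, "pn_trajectory"))
  idx <- if (window > 0)
    which(abs(traj$times - time) <= window) else which.min(abs(traj$times - time))
  profs <- lapply(idx, function(i) {
    s <- traj$states[[i]]
    list(L = column_profile(s$phi_L, traj$lattice),
         N = column_profile(s$phi_N, traj$lattice))
  })
  # align profiles on the instantaneous zone centre before averaging
  centers <- vapply(profs, function(p)
    if (max(p$L$value) < 1e-9) NA_real_ else
      p$L$coord[which.max(p$L$value)], numeric(1))
  keep <- !is.na(centers)
  if (!any(keep)) return(list(prepeak = NA, offset = NA_real_))
  profs <- profs[keep]; centers <- centers[keep]
  ref <- stats::median(centers)
  shift_mean <- function(field) {
    mats <- mapply(function(p, cen) {
      d <- round(ref - cen)
      v <- p[[field]]$value
      if (d > 0) c(rep(v[1], d), v[seq_len(length(v) - d)])
      else if (d < 0) c(v[(-d + 1):length(v)], rep(v[length(v)], -d))
      else v
    }, profs, centers)
    rowMeans(as.matrix(mats))
  }
  coord <- profs[[1]]$L$coord
  prL <- data.frame(coord = coord, value = shift_mean("L"))
  prN <- data.frame(coord = coord, value = shift_mean("N"))
  if (max(prL$value) < 1e-9)
    return(list(prepeak = NA, offset = NA_real_))
  center <- prL$coord[which.max(prL$value)]
  ahead <- which(prN$coord > center)
  if (length(ahead) < 3L) return(list(prepeak = NA, offset = NA_real_))
  v <- prN$value
  # interior local maxima of the Notch profile ahead of the zone centre
  loc <- ahead[ahead > 1L & ahead < length(v)]
  loc <- loc[v[loc] >= v[loc - 1L] & v[loc] >= v[loc + 1L]]
  if (!length(loc)) return(list(prepeak = FALSE, offset = NA_real_))
  q <- loc[which.max(v[loc])]
  beyond <- which(prN$coord > prN$coord[q])
  plateau <- if (length(beyond)) stats::median(v[beyond]) else 0
  n_center <- v[which.min(abs(prN$coord - center))]
  ok <- v[q] > plateau * (1 + margin) && v[q] > n_center * (1 + margin)
  list(prepeak = ok,
       offset = if (ok) prN$coord[q] - center else NA_real_)
}

#' Salt-and-pepper (lateral inhibition) pattern index
#'
#' Moran-type neighbour-pair correlation of a field over a cell subset: the
#' field is standardised over the masked cells (population moments) and the
#' index is the mean over undirected neighbour pairs of the product of the
#' two standardised deviations. Values near -1 indicate perfect
#' anti-correlation between neighbours (a salt-and-pepper pattern, e.g. an
#' alternating two-colouring of a chain); spatially random fields give 0 in
#' expectation. Invariant under affine rescaling of the field.
#'
#' @param state A `tissue_state`, or a numeric per-cell vector.
#' @param lattice A `cell_lattice`.
#' @param field Field name when `state` is a `tissue_state`
#'   (default `"phi_N"`, the Notch signalling level).
#' @param mask Optional integer subset of cells; every masked cell must have
#'   at least one masked neighbour.
#' @return Numeric index in `[-1, 1]`, or `NA` when the field has zero
#'   variance over the mask.
#' @export
salt_and_pepper_index <- function(state, lattice, field = "phi_N",
                                  mask = NULL) {
  stopifnot(inherits(lattice, "cell_lattice"))
  x <- if (is.numeric(state)) state else state[[field]]
  if (length(x) != lattice$n_cells)
    stop("salt_and_pepper_index: field length does not match lattice size")
  if (is.null(mask)) mask <- seq_len(lattice$n_cells)
  inmask <- logical(lattice$n_cells)
  inmask[mask] <- TRUE
  i <- rep.int(seq_len(lattice$n_cells), lattice$degree)
  j <- unlist(lattice$neighbors, use.names = FALSE)
  keep <- inmask[i] & inmask[j] & i < j
  if (!any(keep))
    stop("salt_and_pepper_index: no neighbour pairs within mask")
  xm <- x[mask]
  mu <- mean(xm)
  s <- sqrt(mean((xm - mu)^2))
  if (s < 1e-12) return(NA_real_)
  z <- (x - mu) / s
  mean(z[i[keep]] * z[j[keep]])
}

#' Lateral-inhibition index behind the wavefront
#'
#' Protocol observable for the basal-Notch analysis: at the given snapshot,
#' the wavefront position along the wave axis is located on Omega, the mask
#' is taken as the neuroepithelial cells (`omega < 0.5`) at or behind the
#' front -- the cells in and around the transition zone where lateral
#' inhibition can act -- and the [salt_and_pepper_index()] of the chosen
#' field over that mask is returned.
#'
#' The mask is restricted to the conversion band -- neuroepithelial cells at
#' or behind the front that lie within `band` lattice units of a cell that
#' has already transitioned -- because that is where the laterally inhibited
#' state is expressed before the transition consumes it; far-from-front
#' neuroepithelium carries only uncorrelated fluctuations. When `times`
#' contains several snapshot times the per-snapshot indices are averaged,
#' which suppresses single-snapshot estimation noise.
#'
#' To suppress the fast uncorrelated component of the biochemical noise
#' (which dilutes the index towards zero without carrying spatial
#' information), the scored field is averaged per cell over the snapshots
#' within `field_window` time units of each evaluation time; the persistent
#' laterally-inhibited structure survives this averaging, the
#' cell-autonomous fluctuations largely cancel.
#'
#' @param traj A `pn_trajectory` (integrated variant).
#' @param times Snapshot time(s); indices are averaged over them.
#' @param field Field to score (default `"phi_N"`).
#' @param band Maximal distance (lattice units) from a transitioned cell.
#' @param min_cells Minimal mask size per snapshot (below it the snapshot is
#'   skipped).
#' @param field_window Half-width (time units) of the per-cell field
#'   averaging window.
#' @return Numeric index or `NA`.
#' @export
pattern_index_behind_front <- function(traj, times = max(traj$times),
                                       field = "phi_N", band = 2.5,
                                       min_cells = 10L, field_window = 1) {
  stopifnot(inherits(traj, "pn_trajectory"))
  lattice <- traj$lattice
  one <- function(time) {
    s <- state_at(traj, time)
    if (field_window > 0) {
      idx <- which(abs(traj$times - time) <= field_window)
      if (length(idx) > 1L) {
        s[[field]] <- rowMeans(vapply(idx, function(i)
          traj$states[[i]][[field]], numeric(lattice$n_cells)))
      }
    }
    fp <- wavefront_position(s, lattice, field = "omega")
    if (!is.finite(fp)) return(NA_real_)
    nb <- which(s$omega >= 0.5)
    if (!length(nb)) return(NA_real_)
    cand <- which(s$omega < 0.5 & lattice$coords$x <= fp)
    if (!length(cand)) return(NA_real_)
    # distance of each candidate to the nearest transitioned cell
    dmin <- vapply(cand, function(i) {
      dx <- lattice$coords$x[nb] - lattice$coords$x[i]
      dy <- lattice$coords$y[nb] - lattice$coords$y[i]
      sqrt(min(dx * dx + dy * dy))
    }, numeric(1))
    mask <- cand[dmin <= band]
    deg_in <- vapply(mask, function(i)
      sum(lattice$neighbors[[i]] %in% mask), integer(1))
    mask <- mask[deg_in > 0L]
    if (length(mask) < min_cells) return(NA_real_)
    salt_and_pepper_index(s, lattice, field = field, mask = mask)
  }
  vals <- vapply(times, one, numeric(1))
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Radius of a target wave around a nucleation site
#'
#' For ectopic-excitation runs: per recorded snapshot, the largest distance
#' from the nucleating cell at which the NE-to-NB transition
#' (`omega >= 0.5`) has occurred.
#'
#' @param traj A `pn_trajectory`.
#' @param center Index of the nucleating cell.
#' @return Data frame with `time` and `radius` (`NA` before nucleation).
#' @export
target_wave_radius <- function(traj, center) {
  stopifnot(inherits(traj, "pn_trajectory"))
  cc <- c(traj$lattice$coords$x[center], traj$lattice$coords$y[center])
  d <- sqrt((traj$lattice$coords$x - cc[1])^2 +
              (traj$lattice$coords$y - cc[2])^2)
  radius <- vapply(traj$states, function(s) {
    hit <- s$omega >= 0.5
    if (!any(hit)) NA_real_ else max(d[hit])
  }, numeric(1))
  data.frame(time = traj$times, radius = radius)
}
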