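#' Van der Waals radii table
#'
#' Bondi-style element radii used by the pore profiler; shipped as an
#' editable CSV. The reported pore dimensions depend on this table, so
#' comparisons between profiles should hold the table fixed.
#'
#' @param path Optional alternative CSV (columns element, radius).
#' @return Named numeric vector of radii (Angstrom).
#' @export
default_vdw_radii <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "vdw_radii.csv", package = "metscreen")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tab$radius, tab$element)
}

# Normalize a structure argument into a data.frame with x,y,z,vdw columns.
structure_atoms <- function(structure, vdw_radii, hydrogens = FALSE) {
  if (inherits(structure, "pdb")) {
    at <- structure$atom
    df <- data.frame(element = toupper(substr(trimws(at$elety), 1, 1)),
                     x = at$x, y = at$y, z = at$z)
  } else df <- as.data.frame(structure)
  if (!all(c("x", "y", "z") %in% names(df)))
    abort_input("structure needs x, y, z columns")
  if (!hydrogens && "element" %in% names(df))
    df <- df[df$element != "H", , drop = FALSE]
  if (!nrow(df)) abort_input("structure has no heavy atoms")
  if (!"vdw" %in% names(df)) {
    if (!"element" %in% names(df))
      abort_input("structure needs an element or vdw column")
    r <- vdw_radii[df$element]
    r[is.na(r)] <- vdw_radii[["X"]]
    df$vdw <- as.numeric(r)
  }
  df
}

#' Profile the radius of a channel pore along an axis
#'
#' HOLE-style pore profiling: at each position `z` along the pore axis, the
#' pore radius is the radius of the largest probe sphere that fits, i.e.
#' the maximum over probe centers in the plane normal to the axis of
#' `min over atoms (distance(center, atom) - vdW radius)`. The probe center
#' is optimized by Nelder-Mead with seeded random restarts, warm-started
#' from the previous plane's center (the first plane starts at the axis
#' anchor), and constrained to a cylinder of `max_radius` around the axis.
#' Planes where no atom lies within the search cylinder report the capped
#' `max_radius` and are flagged.
#'
#' @param structure A `bio3d` pdb object, or data frame with `x`, `y`, `z`
#'   and either `element` or a per-atom `vdw` column.
#' @param axis Unit 3-vector of the pore axis (default z).
#' @param anchor Point on the axis (default the heavy-atom centroid).
#' @param z_range Axial interval profiled, relative to the anchor (default
#'   spans the structure).
#' @param step Grid step in Angstrom (default 0.5).
#' @param seed Integer seed for the restart sampler (default 1).
#' @param n_restarts Random restarts per plane in addition to the
#'   warm start (default 8).
#' @param max_radius Search-cylinder radius and radius cap (default 15).
#' @param vdw_radii Named radii vector ([default_vdw_radii()]).
#' @return Object of class `pore_profile`: data frame `profile` (z, radius,
#'   cx, cy, cz, capped), plus `min_radius`, `min_diameter`, `z_at_min`.
#' @export
profile_pore <- function(structure, axis = c(0, 0, 1), anchor = NULL,
                         z_range = NULL, step = 0.5, seed = 1L,
                         n_restarts = 8L, max_radius = 15,
                         vdw_radii = default_vdw_radii()) {
  atoms <- structure_atoms(structure, vdw_radii)
  axis <- unitize(as.numeric(axis))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (is.null(anchor)) {
    anchor <- colMeans(xyz)
    anchor <- anchor - sum(anchor * axis) * axis + sum(colMeans(xyz) * axis) * axis
  }
  anchor <- as.numeric(anchor)
  # orthonormal in-plane basis (u, v) completing the axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(pracma_cross(axis, ref))
  v <- pracma_cross(axis, u)
  t_atoms <- as.numeric((xyz - matrix(anchor, nrow(xyz), 3, TRUE)) %*% axis)
  if (is.null(z_range)) z_range <- range(t_atoms)
  zs <- seq(z_range[1], z_range[2], by = step)

  objective <- function(par, plane_pt) {
    if (sum(par^2) > max_radius^2) return(-1e6 - sum(par^2))
    ctr <- plane_pt + par[1] * u + par[2] * v
    d <- sqrt(colSums((t(xyz) - ctr)^2)) - atoms$vdw
    min(d)
  }

  res <- with_seed(seed, {
    prev <- c(0, 0)
    rows <- vector("list", length(zs))
    for (k in seq_along(zs)) {
      plane_pt <- anchor + zs[k] * axis
      # atoms anywhere can cap the sphere, but a plane is flagged when no
      # atom lies within max_radius of it along the axis
      near <- any(abs(t_atoms - zs[k]) <= max_radius)
      starts <- rbind(prev,
                      matrix(stats::runif(2 * n_restarts, -2, 2), ncol = 2) +
                        matrix(prev, n_restarts, 2, TRUE))
      best <- NULL
      for (s in seq_len(nrow(starts))) {
        opt <- stats::optim(starts[s, ], objective, plane_pt = plane_pt,
                            method = "Nelder-Mead",
                            control = list(fnscale = -1, maxit = 200,
                                           reltol = 1e-10))
        if (is.null(best) || opt$value > best$value) best <- opt
      }
      capped <- !near || best$value >= max_radius
      radius <- min(max(best$value, 0), max_radius)
      ctr <- plane_pt + best$par[1] * u + best$par[2] * v
      rows[[k]] <- data.frame(z = zs[k], radius = radius,
                              cx = ctr[1], cy = ctr[2], cz = ctr[3],
                              capped = capped)
      prev <- best$par
    }
    do.call(rbind, rows)
  })
  imin <- which.min(res$radius)
  structure(list(profile = res,
                 min_radius = res$radius[imin],
                 min_diameter = 2 * res$radius[imin],
                 z_at_min = res$z[imin],
                 axis = axis, anchor = anchor, step = step, seed = seed),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf("<pore_profile> %d planes, z in [%.1f, %.1f]; min radius %.2f A (diameter %.2f A) at z = %.1f\n",
              nrow(x$profile), min(x$profile$z), max(x$profile$z),
              x$min_radius, x$min_diameter, x$z_at_min))
  invisible(x)
}

# Minimal cross product (avoids importing pracma into the package).
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Derive pore zone boundaries from a radius profile
#'
#' Splits the profiled axial span into `bottom`, `middle` and `top`
#' intervals around the central constriction: the `middle` zone is the
#' contiguous region containing the global radius minimum where the radius
#' stays within `frac` of the way from the minimum to the maximum (at least
#' `min_halfwidth` to each side); the expanded flanks become `bottom` and
#' `top`. A profile with no constriction (radius range below `flat_tol`)
#' falls back to a single `middle` zone with a warning.
#'
#' @param p A [profile_pore()] result.
#' @param frac Fraction of the radius range counted as "narrow"
#'   (default 0.25).
#' @param min_halfwidth Minimum half-width of the middle zone in Angstrom
#'   (default 1.0).
#' @param flat_tol Radius range below which the profile counts as flat
#'   (default 0.2 Angstrom).
#' @return Named list of `c(lo, hi)` axial intervals (`bottom`, `middle`,
#'   `top`), or a single `middle` interval for flat profiles.
#' @export
zone_boundaries_from_profile <- function(p, frac = 0.25, min_halfwidth = 1.0,
                                         flat_tol = 0.2) {
  stopifnot(inherits(p, "pore_profile"))
  prof <- p$profile
  rng <- range(prof$radius)
  if (diff(rng) < flat_tol) {
    warning("profile has no constriction; falling back to a single zone")
    return(list(middle = c(min(prof$z), max(prof$z))))
  }
  cutoff <- rng[1] + frac * diff(rng)
  imin <- which.min(prof$radius)
  lo <- imin
  while (lo > 1 && prof$radius[lo - 1] <= cutoff) lo <- lo - 1
  hi <- imin
  while (hi < nrow(prof) && prof$radius[hi + 1] <= cutoff) hi <- hi + 1
  z_lo <- min(prof$z[lo], prof$z[imin] - min_halfwidth)
  z_hi <- max(prof$z[hi], prof$z[imin] + min_halfwidth)
  z_lo <- max(z_lo, min(prof$z))
  z_hi <- min(z_hi, max(prof$z))
  zmin <- min(prof$z); zmax <- max(prof$z)
  zones <- list()
  if (z_lo > zmin) zones$bottom <- c(zmin, z_lo)
  zones$middle <- c(z_lo, z_hi)
  if (z_hi < zmax) zones$top <- c(z_hi, zmax)
  zones
}

#' Write a pore profile as CSV
#' @param p A [profile_pore()] result.
#' @param path Output CSV path.
#' @export
write_pore_profile <- function(p, path) {
  utils::write.csv(p$profile, path, row.names = FALSE)
  invisible(path)
}
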