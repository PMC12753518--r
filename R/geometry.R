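# Synthetic cochlear geometry: a parametric two-turn spiral with three
# stacked fluid ducts (scala tympani, scala media, scala vestibuli), a
# modiolar core, a bony capsule, and 25 auditory-nerve-fiber trajectories
# whose dendritic lengths reproduce the morphometric order statistics of the
# traced human fiber set (min 1,320 um, median 1,732 um, max 2,312 um).
#
# Conventions: all lengths in micrometers; the cochlear axis is +z; the
# insertion angle alpha is measured in degrees from the basal entry
# (alpha = 0) and increases apically up to 690 degrees (~1.9 turns).

#' Default configuration for the synthetic cochlea
#'
#' The parameter values are chosen once to satisfy the anatomical relations
#' the downstream analyses depend on: a duct-center arc length close to 25 mm
#' over the 690 degree span, duct calibers that taper apically, fiber
#' terminals at the scala tympani / organ-of-Corti boundary, and somas in a
#' Rosenthal's-canal band inside the modiolus.
#'
#' @param turns number of turns of the spiral (default 690/360).
#' @param basal_radius spiral (duct-center) radius at alpha = 0, um.
#' @param radius_ratio basal-to-apical radius ratio of the logarithmic spiral.
#' @param pitch vertical rise per full turn, um.
#' @param st_radii,sm_radii,sv_radii basal and apical cross-section radii of
#'   the three ducts, um.
#' @param partition thickness of the partition between ST and SV, um.
#' @param lamina_half half-thickness of the osseous-spiral-lamina shelf that
#'   carries the dendrites (labeled as modiolus tissue in the voxel map), um.
#' @param sm_gap lateral clearance of the scala media pocket, um.
#' @param terminal_radial_frac radial position of the fiber terminal
#'   (organ-of-Corti site) as a fraction of the ST radius, lateral of the
#'   duct center.
#' @param terminal_clear height of the terminal above the scala tympani
#'   roof, um (the basilar-membrane/lamina clearance).
#' @param soma_depth radial depth of the soma below the inner ST wall, um.
#' @param soma_drop height of the soma below the duct center, um.
#' @param dendrite_stats min/median/max dendritic (peripheral process)
#'   lengths, um.
#' @param axon_length arc length of central-axon trajectory to generate, um.
#' @param modiolus_margin radial clearance between the inner ST wall and the
#'   modiolar boundary, um.
#' @return a list of class `cochlea_config`.
#' @export
geometry_config <- function(turns = 690 / 360,
                            basal_radius = 2920,
                            radius_ratio = 2,
                            pitch = 1252,
                            st_radii = c(400, 260),
                            sm_radii = c(80, 60),
                            sv_radii = c(380, 240),
                            partition = 700,
                            lamina_half = 200,
                            sm_gap = 30,
                            terminal_radial_frac = 0.30,
                            terminal_clear = 600,
                            soma_depth = 150,
                            soma_drop = -100,
                            dendrite_stats = c(min = 1320, median = 1732, max = 2312),
                            axon_length = 6000,
                            modiolus_margin = 120) {
  cfg <- list(
    turns = turns, basal_radius = basal_radius, radius_ratio = radius_ratio,
    pitch = pitch, st_radii = st_radii, sm_radii = sm_radii,
    sv_radii = sv_radii, partition = partition, lamina_half = lamina_half,
    sm_gap = sm_gap,
    terminal_radial_frac = terminal_radial_frac,
    terminal_clear = terminal_clear,
    soma_depth = soma_depth, soma_drop = soma_drop,
    dendrite_stats = dendrite_stats, axon_length = axon_length,
    modiolus_margin = modiolus_margin
  )
  class(cfg) <- "cochlea_config"
  cfg
}

#' Build the synthetic cochlear geometry
#'
#' @param config a `cochlea_config`, see [geometry_config()].
#' @return an object of class `cochlear_geometry` with the cochlear axis
#'   (origin + unit vector), the insertion-angle range in degrees, and the
#'   parametric duct description. Deterministic for a fixed config.
#' @export
build_geometry <- function(config = geometry_config()) {
  numeric_fields <- c(
    "turns", "basal_radius", "radius_ratio", "pitch", "st_radii", "sm_radii",
    "sv_radii", "partition", "soma_depth", "axon_length"
  )
  for (f in numeric_fields) {
    v <- config[[f]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("configuration error: '%s' must be positive and finite", f))
    }
  }
  if (config$radius_ratio <= 1) {
    stop("configuration error: 'radius_ratio' must exceed 1")
  }
  alpha_max <- config$turns * 360
  geom <- list(
    config = config,
    axis_origin = c(0, 0, 0),
    axis_dir = c(0, 0, 1),
    alpha_range = c(0, alpha_max),
    lambda = log(config$radius_ratio) / alpha_max # per degree
  )
  class(geom) <- "cochlear_geometry"

  ## invariant check: duct cross-sections pairwise disjoint along the spiral
  a <- seq(0, alpha_max, by = 10)
  for (pair in list(c("st", "sm"), c("st", "sv"), c("sm", "sv"))) {
    c1 <- canal_center(geom, a, pair[1L]); r1 <- canal_radius(geom, a, pair[1L])
    c2 <- canal_center(geom, a, pair[2L]); r2 <- canal_radius(geom, a, pair[2L])
    d <- sqrt((c1[, 1L] - c2[, 1L])^2 + (c1[, 2L] - c2[, 2L])^2)
    if (any(d <= r1 + r2)) {
      stop(sprintf("configuration error: %s and %s cross-sections intersect",
                   pair[1L], pair[2L]))
    }
  }
  geom
}

#' Spiral (duct-center) radius at insertion angle alpha
#' @param geom a `cochlear_geometry`.
#' @param alpha insertion angle(s), degrees.
#' @return radius in um (logarithmic spiral, strictly decreasing in alpha).
#' @export
spiral_radius <- function(geom, alpha) {
  geom$config$basal_radius * exp(-geom$lambda * alpha)
}

#' Spiral (duct-center) height at insertion angle alpha
#' @inheritParams spiral_radius
#' @return height in um (linear in alpha, non-decreasing).
#' @export
spiral_height <- function(geom, alpha) {
  geom$config$pitch * alpha / 360
}

#' Cross-section radius of a duct at insertion angle alpha
#' @inheritParams spiral_radius
#' @param which one of "st", "sm", "sv".
#' @export
canal_radius <- function(geom, alpha, which = c("st", "sm", "sv")) {
  which <- match.arg(which)
  rr <- geom$config[[paste0(which, "_radii")]]
  frac <- alpha / geom$alpha_range[2L]
  rr[1L] + (rr[2L] - rr[1L]) * frac
}

#' Cross-section center of a duct in the (radial, z) half-plane at alpha
#' @inheritParams canal_radius
#' @return matrix with columns `radial` and `z` (um).
#' @export
canal_center <- function(geom, alpha, which = c("st", "sm", "sv")) {
  which <- match.arg(which)
  cfg <- geom$config
  r <- spiral_radius(geom, alpha)
  z <- spiral_height(geom, alpha)
  st <- canal_radius(geom, alpha, "st")
  out <- switch(which,
    st = cbind(r, z),
    sv = cbind(r, z + st + canal_radius(geom, alpha, "sv") + cfg$partition),
    sm = cbind(r + 0.75 * st + canal_radius(geom, alpha, "sm") + cfg$sm_gap,
               z + st + cfg$terminal_clear)
  )
  colnames(out) <- c("radial", "z")
  out
}

#' Map duct-frame coordinates to 3D
#'
#' @inheritParams spiral_radius
#' @param radial radial coordinate(s), um.
#' @param z height(s), um.
#' @return matrix of 3D points.
#' @export
frame_point <- function(geom, alpha, radial, z) {
  th <- alpha * pi / 180
  cbind(radial * cos(th), radial * sin(th), z)
}

#' Bounding box of the cochlear capsule
#' @param geom a `cochlear_geometry`.
#' @return list with `xy_radius` (capsule radius, um) and `z` (range, um).
#' @export
geometry_bbox <- function(geom) {
  cfg <- geom$config
  r0 <- cfg$basal_radius
  xy <- r0 + cfg$st_radii[1L] + 2 * cfg$sm_radii[1L] + cfg$sm_gap + 100
  sv_top <- max(canal_center(geom, seq(0, geom$alpha_range[2L], by = 5), "sv")[, "z"] +
                  canal_radius(geom, seq(0, geom$alpha_range[2L], by = 5), "sv"))
  list(xy_radius = xy, z = c(-1700, sv_top + 200))
}

#' Modiolar boundary radius at height z
#' @param geom a `cochlear_geometry`.
#' @param z height(s), um.
#' @return cylindrical radius of the modiolar domain at z (um).
#' @export
modiolus_radius <- function(geom, z) {
  zr <- c(0, spiral_height(geom, geom$alpha_range[2L]))
  zc <- pmin(pmax(z, zr[1L]), zr[2L])
  a <- geom$alpha_range[2L] * zc / zr[2L]
  out <- spiral_radius(geom, a) - canal_radius(geom, a, "st") -
    geom$config$modiolus_margin
  out[z < -1600 | z > zr[2L] + 400] <- 0
  out
}

## ---- fiber placement -------------------------------------------------------

#' The paper-named fiber insertion angles
#' @keywords internal
named_anf_alphas <- function() c(23, 77, 195, 256, 416, 467, 494, 680)

#' Default insertion angles for n fibers
#'
#' The named angles are always present for n >= 8; the remainder fill an even
#' grid over [23, 680] degrees (each named angle claims its nearest grid
#' slot).
#' @param n number of fibers.
#' @return sorted numeric vector of angles, degrees.
#' @export
default_anf_alphas <- function(n = 25L) {
  named <- named_anf_alphas()
  if (n < length(named)) return(named[seq_len(n)])
  grid <- seq(23, 680, length.out = n)
  taken <- rep(FALSE, n)
  for (a in named) {
    free <- which(!taken)
    slot <- free[which.min(abs(grid[free] - a))]
    grid[slot] <- a
    taken[slot] <- TRUE
  }
  sort(grid)
}

#' Deterministic dendritic-length profile
#'
#' Monotone decreasing in alpha (basal fibers have the longest peripheral
#' processes), piecewise-linearly rescaled so the default 25-fiber set
#' reproduces min = 1,320, median = 1,732 and max = 2,312 um exactly.
#' @param alpha insertion angle(s), degrees.
#' @return dendritic length(s), um.
#' @export
dendrite_length_profile <- function(alpha) {
  stats <- c(1320, 1732, 2312)
  a_med <- median(default_anf_alphas(25L))
  a_lo <- 23; a_hi <- 680
  alpha <- pmin(pmax(alpha, a_lo), a_hi)
  ifelse(alpha >= a_med,
    stats[1L] + (stats[2L] - stats[1L]) * (a_hi - alpha) / (a_hi - a_med),
    stats[2L] + (stats[3L] - stats[2L]) * (a_med - alpha) / (a_med - a_lo)
  )
}

## anchor points of the fiber course at angle alpha, in the duct frame: the
## dendrite leaves the organ-of-Corti terminal high on the lamina shelf,
## drops to a knee over the inner half of the duct, runs to the shelf's
## modiolar end, and hooks down into Rosenthal's canal (soma).
fiber_anchors <- function(geom, alpha) {
  cfg <- geom$config
  r <- spiral_radius(geom, alpha)
  z <- spiral_height(geom, alpha)
  st <- canal_radius(geom, alpha, "st")
  list(
    terminal = c(r + cfg$terminal_radial_frac * st,
                 z + st + cfg$terminal_clear),
    knee = c(r + 0.25 * st, z + st + 80),
    lamina_end = c(r - st - cfg$soma_depth + 100, z + st + 80),
    soma = c(r - st - cfg$soma_depth, z - cfg$soma_drop)
  )
}

## lamina-shelf height (duct-frame z) as a function of the radial
## coordinate, following the dendritic course; clamped outside its span
shelf_height <- function(geom, alpha, radial) {
  an_r <- spiral_radius(geom, alpha)
  st <- canal_radius(geom, alpha, "st")
  z <- spiral_height(geom, alpha)
  cfg <- geom$config
  xr <- cbind(an_r - st - cfg$soma_depth + 100, an_r + 0.25 * st,
              an_r + cfg$terminal_radial_frac * st)
  yz <- cbind(z + st + 80, z + st + 80, z + st + cfg$terminal_clear)
  out <- numeric(length(radial))
  lo <- radial <= xr[, 1L]
  hi <- radial >= xr[, 3L]
  mid1 <- !lo & radial <= xr[, 2L]
  mid2 <- !hi & radial > xr[, 2L]
  out[lo] <- yz[lo, 1L]
  out[hi] <- yz[hi, 3L]
  out[mid1] <- yz[mid1, 1L] + (yz[mid1, 2L] - yz[mid1, 1L]) *
    (radial[mid1] - xr[mid1, 1L]) / (xr[mid1, 2L] - xr[mid1, 1L])
  out[mid2] <- yz[mid2, 2L] + (yz[mid2, 3L] - yz[mid2, 2L]) *
    (radial[mid2] - xr[mid2, 2L]) / (xr[mid2, 3L] - xr[mid2, 2L])
  out
}

## peripheral (dendritic) course with exact arc length, in the duct frame:
## the lamina-shelf run (terminal -> knee -> modiolar shelf end) followed by
## a Bezier hook descending into Rosenthal's canal, whose dip is solved so
## the total arc length equals the requested dendritic length.
dendrite_curve <- function(geom, alpha, length_um) {
  an <- fiber_anchors(geom, alpha)
  p0 <- an$terminal
  s <- an$soma
  a_end <- an$lamina_end
  densify <- function(a, b) {
    n <- max(2L, ceiling(sqrt(sum((b - a)^2)) / 10))
    cbind(seq(a[1L], b[1L], length.out = n), seq(a[2L], b[2L], length.out = n))
  }
  shelf <- rbind(densify(p0, an$knee), densify(an$knee, a_end)[-1L, ])
  len1 <- sum(sqrt(rowSums((shelf[-1L, ] - shelf[-nrow(shelf), ])^2)))
  target2 <- length_um - len1
  leg2_len <- function(beta) {
    b <- bezier_points(c(a_end, 0), c(a_end[1L], a_end[2L] - beta, 0),
                       c(s[1L], s[2L] + 200, 0), c(s, 0), n = 200L)
    sum(sqrt(rowSums((b[-1L, 1:2, drop = FALSE] - b[-200L, 1:2, drop = FALSE])^2)))
  }
  if (target2 < leg2_len(0)) {
    stop(sprintf("dendritic length %.0f um infeasible at alpha %.0f", length_um, alpha))
  }
  beta <- uniroot(function(b) leg2_len(b) - target2, c(0, 9000), tol = 1e-4)$root
  leg2 <- bezier_points(c(a_end, 0), c(a_end[1L], a_end[2L] - beta, 0),
                        c(s[1L], s[2L] + 200, 0), c(s, 0), n = 200L)[, 1:2]
  rbind(shelf, leg2[-1L, , drop = FALSE])
}

## central (axonal) course: straight transition toward the modiolar core,
## then a descending helix of radius 500 um around the cochlear axis.
axon_curve <- function(geom, alpha, soma_frame, length_um) {
  th <- alpha * pi / 180
  s3 <- c(soma_frame[1L] * cos(th), soma_frame[1L] * sin(th), soma_frame[2L])
  h_entry <- c(500 * cos(th), 500 * sin(th), soma_frame[2L] - 600)
  trans_len <- sqrt(sum((h_entry - s3)^2))
  n1 <- max(2L, ceiling(trans_len / 20))
  trans <- cbind(seq(s3[1L], h_entry[1L], length.out = n1),
                 seq(s3[2L], h_entry[2L], length.out = n1),
                 seq(s3[3L], h_entry[3L], length.out = n1))
  rem <- max(length_um - trans_len, 500)
  per_turn <- sqrt((2 * pi * 500)^2 + 600^2)
  n_turns <- rem / per_turn
  tt <- seq(0, n_turns, length.out = max(3L, ceiling(rem / 20)))
  helix <- cbind(500 * cos(th + 2 * pi * tt),
                 500 * sin(th + 2 * pi * tt),
                 h_entry[3L] - 600 * tt)
  rbind(trans, helix[-1L, , drop = FALSE])
}

#' Place auditory nerve fiber trajectories
#'
#' Builds `n` fiber polylines running from the peripheral terminal at the
#' organ-of-Corti position, through the osseous spiral lamina, hooking down
#' into Rosenthal's canal (soma), and continuing as a central axon descending
#' through the modiolar core. Dendritic arc lengths follow
#' [dendrite_length_profile()] (deterministic anatomy, not a random draw).
#'
#' @param geom a `cochlear_geometry`.
#' @param n number of fibers (default 25).
#' @param alphas optional insertion angles, degrees; defaults to
#'   [default_anf_alphas()]. Must lie inside the geometry range.
#' @param seed optional integer, stored for provenance; placement itself is
#'   deterministic.
#' @return an object of class `anf_set`: list of `anf_path` objects with
#'   fields `id` ("ANF<alpha>"), `alpha_deg`, `polyline` (3D um), and arc
#'   landmarks `dendrite_length` and `soma_arc_pos`.
#' @export
place_anfs <- function(geom, n = 25L, alphas = NULL, seed = NULL) {
  if (n < 1L) stop("n must be >= 1")
  if (is.null(alphas)) alphas <- default_anf_alphas(n)
  if (length(alphas) != n) stop("length(alphas) must equal n")
  if (any(alphas < 23 - 1e-9 | alphas > geom$alpha_range[2L] + 1e-9)) {
    stop("fiber alpha outside the geometry range [23, alpha_max]")
  }
  fibers <- lapply(alphas, function(a) {
    len <- dendrite_length_profile(a)
    dcur <- dendrite_curve(geom, a, len)
    th <- a * pi / 180
    d3 <- cbind(dcur[, 1L] * cos(th), dcur[, 1L] * sin(th), dcur[, 2L])
    soma_frame <- fiber_anchors(geom, a)$soma
    a3 <- axon_curve(geom, a, soma_frame, geom$config$axon_length)
    poly <- rbind(d3, a3[-1L, , drop = FALSE])
    structure(list(
      id = sprintf("ANF%d", round(a)),
      alpha_deg = a,
      polyline = poly,
      dendrite_length = len,
      soma_arc_pos = len + 10
    ), class = "anf_path")
  })
  structure(fibers, class = "anf_set", seed = seed)
}

#' @export
print.cochlear_geometry <- function(x, ...) {
  cat(sprintf(
    "Synthetic cochlear geometry: alpha in [%g, %g] deg, basal radius %g um,\n",
    x$alpha_range[1L], x$alpha_range[2L], x$config$basal_radius
  ))
  cat(sprintf("  duct-center arc length %.1f mm, pitch %g um/turn\n",
              duct_center_arclength(x) / 1000, x$config$pitch))
  invisible(x)
}

#' @export
print.anf_set <- function(x, ...) {
  al <- vapply(x, function(f) f$alpha_deg, numeric(1L))
  dl <- vapply(x, function(f) f$dendrite_length, numeric(1L))
  cat(sprintf("%d auditory nerve fibers, alpha %g-%g deg,\n", length(x),
              min(al), max(al)))
  cat(sprintf("  dendritic length %g-%g um (median %g)\n", min(dl), max(dl),
              median(dl)))
  invisible(x)
}

#' Arc length of the duct-center spiral
#' @param geom a `cochlear_geometry`.
#' @return arc length in um over the full alpha range.
#' @export
duct_center_arclength <- function(geom) {
  a <- seq(0, geom$alpha_range[2L], by = 0.5)
  pts <- frame_point(geom, a, spiral_radius(geom, a), spiral_height(geom, a))
  s <- polyline_arclength(pts)
  s[length(s)]
}

#' Analytic duct volume of the parametric solid
#'
#' Exact volume of the swept-disk solid in cylindrical coordinates:
#' V = int pi rho(alpha)^2 r_c(alpha) d alpha (alpha in radians), where rho is
#' the cross-section radius and r_c the radial coordinate of its center.
#' Evaluated by fine trapezoidal quadrature.
#'
#' @param geom a `cochlear_geometry`.
#' @param which duct name.
#' @return volume in um^3.
#' @export
duct_volume <- function(geom, which = c("st", "sm", "sv")) {
  which <- match.arg(which)
  a <- seq(0, geom$alpha_range[2L], length.out = 4001L)
  rho <- canal_radius(geom, a, which)
  rc <- canal_center(geom, a, which)[, "radial"]
  f <- pi * rho^2 * rc
  da <- diff(a[1:2]) * pi / 180
  sum((f[-1L] + f[-length(f)]) / 2) * da
}
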