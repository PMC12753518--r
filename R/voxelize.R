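# Voxelized conductivity map of the implanted cochlea. Domains: the three
# fluid ducts, modiolus, bony capsule, silicone carrier, platinum contacts,
# and the surrounding (bone-like) exterior standing in for the grounded
# far-field sphere. The exterior padding is at least one cochlear diameter on
# all sides; the box boundary is the monopolar return (ground).

DOMAIN_LEVELS <- c("exterior", "bone", "modiolus", "st", "sm", "sv",
                   "carrier", "contact")

#' Default domain conductivities (S/m)
#'
#' Perilymph 1.43 (ST, SV), endolymph 1.67 (SM), modiolus 0.0334, compact
#' bone and surrounding medium 0.016, contacts 1000. The silicone carrier is
#' an insulator; it carries 1e-6 S/m in the discrete map to keep the
#' finite-difference operator non-singular.
#'
#' @return named numeric vector over the domain labels.
#' @export
default_conductivities <- function() {
  c(exterior = 0.016, bone = 0.016, modiolus = 0.0334,
    st = 1.43, sm = 1.67, sv = 1.43, carrier = 1e-6, contact = 1000)
}

#' Ossification stages as scala tympani conductivities (S/m)
#' @return named numeric vector (developing 1, moderate 0.65, severe 0.3,
#'   complete 0.03).
#' @export
ossification_levels <- function() {
  c(developing = 1, moderate = 0.65, severe = 0.3, complete = 0.03)
}

#' Voxelize the cochlear geometry and electrode arrays
#'
#' Voxel centers are classified into domains in priority order: contacts
#' override carrier, carrier overrides duct fluid, ducts override modiolus
#' and bone. Contacts are rasterized conservatively (a voxel belongs to a
#' contact when its center lies within half a voxel spacing of the
#' cylinder), so the injection site exists at coarse resolutions; the
#' carrier is rasterized by strict center-in-solid so the perilymph sheath
#' around it is preserved.
#'
#' @param geom a `cochlear_geometry`.
#' @param arrays list of `electrode_array` objects to embed (may be empty).
#' @param spacing voxel edge length, um.
#' @param conductivities named vector, see [default_conductivities()].
#' @param ossification "none" or one of `names(ossification_levels())`.
#' @param padding exterior padding, um; default (and minimum) one cochlear
#'   diameter.
#' @return object of class `conductivity_map` with `sigma` and `label` 3D
#'   arrays, axis coordinate vectors, and per-contact voxel indices.
#' @export
voxelize <- function(geom, arrays = list(), spacing,
                     conductivities = default_conductivities(),
                     ossification = "none", padding = NULL) {
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be positive")
  bb <- geometry_bbox(geom)
  diam <- 2 * bb$xy_radius
  if (is.null(padding)) padding <- diam
  if (padding < diam) stop("exterior padding below one cochlear diameter")
  ext <- bb$xy_radius + padding
  xs <- grid_axis(-ext, ext, spacing)
  ys <- xs
  zs <- grid_axis(bb$z[1L] - padding, bb$z[2L] + padding, spacing)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)

  X <- rep(xs, times = ny * nz)
  Y <- rep(rep(ys, each = nx), times = nz)
  Z <- rep(zs, each = nx * ny)
  lab <- rep(1L, nx * ny * nz) # exterior

  cylr <- sqrt(X^2 + Y^2)
  cap <- cylr <= bb$xy_radius & Z >= bb$z[1L] & Z <= bb$z[2L]
  lab[cap] <- 2L # bone
  lab[cylr < modiolus_radius(geom, Z)] <- 3L

  th <- (atan2(Y, X) * 180 / pi) %% 360
  amax <- geom$alpha_range[2L]
  cand <- which(cap)
  ## osseous spiral lamina: the sheet carrying the dendrites over the top of
  ## the scala tympani belongs to the modiolus domain
  for (k in 0:1) {
    al <- th[cand] + 360 * k
    ok <- al <= amax
    ci <- cand[ok]; al <- al[ok]
    r <- spiral_radius(geom, al)
    z <- spiral_height(geom, al)
    st <- canal_radius(geom, al, "st")
    inside <- cylr[ci] > r - st - geom$config$modiolus_margin &
      cylr[ci] < r + 0.75 * st &
      abs(Z[ci] - shelf_height(geom, al, cylr[ci])) < geom$config$lamina_half
    lab[ci[inside]] <- 3L
  }
  for (k in 0:1) {
    al <- th[cand] + 360 * k
    ok <- al <= amax
    ci <- cand[ok]; al <- al[ok]
    for (duct in c("st", "sm", "sv")) {
      cc <- canal_center(geom, al, duct)
      rho <- canal_radius(geom, al, duct)
      inside <- (cylr[ci] - cc[, "radial"])^2 + (Z[ci] - cc[, "z"])^2 < rho^2
      lab[ci[inside]] <- match(duct, DOMAIN_LEVELS)
    }
  }

  contact_voxels <- list()
  for (arr in arrays) {
    scala_lab <- match(arr$centerline$scala, DOMAIN_LEVELS)
    idx <- which(lab == scala_lab | lab == 7L)
    if (length(idx)) {
      cp <- arr$centerline$points
      crad <- carrier_radius(arr$centerline, arr$centerline$alpha)
      nd <- polyline_min_dist(cbind(X[idx], Y[idx], Z[idx]), cp)
      inside <- nd$dist < crad[nd$index]
      lab[idx[inside]] <- 7L # carrier
    }
    ct <- arr$contacts
    for (i in seq_len(nrow(ct))) {
      ctr <- c(ct$x[i], ct$y[i], ct$z[i])
      axis <- c(ct$ox[i], ct$oy[i], ct$oz[i])
      reach <- ct$radius[i] + ct$height[i] + spacing
      near <- which(abs(X - ctr[1L]) < reach & abs(Y - ctr[2L]) < reach &
                      abs(Z - ctr[3L]) < reach)
      dx <- X[near] - ctr[1L]; dy <- Y[near] - ctr[2L]; dz <- Z[near] - ctr[3L]
      axial <- dx * axis[1L] + dy * axis[2L] + dz * axis[3L]
      rad2 <- dx^2 + dy^2 + dz^2 - axial^2
      inside <- abs(axial) <= ct$height[i] / 2 & rad2 <= ct$radius[i]^2
      if (!any(inside)) {
        ## conservative fallback: dilate by half a spacing so a thin contact
        ## still occupies the voxel(s) it straddles
        inside <- abs(axial) <= ct$height[i] / 2 + spacing / 2 &
          rad2 <= (ct$radius[i] + spacing / 2)^2
      }
      vox <- near[inside]
      if (!length(vox)) {
        stop(sprintf("spacing %g um too coarse: contact %s occupies no voxels",
                     spacing, ct$id[i]))
      }
      lab[vox] <- 8L
      key <- if (length(arrays) > 1L) paste(arr$tag, ct$id[i], sep = ":") else ct$id[i]
      contact_voxels[[key]] <- vox
    }
  }

  sigma <- unname(conductivities[DOMAIN_LEVELS])[lab]
  map <- structure(list(
    spacing = spacing, xs = xs, ys = ys, zs = zs,
    dim = c(nx, ny, nz),
    sigma = array(sigma, dim = c(nx, ny, nz)),
    label = array(lab, dim = c(nx, ny, nz)),
    legend = setNames(seq_along(DOMAIN_LEVELS), DOMAIN_LEVELS),
    conductivities = conductivities,
    contact_voxels = contact_voxels,
    arrays = vapply(arrays, function(a) a$tag, character(1L))
  ), class = "conductivity_map")
  if (!identical(ossification, "none")) map <- apply_ossification(map, ossification)
  map
}

grid_axis <- function(lo, hi, spacing) {
  n <- ceiling((hi - lo) / spacing) + 1L
  mid <- (lo + hi) / 2
  mid + (seq_len(n) - (n + 1) / 2) * spacing
}

#' @export
print.conductivity_map <- function(x, ...) {
  cat(sprintf("Conductivity map %d x %d x %d voxels at %g um spacing\n",
              x$dim[1L], x$dim[2L], x$dim[3L], x$spacing))
  tab <- table(factor(DOMAIN_LEVELS[x$label], levels = DOMAIN_LEVELS))
  print(tab)
  invisible(x)
}

#' Set the scala tympani conductivity (ossification)
#'
#' @param map a `conductivity_map`.
#' @param level a stage name from [ossification_levels()] or a numeric
#'   conductivity in S/m.
#' @return modified map.
#' @export
apply_ossification <- function(map, level) {
  sig <- if (is.numeric(level)) level else {
    lv <- ossification_levels()
    if (!level %in% names(lv)) stop(sprintf("unknown ossification level '%s'", level))
    lv[[level]]
  }
  if (sig <= 0) stop("ST conductivity must be positive")
  map$sigma[map$label == map$legend[["st"]]] <- sig
  map$conductivities[["st"]] <- sig
  map
}

#' Scale modiolus and/or bone conductivities
#'
#' @param map a `conductivity_map`.
#' @param modiolus_factor multiplier of the modiolar conductivity.
#' @param bone_factor multiplier of the bone (and exterior medium)
#'   conductivity.
#' @return modified map.
#' @export
conductivity_variant <- function(map, modiolus_factor = 1, bone_factor = 1) {
  if (modiolus_factor <= 0 || bone_factor <= 0) stop("factors must be positive")
  if (modiolus_factor != 1) {
    sel <- map$label == map$legend[["modiolus"]]
    map$sigma[sel] <- map$sigma[sel] * modiolus_factor
    map$conductivities[["modiolus"]] <- map$conductivities[["modiolus"]] * modiolus_factor
  }
  if (bone_factor != 1) {
    sel <- map$label == map$legend[["bone"]] | map$label == map$legend[["exterior"]]
    map$sigma[sel] <- map$sigma[sel] * bone_factor
    map$conductivities[["bone"]] <- map$conductivities[["bone"]] * bone_factor
    map$conductivities[["exterior"]] <- map$conductivities[["exterior"]] * bone_factor
  }
  map
}

#' Labeled volume of a domain
#' @param map a `conductivity_map`.
#' @param which domain name.
#' @return volume in um^3.
#' @export
domain_volume <- function(map, which) {
  sum(map$label == map$legend[[which]]) * map$spacing^3
}

#' Construct a uniform conductivity map (for solver verification)
#'
#' @param n voxels per edge.
#' @param spacing voxel edge, um.
#' @param sigma conductivity, S/m.
#' @return `conductivity_map` with all voxels labeled exterior.
#' @export
uniform_map <- function(n, spacing, sigma = 1.43) {
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  structure(list(
    spacing = spacing, xs = ax, ys = ax, zs = ax, dim = c(n, n, n),
    sigma = array(sigma, dim = c(n, n, n)),
    label = array(1L, dim = c(n, n, n)),
    legend = setNames(seq_along(DOMAIN_LEVELS), DOMAIN_LEVELS),
    conductivities = c(default_conductivities()[1:7], contact = 1000),
    contact_voxels = list(),
    arrays = character(0)
  ), class = "conductivity_map")
}
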