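# Extracellular field computation for monopolar unit-current stimulation:
# analytic point source in a homogeneous medium, and a 7-point
# finite-difference solution of div(sigma grad V) = -source on the voxel
# conductivity map with harmonic-mean face conductivities and a grounded
# (Dirichlet 0) outer box boundary.

#' Analytic point-source potential in a homogeneous medium
#'
#' Ve = I / (4 pi sigma r).
#'
#' @param I injected current, uA.
#' @param sigma conductivity, S/m.
#' @param r distance(s), um.
#' @return potential in mV.
#' @export
point_source_potential <- function(I = 1, sigma, r) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(r <= 0)) stop("singularity: r must be positive")
  1000 * I / (4 * pi * sigma * r)
}

## face conductances in mS for the 7-point stencil; ghost Dirichlet faces
## folded into the diagonal
face_conductances <- function(map) {
  s <- map$sigma
  if (any(s <= 0)) stop("conductivity map contains non-positive sigma")
  d <- map$dim
  h <- map$spacing
  harm <- function(a, b) 2 * a * b / (a + b)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[-d[1L], , ] <- harm(s[-d[1L], , , drop = FALSE], s[-1L, , , drop = FALSE])
  gy[, -d[2L], ] <- harm(s[, -d[2L], , drop = FALSE], s[, -1L, , drop = FALSE])
  gz[, , -d[3L]] <- harm(s[, , -d[3L], drop = FALSE], s[, , -1L, drop = FALSE])
  scale <- h * 1e-3 # sigma [S/m] * h [um] * 1e-6 -> S; * 1e3 -> mS
  gx <- gx * scale; gy <- gy * scale; gz <- gz * scale
  diag <- array(0, d)
  diag[-1L, , ] <- diag[-1L, , , drop = FALSE] + gx[-d[1L], , , drop = FALSE]
  diag[-d[1L], , ] <- diag[-d[1L], , , drop = FALSE] + gx[-d[1L], , , drop = FALSE]
  diag[, -1L, ] <- diag[, -1L, , drop = FALSE] + gy[, -d[2L], , drop = FALSE]
  diag[, -d[2L], ] <- diag[, -d[2L], , drop = FALSE] + gy[, -d[2L], , drop = FALSE]
  diag[, , -1L] <- diag[, , -1L, drop = FALSE] + gz[, , -d[3L], drop = FALSE]
  diag[, , -d[3L]] <- diag[, , -d[3L], drop = FALSE] + gz[, , -d[3L], drop = FALSE]
  ## Dirichlet ghost faces at half a spacing outside each boundary plane
  gb <- 2 * scale
  diag[1L, , ] <- diag[1L, , , drop = FALSE] + gb * s[1L, , , drop = FALSE]
  diag[d[1L], , ] <- diag[d[1L], , , drop = FALSE] + gb * s[d[1L], , , drop = FALSE]
  diag[, 1L, ] <- diag[, 1L, , drop = FALSE] + gb * s[, 1L, , drop = FALSE]
  diag[, d[2L], ] <- diag[, d[2L], , drop = FALSE] + gb * s[, d[2L], , drop = FALSE]
  diag[, , 1L] <- diag[, , 1L, drop = FALSE] + gb * s[, , 1L, drop = FALSE]
  diag[, , d[3L]] <- diag[, , d[3L], drop = FALSE] + gb * s[, , d[3L], drop = FALSE]
  list(gx = as.numeric(gx), gy = as.numeric(gy), gz = as.numeric(gz),
       diag = as.numeric(diag))
}

rhs_for_contact <- function(map, contact) {
  n <- prod(map$dim)
  b <- numeric(n)
  if (is.character(contact)) {
    vox <- map$contact_voxels[[contact]]
    if (is.null(vox)) stop(sprintf("unknown contact '%s' in map", contact))
  } else {
    vox <- as.integer(contact) # raw voxel indices (testing)
  }
  b[vox] <- 1 / length(vox) # 1 uA total, uniform over contact voxels
  b
}

#' Solve the extracellular potential for a unit monopolar current
#'
#' Injects 1 uA distributed uniformly over the contact voxels and solves the
#' finite-difference system to a relative residual of `tol`.
#'
#' @param map a `conductivity_map`.
#' @param contact a contact id present in the map, or an integer vector of
#'   voxel indices to use as the source (for verification studies).
#' @param method "pcg" (matrix-free preconditioned conjugate gradients) or
#'   "cholesky" (sparse direct solve; equivalent within the residual
#'   contract).
#' @param tol relative residual tolerance.
#' @param maxit PCG iteration cap.
#' @param boundary "ground" (Dirichlet 0 on the padded box, the stand-in for
#'   the grounded far-field sphere) or "free" (Dirichlet values from the
#'   analytic monopole about the source centroid; used to verify the interior
#'   discretization against the free-space solution on uniform maps).
#' @param warm_start optional `field_solution` on the same grid used as the
#'   PCG initial guess (effective when only part of the conductivity map
#'   changed, as in the sensitivity sweeps).
#' @return object of class `field_solution`: per-voxel potential `v` (mV per
#'   uA), grid axes, contact id and solver metadata.
#' @export
solve_field <- function(map, contact, method = c("pcg", "cholesky"),
                        tol = 1e-8, maxit = 50000L,
                        boundary = c("ground", "free"), warm_start = NULL) {
  method <- match.arg(method)
  boundary <- match.arg(boundary)
  fc <- face_conductances(map)
  b <- rhs_for_contact(map, contact)
  if (boundary == "free") {
    b <- b + free_boundary_rhs(map, contact)
  }
  if (method == "pcg") {
    x0 <- if (inherits(warm_start, "field_solution")) {
      as.numeric(warm_start$v)
    } else {
      numeric(0)
    }
    sol <- pcg_solve(fc$diag, fc$gx, fc$gy, fc$gz, b, as.integer(map$dim),
                     tol, as.integer(maxit), x0)
    if (sol$residual > tol) {
      err <- simpleError(sprintf(
        "field solver did not converge: residual %.3g after %d iterations",
        sol$residual, sol$iterations))
      err$residual_history <- sol$residual_history
      stop(err)
    }
    v <- sol$v
    meta <- list(method = "pcg", iterations = sol$iterations,
                 residual = sol$residual)
  } else {
    A <- stencil_matrix(fc, map$dim)
    ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
    v <- as.numeric(Matrix::solve(ch, b))
    resid <- sqrt(sum((as.numeric(A %*% v) - b)^2)) / sqrt(sum(b^2))
    meta <- list(method = "cholesky", iterations = 1L, residual = resid)
  }
  field_solution(map, contact, v, meta)
}

#' Solve fields for many contacts of one map with a single factorization
#'
#' @param map a `conductivity_map`.
#' @param contacts character vector of contact ids (default: all in the map).
#' @return named list of `field_solution` objects.
#' @export
solve_field_set <- function(map, contacts = names(map$contact_voxels)) {
  if (!length(contacts)) stop("no contacts to solve")
  fc <- face_conductances(map)
  A <- stencil_matrix(fc, map$dim)
  ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  B <- vapply(contacts, function(cid) rhs_for_contact(map, cid),
              numeric(prod(map$dim)))
  V <- as.matrix(Matrix::solve(ch, B))
  out <- lapply(seq_along(contacts), function(i) {
    resid <- sqrt(sum((as.numeric(A %*% V[, i]) - B[, i])^2)) / sqrt(sum(B[, i]^2))
    field_solution(map, contacts[i], V[, i],
                   list(method = "cholesky", iterations = 1L, residual = resid))
  })
  names(out) <- contacts
  out
}

## Dirichlet boundary contribution for the free-space verification mode:
## each boundary face (at half a spacing outside the last voxel center)
## carries the analytic monopole potential of the source centroid.
free_boundary_rhs <- function(map, contact) {
  vox <- if (is.character(contact)) map$contact_voxels[[contact]] else as.integer(contact)
  d <- map$dim
  ijk <- arrayInd(vox, d)
  ctr <- c(mean(map$xs[ijk[, 1L]]), mean(map$ys[ijk[, 2L]]), mean(map$zs[ijk[, 3L]]))
  sigma <- map$sigma[vox[1L]]
  h <- map$spacing
  b <- array(0, d)
  gb <- function(s) 2 * s * h * 1e-3 # boundary face conductance, mS
  add_face <- function(b, ax, side) {
    idx <- lapply(seq_len(3L), function(a) seq_len(d[a]))
    idx[[ax]] <- if (side == 1L) 1L else d[ax]
    co <- expand.grid(i = idx[[1L]], j = idx[[2L]], k = idx[[3L]])
    px <- map$xs[co$i]; py <- map$ys[co$j]; pz <- map$zs[co$k]
    if (ax == 1L) px <- px + (if (side == 1L) -h / 2 else h / 2)
    if (ax == 2L) py <- py + (if (side == 1L) -h / 2 else h / 2)
    if (ax == 3L) pz <- pz + (if (side == 1L) -h / 2 else h / 2)
    r <- sqrt((px - ctr[1L])^2 + (py - ctr[2L])^2 + (pz - ctr[3L])^2)
    sv <- map$sigma[cbind(co$i, co$j, co$k)]
    b[cbind(co$i, co$j, co$k)] <- b[cbind(co$i, co$j, co$k)] +
      gb(sv) * point_source_potential(1, sigma, r)
    b
  }
  for (ax in 1:3) for (side in 1:2) b <- add_face(b, ax, side)
  as.numeric(b)
}

stencil_matrix <- function(fc, dims) {
  n <- prod(dims)
  nx <- dims[1L]; nxy <- dims[1L] * dims[2L]
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (ax in 1:3) {
    g <- switch(ax, fc$gx, fc$gy, fc$gz)
    stride <- switch(ax, 1L, nx, nxy)
    has <- which(g != 0)
    ii <- c(ii, has); jj <- c(jj, has + stride); xx <- c(xx, -g[has])
  }
  Matrix::sparseMatrix(
    i = c(seq_len(n), ii, jj), j = c(seq_len(n), jj, ii),
    x = c(fc$diag, xx, xx), dims = c(n, n)
  )
}

field_solution <- function(map, contact, v, meta) {
  structure(list(
    v = array(v, dim = map$dim),
    xs = map$xs, ys = map$ys, zs = map$zs, spacing = map$spacing,
    dim = map$dim,
    contact = if (is.character(contact)) contact else "voxel-source",
    source_voxels = if (is.character(contact)) map$contact_voxels[[contact]] else as.integer(contact),
    current_uA = 1,
    meta = meta
  ), class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf(
    "Field solution for contact %s (1 uA): %s, residual %.2e, max |Ve| %.3g mV\n",
    x$contact, x$meta$method, x$meta$residual, max(abs(x$v))))
  invisible(x)
}

#' Sample the potential at arbitrary points (trilinear interpolation)
#'
#' @param field a `field_solution`.
#' @param points matrix of 3D points (um), one per row.
#' @return numeric vector of potentials, mV per uA, in input order.
#' @export
sample_potential <- function(field, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  xs <- field$xs; ys <- field$ys; zs <- field$zs
  h <- field$spacing
  out <- numeric(nrow(points))
  bad <- points[, 1L] < xs[1L] | points[, 1L] > xs[length(xs)] |
    points[, 2L] < ys[1L] | points[, 2L] > ys[length(ys)] |
    points[, 3L] < zs[1L] | points[, 3L] > zs[length(zs)]
  if (any(bad)) {
    p <- points[which(bad)[1L], ]
    stop(sprintf("point (%.1f, %.1f, %.1f) outside the field grid",
                 p[1L], p[2L], p[3L]))
  }
  ix <- pmin(pmax(floor((points[, 1L] - xs[1L]) / h) + 1L, 1L), length(xs) - 1L)
  iy <- pmin(pmax(floor((points[, 2L] - ys[1L]) / h) + 1L, 1L), length(ys) - 1L)
  iz <- pmin(pmax(floor((points[, 3L] - zs[1L]) / h) + 1L, 1L), length(zs) - 1L)
  fx <- (points[, 1L] - xs[ix]) / h
  fy <- (points[, 2L] - ys[iy]) / h
  fz <- (points[, 3L] - zs[iz]) / h
  v <- field$v
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    out <- out + w * v[cbind(ix + dx, iy + dy, iz + dz)]
  }
  out
}

#' Normalized potential profile along the electrode carrier
#'
#' Samples the potential along the array centerline and normalizes by its
#' maximum (which lies at the active contact's angle).
#'
#' @param field a `field_solution`.
#' @param centerline a `centerline`.
#' @param active_alpha angle of the active contact, degrees (metadata).
#' @return list with `alpha` (degrees), `profile` (normalized to max 1), and
#'   `alpha_at_max`.
#' @export
potential_along_carrier <- function(field, centerline, active_alpha = NA) {
  ve <- sample_potential(field, centerline$points)
  vmax <- max(abs(ve))
  if (vmax == 0) stop("zero field: cannot normalize carrier profile")
  prof <- ve / ve[which.max(abs(ve))]
  list(alpha = centerline$alpha, profile = prof,
       alpha_at_max = centerline$alpha[which.max(abs(ve))],
       active_alpha = active_alpha)
}

#' Net current through a closed voxel box around the source
#'
#' Sums the face currents crossing the axis-aligned box `lo:hi` (voxel index
#' ranges). For a correct discrete solution this equals the injected current
#' when the box encloses the source and no boundary.
#'
#' @param field a `field_solution`.
#' @param map the `conductivity_map` it was solved on.
#' @param lo,hi integer length-3 voxel index corners (inclusive).
#' @return outward current, uA.
#' @export
flux_through_box <- function(field, map, lo, hi) {
  fc <- face_conductances(map)
  d <- map$dim
  g <- list(array(fc$gx, d), array(fc$gy, d), array(fc$gz, d))
  v <- field$v
  out <- 0
  for (ax in 1:3) {
    idx_in <- lapply(1:3, function(a) seq(lo[a], hi[a]))
    ## +face: between hi[ax] and hi[ax]+1
    ip <- idx_in; ip[[ax]] <- hi[ax]
    op <- idx_in; op[[ax]] <- hi[ax] + 1L
    out <- out + sum(do.call(`[`, c(list(g[[ax]]), ip, drop = FALSE)) *
                       (do.call(`[`, c(list(v), ip, drop = FALSE)) -
                          do.call(`[`, c(list(v), op, drop = FALSE))))
    ## -face: between lo[ax]-1 and lo[ax]
    im <- idx_in; im[[ax]] <- lo[ax] - 1L
    om <- idx_in; om[[ax]] <- lo[ax]
    out <- out + sum(do.call(`[`, c(list(g[[ax]]), im, drop = FALSE)) *
                       (do.call(`[`, c(list(v), om, drop = FALSE)) -
                          do.call(`[`, c(list(v), im, drop = FALSE))))
  }
  out
}
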