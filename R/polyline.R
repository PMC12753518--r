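# Polyline utilities shared by the geometry, array and cable modules.
# All coordinates are micrometers in a right-handed frame with the cochlear
# axis along +z.

#' Cumulative arc length of a polyline
#'
#' @param pts numeric matrix, one 3D point per row (columns x, y, z).
#' @return numeric vector of cumulative arc lengths, starting at 0.
#' @export
polyline_arclength <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

#' Resample a polyline at (approximately) uniform arc-length spacing
#'
#' Linear interpolation between vertices; the first and last points are kept
#' exactly so the total arc length is preserved to interpolation accuracy.
#'
#' @param pts matrix of 3D points.
#' @param spacing target spacing in micrometers.
#' @return matrix of resampled points.
#' @export
resample_polyline <- function(pts, spacing) {
  s <- polyline_arclength(pts)
  total <- s[length(s)]
  n <- max(2L, ceiling(total / spacing) + 1L)
  si <- seq(0, total, length.out = n)
  cbind(
    approx(s, pts[, 1L], xout = si)$y,
    approx(s, pts[, 2L], xout = si)$y,
    approx(s, pts[, 3L], xout = si)$y
  )
}

#' Point on a polyline at a given arc position
#'
#' @param pts matrix of 3D points.
#' @param at arc positions (micrometers from the first vertex).
#' @return matrix of interpolated points, one row per element of `at`.
#' @export
polyline_point_at <- function(pts, at) {
  s <- polyline_arclength(pts)
  if (any(at < -1e-9 | at > s[length(s)] + 1e-9)) {
    stop("arc position outside polyline range")
  }
  at <- pmin(pmax(at, 0), s[length(s)])
  cbind(
    approx(s, pts[, 1L], xout = at)$y,
    approx(s, pts[, 2L], xout = at)$y,
    approx(s, pts[, 3L], xout = at)$y
  )
}

#' Minimum distance from each of a set of query points to a polyline
#'
#' Vectorized over vertices only (the polyline is assumed densely sampled).
#'
#' @param q matrix of query points (rows).
#' @param pts polyline vertex matrix.
#' @return list with `dist` (per query point) and `index` (nearest vertex row).
#' @keywords internal
polyline_min_dist <- function(q, pts) {
  ## distance matrix computed blockwise to bound memory
  nq <- nrow(q)
  dist <- numeric(nq)
  idx <- integer(nq)
  block <- max(1L, floor(2e6 / nrow(pts)))
  px <- pts[, 1L]; py <- pts[, 2L]; pz <- pts[, 3L]
  for (start in seq(1L, nq, by = block)) {
    end <- min(start + block - 1L, nq)
    qq <- q[start:end, , drop = FALSE]
    d2 <- outer(qq[, 1L], px, "-")^2 +
      outer(qq[, 2L], py, "-")^2 +
      outer(qq[, 3L], pz, "-")^2
    idx[start:end] <- max.col(-d2, ties.method = "first")
    dist[start:end] <- sqrt(d2[cbind(seq_len(end - start + 1L), idx[start:end])])
  }
  list(dist = dist, index = idx)
}

#' Sample a cubic Bezier segment
#' @keywords internal
bezier_points <- function(p0, c1, c2, p1, n = 200L) {
  t <- seq(0, 1, length.out = n)
  b0 <- (1 - t)^3; b1 <- 3 * (1 - t)^2 * t; b2 <- 3 * (1 - t) * t^2; b3 <- t^3
  cbind(
    b0 * p0[1L] + b1 * c1[1L] + b2 * c2[1L] + b3 * p1[1L],
    b0 * p0[2L] + b1 * c1[2L] + b2 * c2[2L] + b3 * p1[2L],
    b0 * p0[3L] + b1 * c1[3L] + b2 * c2[3L] + b3 * p1[3L]
  )
}
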