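# Electrode-array construction: iterative cubic-spline centerline fit inside
# the scala tympani or scala vestibuli holding an approximately constant
# minimum distance (255 um) to all fiber trajectories, a carrier tapering
# from 600 to 300 um diameter, and cylindrical contacts oriented either
# toward the fibers (default) or toward the cochlear axis (alternative).

ARRAY_TARGET_DIST <- 255   # um, centerline-to-fiber minimum distance
CARRIER_RADIUS_BASE <- 300 # um at alpha = 0
CARRIER_RADIUS_APEX <- 150 # um at the apical end

#' Carrier radius at insertion angle alpha
#' @param centerline a `centerline` object.
#' @param alpha insertion angle(s), degrees.
#' @return carrier radius, um (monotone taper, 300 um basal to 150 um apical).
#' @export
carrier_radius <- function(centerline, alpha) {
  amax <- centerline$alpha_max
  CARRIER_RADIUS_BASE +
    (CARRIER_RADIUS_APEX - CARRIER_RADIUS_BASE) * alpha / amax
}

## evaluate a centerline parameterized by duct-frame offsets at angles a
centerline_eval <- function(geom, scala, alphas_ctrl, u, v, a) {
  uf <- splinefun(alphas_ctrl, u, method = "natural")
  vf <- splinefun(alphas_ctrl, v, method = "natural")
  cc <- canal_center(geom, a, scala)
  frame_point(geom, a, cc[, "radial"] + uf(a), cc[, "z"] + vf(a))
}

#' Fit an electrode-array centerline
#'
#' Alternating-projection fit: at each iteration the nearest centerline point
#' to every fiber is projected onto the 255 um isodistance surface of that
#' fiber; the z (height) component of the projection follows the fiber-derived
#' slope while the radial component moves the curve laterally; the control
#' offsets are under-relaxed, clamped inside the scala cross-section, and
#' re-splined. Converges when the largest control-point move drops below
#' `tol`.
#'
#' @param geom a `cochlear_geometry`.
#' @param anfs an `anf_set` (>= 1 fiber).
#' @param scala "st" or "sv".
#' @param style "lw" (lateral wall) or "pm" (peri-modiolar); selects the
#'   initialization side inside the scala and hence the converged branch.
#' @param couple_lateral if TRUE, the paired ST/SV centerlines are fitted and
#'   the lateral (in-plane radial) offset of both is dictated by the narrower
#'   canal; the curve for `scala` is returned.
#' @param tol convergence tolerance on control-point moves, um.
#' @param max_iter maximum number of iterations.
#' @param relax under-relaxation factor of the projection step.
#' @return an object of class `centerline`: dense 3D points over the full
#'   alpha span, arc-length parameterization, scala/style tags and the fitted
#'   per-fiber minimum distances.
#' @export
fit_centerline <- function(geom, anfs, scala = c("st", "sv"),
                           style = c("lw", "pm"), couple_lateral = FALSE,
                           tol = 1, max_iter = 200L, relax = 0.5) {
  scala <- match.arg(scala)
  style <- match.arg(style)
  if (length(anfs) < 1L) stop("at least one fiber is required")
  if (couple_lateral) {
    this <- fit_centerline(geom, anfs, scala, style, FALSE, tol, max_iter, relax)
    other <- fit_centerline(geom, anfs, setdiff(c("st", "sv"), scala), style,
                            FALSE, tol, max_iter, relax)
    ## the narrower canal dictates the shared lateral coordinate
    rho_this <- canal_radius(geom, this$control_alphas, scala)
    rho_other <- canal_radius(geom, this$control_alphas, other$scala)
    narrower_u <- ifelse(rho_other < rho_this, other$control_u, this$control_u)
    lim <- pmin(rho_this, rho_other) - 40
    narrower_u <- pmin(pmax(narrower_u, -lim), lim)
    return(finalize_centerline(geom, anfs, scala, style,
                               this$control_alphas, narrower_u, this$control_v,
                               coupled = TRUE))
  }

  alpha_f <- vapply(anfs, function(f) f$alpha_deg, numeric(1L))
  ord <- order(alpha_f)
  alpha_f <- alpha_f[ord]
  fib <- lapply(anfs[ord], function(f) resample_polyline(f$polyline, 25))
  amax <- geom$alpha_range[2L]
  alphas_ctrl <- c(0, alpha_f, amax)
  if (anyDuplicated(alphas_ctrl)) {
    keep <- !duplicated(alphas_ctrl)
    alphas_ctrl <- alphas_ctrl[keep]
  }
  nc <- length(alphas_ctrl)
  interior <- seq(2L, nc - 1L)

  ## initialization: lateral-wall arrays start in the outer half of the
  ## scala, peri-modiolar arrays in the inner half; both start on the
  ## fiber-facing side (up in ST, down in SV) so the projection locks onto
  ## the lamina shelf (lw) or the descending dendrites at the modiolar wall
  ## (pm)
  rho <- canal_radius(geom, alphas_ctrl, scala)
  side <- if (scala == "st") 1 else -1
  u <- if (style == "lw") 0.22 * rho else -0.42 * rho
  v <- side * (if (style == "lw") 0.5 else 0.2) * rho

  a_dense <- seq(0, amax, by = 2)
  th_dense <- a_dense * pi / 180
  for (it in seq_len(max_iter)) {
    pts <- centerline_eval(geom, scala, alphas_ctrl, u, v, a_dense)
    du <- numeric(nc); dv <- numeric(nc)
    for (i in seq_along(fib)) {
      nd <- polyline_min_dist(pts, fib[[i]])
      j <- which.min(nd$dist)
      d <- nd$dist[j]
      p <- fib[[i]][nd$index[j], ]
      q <- pts[j, ]
      udir <- if (d > 1e-9) (q - p) / d else c(0, 0, 1)
      delta <- (ARRAY_TARGET_DIST - d) * udir
      er <- c(cos(th_dense[j]), sin(th_dense[j]), 0)
      ci <- i + 1L # control index of fiber i (after the basal end control)
      du[ci] <- sum(delta * er)
      dv[ci] <- delta[3L]
    }
    u[interior] <- u[interior] + relax * du[interior]
    v[interior] <- v[interior] + relax * dv[interior]
    ## clamp inside the scala cross-section
    nrm <- sqrt(u^2 + v^2)
    lim <- rho - 40
    scale <- ifelse(nrm > lim, lim / nrm, 1)
    u <- u * scale; v <- v * scale
    ## end controls follow their nearest interior neighbor
    u[1L] <- u[2L]; v[1L] <- v[2L]
    u[nc] <- u[nc - 1L]; v[nc] <- v[nc - 1L]
    step <- max(abs(c(relax * du[interior], relax * dv[interior])))
    if (step < tol) {
      return(finalize_centerline(geom, anfs, scala, style, alphas_ctrl, u, v,
                                 iterations = it))
    }
  }
  cl <- finalize_centerline(geom, anfs, scala, style, alphas_ctrl, u, v,
                            iterations = max_iter)
  err <- simpleError(sprintf(
    "centerline fit did not converge within %d iterations (max residual %.1f um)",
    max_iter, max(abs(cl$fiber_min_dist - ARRAY_TARGET_DIST))))
  err$residuals <- cl$fiber_min_dist - ARRAY_TARGET_DIST
  stop(err)
}

finalize_centerline <- function(geom, anfs, scala, style, alphas_ctrl, u, v,
                                iterations = NA_integer_, coupled = FALSE) {
  amax <- geom$alpha_range[2L]
  a_dense <- seq(0, amax, by = 1)
  pts <- centerline_eval(geom, scala, alphas_ctrl, u, v, a_dense)
  fib <- lapply(anfs, function(f) resample_polyline(f$polyline, 10))
  dmin <- vapply(fib, function(p) min(polyline_min_dist(pts, p)$dist), numeric(1L))
  names(dmin) <- vapply(anfs, function(f) f$id, character(1L))
  structure(list(
    scala = scala, style = style, coupled = coupled,
    alpha = a_dense, points = pts, arclength = polyline_arclength(pts),
    alpha_max = amax,
    control_alphas = alphas_ctrl, control_u = u, control_v = v,
    fiber_min_dist = dmin, iterations = iterations,
    geom_config = geom$config
  ), class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("%s%s centerline: length %.1f mm, median fiber distance %.1f um\n",
              x$style, toupper(x$scala),
              max(x$arclength) / 1000, median(x$fiber_min_dist)))
  invisible(x)
}

#' Place cylindrical contacts on the carrier
#'
#' @param centerline a fitted `centerline`.
#' @param alphas contact insertion angles, degrees (default: the fitted
#'   fibers' angles, one target contact per fiber).
#' @param orientation_mode "default" (facing the fibers: up in ST, down in
#'   SV) or "alternative" (facing the cochlear axis).
#' @param contact_radius,contact_height contact cylinder dimensions, um.
#' @return an `electrode_array`: the centerline plus a contact table with
#'   id, alpha, center (on the carrier surface), orientation unit vector and
#'   cylinder dimensions.
#' @export
place_contacts <- function(centerline, alphas = NULL,
                           orientation_mode = c("default", "alternative"),
                           contact_radius = 150, contact_height = 50) {
  orientation_mode <- match.arg(orientation_mode)
  if (is.null(alphas)) {
    stored <- names(centerline$fiber_min_dist)
    alphas <- as.numeric(sub("^ANF", "", stored))
  }
  if (length(alphas) && any(alphas < 0 | alphas > centerline$alpha_max)) {
    stop("contact alpha beyond the array tip")
  }
  contacts <- NULL
  if (length(alphas)) {
    base <- t(vapply(alphas, function(a) {
      centerline$points[which.min(abs(centerline$alpha - a)), ]
    }, numeric(3L)))
    th <- alphas * pi / 180
    dirs <- switch(orientation_mode,
      default = {
        zsign <- if (centerline$scala == "st") 1 else -1
        cbind(0, 0, rep(zsign, length(alphas)))
      },
      alternative = cbind(-cos(th), -sin(th), 0)
    )
    rad <- carrier_radius(centerline, alphas)
    centers <- base + dirs * rad
    contacts <- data.frame(
      id = sprintf("EL%d", round(alphas)),
      alpha_deg = alphas,
      x = centers[, 1L], y = centers[, 2L], z = centers[, 3L],
      ox = dirs[, 1L], oy = dirs[, 2L], oz = dirs[, 3L],
      radius = contact_radius, height = contact_height,
      stringsAsFactors = FALSE
    )
  } else {
    contacts <- data.frame(
      id = character(0), alpha_deg = numeric(0), x = numeric(0),
      y = numeric(0), z = numeric(0), ox = numeric(0), oy = numeric(0),
      oz = numeric(0), radius = numeric(0), height = numeric(0)
    )
  }
  structure(list(
    centerline = centerline,
    tag = paste0(centerline$style, toupper(centerline$scala)),
    contacts = contacts,
    orientation_mode = orientation_mode
  ), class = "electrode_array")
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("%s electrode array: %d contacts (%s orientation)\n",
              x$tag, nrow(x$contacts), x$orientation_mode))
  print(x$centerline)
  invisible(x)
}

#' Contact center coordinates
#' @param array an `electrode_array`.
#' @param contact_id contact id, e.g. "EL23".
#' @return numeric length-3 center, um.
#' @export
contact_center <- function(array, contact_id) {
  i <- match(contact_id, array$contacts$id)
  if (is.na(i)) stop(sprintf("unknown contact '%s'", contact_id))
  unlist(array$contacts[i, c("x", "y", "z")], use.names = FALSE)
}

#' Distance profile from a contact to a fiber
#'
#' Euclidean distances from the contact center to points along the fiber
#' polyline, as a function of arc position measured from the peripheral
#' terminal. Ties in the minimum break toward the terminal (smaller arc
#' position).
#'
#' @param array an `electrode_array`.
#' @param anf an `anf_path`.
#' @param contact_id contact id.
#' @param spacing arc sampling step, um.
#' @return list with `arc` (um from terminal), `dist` (um), `min_dist` and
#'   `argmin_arc`.
#' @export
min_distance_profile <- function(array, anf, contact_id, spacing = 5) {
  ctr <- contact_center(array, contact_id)
  pts <- resample_polyline(anf$polyline, spacing)
  arc <- polyline_arclength(pts)
  d <- sqrt((pts[, 1L] - ctr[1L])^2 + (pts[, 2L] - ctr[2L])^2 +
              (pts[, 3L] - ctr[3L])^2)
  j <- which(d <= min(d) + 1e-9)[1L] # tie-break toward the terminal
  list(arc = arc, dist = d, min_dist = d[j], argmin_arc = arc[j])
}

#' Build all four electrode arrays
#'
#' Convenience wrapper fitting pmST, pmSV, lwST and lwSV with one contact per
#' fiber angle.
#'
#' @param geom a `cochlear_geometry`.
#' @param anfs an `anf_set`.
#' @param orientation_mode contact orientation, see [place_contacts()].
#' @param couple_lateral couple the lateral coordinates of the ST/SV pair of
#'   each style (the construction used for array comparisons).
#' @return named list of `electrode_array` (pmST, pmSV, lwST, lwSV).
#' @export
build_arrays <- function(geom, anfs, orientation_mode = "default",
                         couple_lateral = TRUE) {
  combos <- list(pmST = c("pm", "st"), pmSV = c("pm", "sv"),
                 lwST = c("lw", "st"), lwSV = c("lw", "sv"))
  out <- lapply(combos, function(cs) {
    cl <- fit_centerline(geom, anfs, scala = cs[2L], style = cs[1L],
                         couple_lateral = couple_lateral)
    place_contacts(cl, orientation_mode = orientation_mode)
  })
  out
}
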