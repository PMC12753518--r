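# JSON serialization of geometry, fibers and arrays, and the binary
# array-container + JSON sidecar used for field solutions at run time.
# Schema: 3D points are [x, y, z] arrays in micrometers.

#' Write the geometry configuration as JSON
#' @param geom a `cochlear_geometry`.
#' @param path output file.
#' @export
write_geometry_json <- function(geom, path) {
  jsonlite::write_json(list(
    type = "cochlear_geometry",
    config = geom$config[order(names(geom$config))],
    alpha_range_deg = geom$alpha_range,
    axis = list(origin = geom$axis_origin, direction = geom$axis_dir),
    units = "um"
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a geometry JSON written by [write_geometry_json()]
#' @param path input file.
#' @return a `cochlear_geometry`.
#' @export
read_geometry_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(geometry_config, j$config[names(j$config) %in%
                                             names(formals(geometry_config))])
  build_geometry(cfg)
}

#' Write a fiber set as JSON
#' @param anfs an `anf_set`.
#' @param path output file.
#' @export
write_anfs_json <- function(anfs, path) {
  jsonlite::write_json(list(
    type = "anf_set", units = "um",
    fibers = lapply(anfs, function(f) list(
      id = f$id, alpha_deg = f$alpha_deg,
      dendrite_length_um = f$dendrite_length,
      soma_arc_pos_um = f$soma_arc_pos,
      polyline = unname(apply(f$polyline, 1L, function(p) p, simplify = FALSE))
    ))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fiber set JSON written by [write_anfs_json()]
#' @param path input file.
#' @return an `anf_set`.
#' @export
read_anfs_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(j$fibers, function(f) {
    structure(list(
      id = f$id, alpha_deg = f$alpha_deg,
      polyline = do.call(rbind, lapply(f$polyline, unlist)),
      dendrite_length = f$dendrite_length_um,
      soma_arc_pos = f$soma_arc_pos_um
    ), class = "anf_path")
  })
  structure(out, class = "anf_set")
}

#' Write electrode arrays as JSON
#' @param arrays named list of `electrode_array`.
#' @param path output file.
#' @export
write_arrays_json <- function(arrays, path) {
  jsonlite::write_json(list(
    type = "electrode_arrays", units = "um",
    arrays = lapply(unname(arrays), function(a) list(
      tag = a$tag, scala = a$centerline$scala, style = a$centerline$style,
      orientation_mode = a$orientation_mode,
      coupled = a$centerline$coupled,
      control_alphas_deg = a$centerline$control_alphas,
      control_radial_um = a$centerline$control_u,
      control_height_um = a$centerline$control_v,
      length_um = max(a$centerline$arclength),
      contacts = a$contacts
    ))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save a field solution as a binary array container with a JSON sidecar
#'
#' @param field a `field_solution`.
#' @param path output `.rds` path; the sidecar is written as `<path>.json`.
#' @export
write_field <- function(field, path) {
  saveRDS(field, path)
  jsonlite::write_json(list(
    type = "field_solution", contact = field$contact,
    current_uA = field$current_uA, dim = field$dim,
    spacing_um = field$spacing,
    origin_um = c(field$xs[1L], field$ys[1L], field$zs[1L]),
    solver = field$meta, units = list(potential = "mV/uA", space = "um")
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a field solution saved by [write_field()]
#' @param path `.rds` path.
#' @return a `field_solution`.
#' @export
read_field <- function(path) readRDS(path)
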