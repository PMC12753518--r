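# End-to-end orchestration: geometry -> fibers -> arrays -> conductivity
# maps -> unit-current fields -> thresholds -> population analyses, with
# content-hash caching of the expensive stages, structured logging, and
# CSV/JSON outputs.

#' Default run configuration
#'
#' The shipped defaults are a desk-scale profile: 360 um field resolution
#' for the per-contact solves, 480 um for the conductivity sweeps, five
#' sweep fibers spread over the basal-apical range, and specificity
#' matrices for two arrays. See the methods vignette for the reasoning.
#'
#' @param seed integer seed recorded and applied at run start.
#' @param out_dir output directory.
#' @param spacing voxel spacing of the main field solves, um.
#' @param sweep_spacing voxel spacing of the conductivity sweeps; NULL (the
#'   default) reuses the main maps and fields.
#' @param n_anf number of fibers.
#' @param arrays array tags to build.
#' @param orientation contact orientation mode.
#' @param experiments subset of "thresholds", "degeneration", "specificity",
#'   "robustness", "sweeps".
#' @param specificity_arrays arrays for which the full fiber x contact
#'   threshold matrix is computed.
#' @param n_sweep_fibers fibers (evenly spread) used in conductivity sweeps.
#' @param pulse_duration_us stimulation pulse duration.
#' @param geometry a `cochlea_config`.
#' @param membrane a `membrane_spec`.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("cochstim-run-"),
                       spacing = 300, sweep_spacing = 420, n_anf = 25L,
                       arrays = c("pmST", "pmSV", "lwST", "lwSV"),
                       orientation = "default",
                       experiments = c("thresholds", "degeneration",
                                       "specificity", "robustness", "sweeps"),
                       specificity_arrays = c("pmST", "lwSV"),
                       n_sweep_fibers = 5L,
                       pulse_duration_us = 50,
                       geometry = geometry_config(),
                       membrane = membrane_spec()) {
  cfg <- as.list(environment())
  bad <- setdiff(cfg$arrays, c("pmST", "pmSV", "lwST", "lwSV"))
  if (length(bad)) stop("unknown array tag(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(cfg$experiments,
                 c("thresholds", "degeneration", "specificity", "robustness",
                   "sweeps"))
  if (length(bad)) stop("unknown experiment(s): ", paste(bad, collapse = ", "))
  if (!all(cfg$specificity_arrays %in% cfg$arrays)) {
    stop("specificity_arrays must be a subset of arrays")
  }
  if (cfg$spacing <= 0 || (!is.null(cfg$sweep_spacing) && cfg$sweep_spacing <= 0)) {
    stop("spacings must be positive")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML or JSON file
#'
#' Scalar fields override the [run_config()] defaults; `geometry` and
#' `membrane` sub-maps override individual parameters of
#' [geometry_config()] and [membrane_spec()].
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  geo <- do.call(geometry_config, as.list(raw$geometry %||% list()))
  mem <- do.call(membrane_spec, as.list(raw$membrane %||% list()))
  raw$geometry <- NULL; raw$membrane <- NULL
  args <- raw[names(raw) %in% names(formals(run_config))]
  do.call(run_config, c(args, list(geometry = geo, membrane = mem)))
}

log_stage <- function(run_log, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%OS1"), msg)
  message(line)
  if (!is.null(run_log)) cat(line, "\n", file = run_log, append = TRUE)
  invisible(NULL)
}

content_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 3L, compress = FALSE)
  unname(tools::md5sum(f))
}

cache_fetch <- function(cache_dir, key, producer, run_log, what) {
  path <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(path)) {
    obj <- tryCatch(readRDS(path), error = function(e) {
      stop(sprintf("corrupted intermediate file '%s' (stage %s): %s",
                   path, what, conditionMessage(e)))
    })
    log_stage(run_log, sprintf("%s: cached (%s)", what, basename(path)))
    return(obj)
  }
  t0 <- Sys.time()
  obj <- producer()
  saveRDS(obj, path)
  log_stage(run_log, sprintf("%s: computed in %.1f s", what,
                             as.numeric(Sys.time() - t0, units = "secs")))
  obj
}

stage_error <- function(stage, e) {
  stop(sprintf("pipeline aborted at stage '%s': %s", stage,
               conditionMessage(e)), call. = FALSE)
}

#' Run the full simulation pipeline
#'
#' Executes geometry, fiber and array construction, voxelization, per
#' contact unit-current field solves, target-pair threshold searches for the
#' three neural conditions, robustness variants, fiber x contact specificity
#' matrices, and conductivity/ossification sweeps, writing CSV/JSON outputs
#' and the resolved configuration into the run directory. Expensive stages
#' are cached by content hash, so re-running an unchanged configuration
#' skips them.
#'
#' @param config a `run_config`.
#' @return the run directory path, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  run_log <- file.path(out_dir, "run.log")
  cfg_export <- config
  cfg_export$geometry <- unclass(cfg_export$geometry)
  cfg_export$membrane <- unclass(cfg_export$membrane)
  jsonlite::write_json(cfg_export, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  ## ---- geometry, fibers, arrays -------------------------------------------
  base_key <- content_hash(list("base", config$geometry, config$n_anf,
                                config$orientation, config$arrays))
  base <- tryCatch(cache_fetch(cache_dir, base_key, function() {
    geom <- build_geometry(config$geometry)
    anfs <- place_anfs(geom, config$n_anf, seed = config$seed)
    arrays <- build_arrays(geom, anfs, orientation_mode = config$orientation)
    arrays <- arrays[config$arrays]
    list(geom = geom, anfs = anfs, arrays = arrays)
  }, run_log, "geometry/arrays"), error = function(e) stage_error("geometry", e))
  geom <- base$geom; anfs <- base$anfs; arrays <- base$arrays
  write_geometry_json(geom, file.path(out_dir, "geometry.json"))
  write_anfs_json(anfs, file.path(out_dir, "anfs.json"))
  write_arrays_json(arrays, file.path(out_dir, "arrays.json"))

  ## chains for the three conditions
  conditions <- c("healthy", "thin_dendrite", "no_dendrite")
  chains <- lapply(conditions, function(cond) {
    lapply(anfs, assemble_chain, spec = config$membrane, condition = cond)
  })
  names(chains) <- conditions
  pulse <- pulse_spec("cathodic", duration_us = config$pulse_duration_us)

  summary <- list(config_seed = config$seed, arrays = list())

  for (tag in names(arrays)) {
    arr <- arrays[[tag]]
    ## ---- conductivity map and per-contact fields -------------------------
    map_key <- content_hash(list("map", config$geometry, config$n_anf, tag,
                                 config$orientation, config$spacing))
    map <- tryCatch(cache_fetch(cache_dir, map_key, function() {
      voxelize(geom, list(arr), spacing = config$spacing)
    }, run_log, paste0("voxelize ", tag)), error = function(e)
      stage_error(paste0("voxelize ", tag), e))

    fields_key <- content_hash(list("fields", map_key))
    fields <- tryCatch(cache_fetch(cache_dir, fields_key, function() {
      out <- list()
      for (cid in arr$contacts$id) out[[cid]] <- solve_field(map, cid)
      out
    }, run_log, paste0("fields ", tag)), error = function(e)
      stage_error(paste0("fields ", tag), e))

    arr_summary <- list()

    ## ---- target-pair thresholds per condition ----------------------------
    if (any(c("thresholds", "degeneration") %in% config$experiments)) {
      reports <- list()
      conds <- if ("degeneration" %in% config$experiments) conditions else "healthy"
      for (cond in conds) {
        reports[[cond]] <- tryCatch(
          run_condition(anfs, map, cond, pulse, config$membrane,
                        baseline = reports[["healthy"]], fields = fields),
          error = function(e) stage_error(paste0("thresholds ", tag, " ", cond), e))
        utils::write.csv(reports[[cond]]$results,
                         file.path(out_dir, sprintf("thresholds_%s_%s.csv", tag, cond)),
                         row.names = FALSE)
        arr_summary[[cond]] <- list(
          median_threshold_uA = median(reports[[cond]]$results$threshold_uA,
                                       na.rm = TRUE),
          median_pct_increase = median(reports[[cond]]$results$pct_increase,
                                       na.rm = TRUE))
      }
      ## distance correlation (healthy)
      dmin <- vapply(seq_along(anfs), function(i) {
        min_distance_profile(arr, anfs[[i]], sprintf("EL%d", round(anfs[[i]]$alpha_deg)),
                             spacing = 25)$min_dist
      }, numeric(1L))
      arr_summary$healthy$threshold_distance_r <- threshold_distance_correlation(
        reports$healthy$results$threshold_uA, dmin)

      ## ---- robustness variants -------------------------------------------
      if ("robustness" %in% config$experiments) {
        rob <- tryCatch(
          robustness_variants(geom, anfs, map, reports$healthy, pulse,
                              config$membrane, fields = fields),
          error = function(e) stage_error(paste0("robustness ", tag), e))
        rob_df <- do.call(rbind, lapply(rob, function(r) {
          data.frame(variant = r$label, fiber = r$fiber,
                     default_uA = r$default_uA, new_uA = r$new_uA,
                     pct_change = r$pct_change, stringsAsFactors = FALSE)
        }))
        utils::write.csv(rob_df,
                         file.path(out_dir, sprintf("robustness_%s.csv", tag)),
                         row.names = FALSE)
        arr_summary$robustness <- lapply(rob, function(r) r$mean_abs_pct_change)
      }
    }

    ## ---- specificity / selectivity matrix --------------------------------
    if ("specificity" %in% config$experiments && tag %in% config$specificity_arrays) {
      tm <- tryCatch(
        threshold_matrix(chains$healthy, fields, pulse),
        error = function(e) stage_error(paste0("matrix ", tag), e))
      utils::write.csv(tm$thresholds,
                       file.path(out_dir, sprintf("threshold_matrix_%s.csv", tag)))
      spec_map <- specificity_map(tm)
      sel_map <- selectivity_map(tm)
      utils::write.csv(spec_map$increase_pct,
                       file.path(out_dir, sprintf("specificity_%s.csv", tag)))
      arr_summary$specificity_median_pct <- spec_map$median_increase_pct
      arr_summary$selectivity_median_pct <- sel_map$median_increase_pct
    }

    ## ---- conductivity and ossification sweeps ----------------------------
    if ("sweeps" %in% config$experiments) {
      idx <- unique(round(seq(1, length(anfs), length.out = config$n_sweep_fibers)))
      sw_chains <- chains$healthy[idx]
      sweep_key <- content_hash(list("sweeps", config$geometry, config$n_anf,
                                     tag, config$orientation, config$spacing,
                                     config$sweep_spacing, idx))
      sweeps <- tryCatch(cache_fetch(cache_dir, sweep_key, function() {
        if (is.null(config$sweep_spacing) ||
            config$sweep_spacing == config$spacing) {
          smap <- map
          baseline <- target_thresholds(smap, sw_chains, pulse, fields = fields)
        } else {
          smap <- voxelize(geom, list(arr), spacing = config$sweep_spacing)
          baseline <- target_thresholds(smap, sw_chains, pulse)
        }
        cs <- conductivity_sensitivity(
          smap, sw_chains, pulse,
          factors = list(modiolus10 = c(10, 1), bone2 = c(1, 2)),
          baseline = baseline)
        os <- ossification_sweep(smap, sw_chains, baseline = baseline,
                                 pulse = pulse)
        ## carrier potential profile at the contact nearest 320 degrees,
        ## default vs tenfold modiolus conductivity
        cid <- arr$contacts$id[which.min(abs(arr$contacts$alpha_deg - 320))]
        f320 <- if (identical(smap$spacing, map$spacing)) fields[[cid]] else
          solve_field(smap, cid)
        prof_def <- potential_along_carrier(f320, arr$centerline,
                                            active_alpha = 320)
        m10 <- conductivity_variant(smap, modiolus_factor = 10)
        prof_m10 <- potential_along_carrier(solve_field(m10, cid,
                                                        warm_start = f320),
                                            arr$centerline, active_alpha = 320)
        list(conductivity = cs, ossification = os,
             carrier = list(default = prof_def, modiolus10 = prof_m10))
      }, run_log, paste0("sweeps ", tag)), error = function(e)
        stage_error(paste0("sweeps ", tag), e))
      sw_df <- do.call(rbind, lapply(c(sweeps$conductivity, sweeps$ossification),
                                     function(r) {
        data.frame(label = r$label, fiber = r$fiber, default_uA = r$default_uA,
                   new_uA = r$new_uA, pct_change = r$pct_change,
                   stringsAsFactors = FALSE)
      }))
      utils::write.csv(sw_df, file.path(out_dir, sprintf("sweeps_%s.csv", tag)),
                       row.names = FALSE)
      carr <- sweeps$carrier
      utils::write.csv(data.frame(alpha_deg = carr$default$alpha,
                                  profile_default = carr$default$profile,
                                  profile_modiolus10 = carr$modiolus10$profile),
                       file.path(out_dir, sprintf("carrier_profile_%s.csv", tag)),
                       row.names = FALSE)
      arr_summary$sweeps <- lapply(c(sweeps$conductivity, sweeps$ossification),
                                   function(r) list(
                                     median_pct_change = r$median_pct_change,
                                     slope = r$slope))
    }

    summary$arrays[[tag]] <- arr_summary
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  log_stage(run_log, "pipeline complete")
  invisible(out_dir)
}

#' Summarize a completed run directory
#'
#' Recomputes the per-array, per-condition medians from the CSV outputs and
#' returns them as one machine-readable list (also compared against
#' `summary.json` by the test suite).
#'
#' @param out_dir a completed run directory.
#' @return nested list of medians.
#' @export
summarize_run <- function(out_dir) {
  if (!file.exists(file.path(out_dir, "config.json"))) {
    stop(sprintf("'%s' is not a completed run directory (config.json missing)",
                 out_dir))
  }
  files <- list.files(out_dir, pattern = "^thresholds_.*\\.csv$")
  if (!length(files)) stop("incomplete run: no threshold outputs found")
  out <- list()
  for (f in files) {
    parts <- strsplit(sub("^thresholds_(.*)\\.csv$", "\\1", f), "_")[[1L]]
    tag <- parts[1L]
    cond <- paste(parts[-1L], collapse = "_")
    df <- utils::read.csv(file.path(out_dir, f))
    out[[tag]][[cond]] <- list(
      median_threshold_uA = median(df$threshold_uA, na.rm = TRUE),
      median_pct_increase = median(df$pct_increase, na.rm = TRUE),
      n = nrow(df))
  }
  out
}
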