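# Neural-degeneration experiments (healthy / thin dendrite / no dendrite)
# and the geometric robustness variants (halved peripheral internode target,
# dendritic length fixed at the 1.7 mm median).

#' Thresholds, SIS and percentage increases for one neural condition
#'
#' Runs the target (same-angle) fiber-contact pairs of one array under the
#' given neural condition and references the percentage increase to the
#' healthy baseline of the same fiber, array and polarity.
#'
#' @param anfs an `anf_set`.
#' @param map `conductivity_map` of the array.
#' @param condition "healthy", "thin_dendrite" or "no_dendrite".
#' @param pulse a `pulse_spec` template.
#' @param spec a `membrane_spec`.
#' @param baseline healthy-condition report (required when `condition` is
#'   not "healthy").
#' @param fields optional precomputed named list of `field_solution` per
#'   contact (avoids re-solving).
#' @param ... passed to [threshold_search()].
#' @return object of class `condition_report`: data.frame with fiber,
#'   threshold, SIS kind/arc and `pct_increase` vs healthy.
#' @export
run_condition <- function(anfs, map, condition = "healthy",
                          pulse = pulse_spec("cathodic"),
                          spec = membrane_spec(), baseline = NULL,
                          fields = NULL, ...) {
  if (condition != "healthy" && is.null(baseline)) {
    stop("missing healthy baseline for percentage computation")
  }
  rows <- lapply(anfs, function(anf) {
    ch <- assemble_chain(anf, spec, condition)
    cid <- sprintf("EL%d", round(anf$alpha_deg))
    f <- if (!is.null(fields)) fields[[cid]] else solve_field(map, cid)
    if (is.null(f)) stop(sprintf("no field for contact %s", cid))
    res <- threshold_search(ch, chain_potentials(f, ch), pulse, ...)
    data.frame(fiber = anf$id, alpha_deg = anf$alpha_deg,
               threshold_uA = res$threshold_uA,
               sis_kind = res$sis_kind %||% NA_character_,
               sis_arc_um = res$sis_arc_um,
               latency_ms = res$latency_ms,
               converged = res$converged,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$condition <- condition
  if (!is.null(baseline)) {
    base <- baseline$results
    i <- match(df$fiber, base$fiber)
    df$pct_increase <- 100 * (df$threshold_uA - base$threshold_uA[i]) /
      base$threshold_uA[i]
  } else {
    df$pct_increase <- 0
  }
  structure(list(results = df, condition = condition,
                 polarity = pulse$polarity),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf(
    "Condition '%s' (%s): median threshold %.1f uA, median increase %+.0f%%\n",
    x$condition, x$polarity, median(x$results$threshold_uA, na.rm = TRUE),
    median(x$results$pct_increase, na.rm = TRUE)))
  invisible(x)
}

#' Robustness variants of the healthy model
#'
#' Reruns the healthy cathodic target-pair thresholds with (a) the
#' peripheral internode target length halved to 125 um and (b) every
#' dendritic length fixed at the 1,700 um median (fibers rebuilt with the
#' peripheral course rescaled between the unchanged terminal and soma
#' anchors), and reports per-fiber and mean absolute percentage changes.
#'
#' @param geom the `cochlear_geometry` (needed to rebuild fixed-length
#'   fibers).
#' @param anfs an `anf_set`.
#' @param map `conductivity_map` of the array.
#' @param baseline healthy-condition `condition_report`.
#' @param pulse a `pulse_spec` template.
#' @param spec a `membrane_spec`.
#' @param fields optional precomputed fields per contact.
#' @param ... passed to [threshold_search()].
#' @return named list of `sweep_result` for variants `half_internode` and
#'   `fixed_dendrite_1700`.
#' @export
robustness_variants <- function(geom, anfs, map, baseline,
                                pulse = pulse_spec("cathodic"),
                                spec = membrane_spec(), fields = NULL, ...) {
  base_df <- baseline$results
  base <- data.frame(fiber = base_df$fiber,
                     threshold_uA = base_df$threshold_uA,
                     sis_kind = base_df$sis_kind, stringsAsFactors = FALSE)

  run_variant <- function(chains) {
    rows <- lapply(chains, function(ch) {
      cid <- sprintf("EL%d", round(ch$alpha_deg))
      f <- if (!is.null(fields)) fields[[cid]] else solve_field(map, cid)
      res <- threshold_search(ch, chain_potentials(f, ch), pulse, ...)
      data.frame(fiber = ch$id, threshold_uA = res$threshold_uA,
                 sis_kind = res$sis_kind %||% NA_character_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  half <- run_variant(lapply(anfs, function(a) {
    assemble_chain(a, spec, "healthy", internode_target = 125,
                   n_range = c(4L, 20L))
  }))
  fixed_anfs <- fixed_dendrite_anfs(geom, anfs, 1700)
  fixed <- run_variant(lapply(fixed_anfs, function(a) {
    assemble_chain(a, spec, "healthy")
  }))

  out <- list(
    half_internode = sweep_result("half_internode", base, half),
    fixed_dendrite_1700 = sweep_result("fixed_dendrite_1700", base, fixed)
  )
  for (nm in names(out)) {
    out[[nm]]$mean_abs_pct_change <- mean(abs(out[[nm]]$pct_change), na.rm = TRUE)
  }
  out
}

#' Rebuild fibers with a fixed dendritic length
#'
#' The peripheral course is regenerated between the unchanged terminal and
#' soma anchors with its arc length set to `length_um`.
#'
#' @param geom a `cochlear_geometry`.
#' @param anfs an `anf_set`.
#' @param length_um fixed dendritic arc length, um.
#' @return an `anf_set` with all dendritic lengths equal to `length_um`.
#' @export
fixed_dendrite_anfs <- function(geom, anfs, length_um = 1700) {
  out <- lapply(anfs, function(f) {
    a <- f$alpha_deg
    dcur <- dendrite_curve(geom, a, length_um)
    th <- a * pi / 180
    d3 <- cbind(dcur[, 1L] * cos(th), dcur[, 1L] * sin(th), dcur[, 2L])
    soma_frame <- fiber_anchors(geom, a)$soma
    a3 <- axon_curve(geom, a, soma_frame, geom$config$axon_length)
    f$polyline <- rbind(d3, a3[-1L, , drop = FALSE])
    f$dendrite_length <- length_um
    f$soma_arc_pos <- length_um + 10
    f
  })
  structure(out, class = "anf_set")
}
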