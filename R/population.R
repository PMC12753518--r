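# Population-level analyses: specificity / selectivity maps from the
# fiber x contact threshold matrix, conductivity-sensitivity sweeps
# (modiolus x10, bone x2, both), and progressive scala tympani ossification.

as_threshold_values <- function(matrix) {
  if (inherits(matrix, "threshold_matrix")) matrix$thresholds else as.matrix(matrix)
}

#' Specificity map: percentage increase over the contact-wise minimum
#'
#' For each contact (column) c: inc(f, c) = 100 (T(f, c) / min_f T(f, c) - 1).
#' The summary median is computed over all unmasked entries excluding the
#' per-contact minima themselves (the structural zeros); set
#' `include_argmin = TRUE` to keep them.
#'
#' @param matrix a `threshold_matrix` or numeric matrix (fibers x contacts).
#' @param include_argmin include the 0% argmin entries in the summary median.
#' @return object of class `specificity_map`: `increase_pct` matrix, per
#'   contact `argmin_fiber` / `argmax_fiber`, and `median_increase_pct`.
#' @export
specificity_map <- function(matrix, include_argmin = FALSE) {
  th <- as_threshold_values(matrix)
  if (any(colSums(!is.na(th)) == 0)) {
    stop("fully masked contact column: no threshold available")
  }
  mins <- apply(th, 2L, min, na.rm = TRUE)
  inc <- 100 * (sweep(th, 2L, mins, "/") - 1)
  argmin <- apply(th, 2L, function(col) which.min(col))
  argmax <- apply(th, 2L, function(col) which.max(col))
  sel <- !is.na(inc)
  if (!include_argmin) sel[cbind(argmin, seq_along(argmin))] <- FALSE
  structure(list(
    increase_pct = inc,
    argmin_fiber = rownames(th)[argmin] %||% argmin,
    argmax_fiber = rownames(th)[argmax] %||% argmax,
    median_increase_pct = median(inc[sel]),
    include_argmin = include_argmin
  ), class = "specificity_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.specificity_map <- function(x, ...) {
  cat(sprintf("Specificity map %d x %d: median increase %.0f%%\n",
              nrow(x$increase_pct), ncol(x$increase_pct),
              x$median_increase_pct))
  invisible(x)
}

#' Selectivity map: percentage increase over the fiber-wise minimum
#'
#' The row-normalized analogue of [specificity_map()] (thresholds normalized
#' for each fiber across all contacts).
#'
#' @inheritParams specificity_map
#' @return a `specificity_map` object computed on the transposed matrix
#'   (columns are fibers).
#' @export
selectivity_map <- function(matrix, include_argmin = FALSE) {
  th <- as_threshold_values(matrix)
  out <- specificity_map(t(th), include_argmin = include_argmin)
  class(out) <- c("selectivity_map", class(out))
  out
}

#' Thresholds of chains at their target (same-angle) contacts
#'
#' @param map a `conductivity_map` containing the contacts.
#' @param chains list of `compartment_chain`.
#' @param pulse a `pulse_spec` template.
#' @param fields optional named list of precomputed `field_solution` per
#'   contact id (skips solving).
#' @param warm_fields optional named list of `field_solution` on the same
#'   grid used as PCG initial guesses.
#' @param ... passed to [threshold_search()].
#' @return data.frame with fiber, threshold, SIS and latency; the solved
#'   fields are attached as attribute "fields" for chaining.
#' @export
target_thresholds <- function(map, chains, pulse = pulse_spec("cathodic"),
                              fields = NULL, warm_fields = NULL, ...) {
  solved <- list()
  res <- lapply(chains, function(ch) {
    cid <- sprintf("EL%d", round(ch$alpha_deg))
    if (is.null(map$contact_voxels[[cid]])) {
      stop(sprintf("map has no contact %s for fiber %s", cid, ch$id))
    }
    f <- fields[[cid]]
    if (is.null(f)) f <- solved[[cid]]
    if (is.null(f)) {
      f <- solve_field(map, cid, warm_start = warm_fields[[cid]])
      solved[[cid]] <<- f
    }
    threshold_search(ch, chain_potentials(f, ch), pulse, ...)
  })
  out <- data.frame(
    fiber = vapply(res, `[[`, character(1L), "fiber"),
    threshold_uA = vapply(res, `[[`, numeric(1L), "threshold_uA"),
    sis_kind = vapply(res, function(r) r$sis_kind %||% NA_character_, character(1L)),
    latency_ms = vapply(res, `[[`, numeric(1L), "latency_ms"),
    stringsAsFactors = FALSE
  )
  attr(out, "fields") <- if (length(solved)) solved else fields
  out
}

sweep_result <- function(label, base, new) {
  stopifnot(identical(base$fiber, new$fiber))
  pct <- 100 * (new$threshold_uA - base$threshold_uA) / base$threshold_uA
  ok <- !is.na(pct)
  fit <- if (sum(ok) >= 2L) lm(new$threshold_uA[ok] ~ base$threshold_uA[ok]) else NULL
  structure(list(
    label = label,
    fiber = base$fiber,
    default_uA = base$threshold_uA,
    new_uA = new$threshold_uA,
    pct_change = pct,
    sis_default = base$sis_kind,
    sis_new = new$sis_kind,
    median_pct_change = median(pct, na.rm = TRUE),
    slope = if (is.null(fit)) NA_real_ else unname(coef(fit)[2L]),
    intercept = if (is.null(fit)) NA_real_ else unname(coef(fit)[1L])
  ), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep '%s': median threshold change %+.1f%%, slope %.2f (n = %d)\n",
              x$label, x$median_pct_change, x$slope, length(x$fiber)))
  invisible(x)
}

#' Conductivity sensitivity: modiolus x10, bone x2, and both
#'
#' Re-solves the fields on modified maps and recomputes the target-contact
#' thresholds of the supplied chains.
#'
#' @param base_map a `conductivity_map` containing the array contacts.
#' @param chains list of `compartment_chain` (the fibers to test).
#' @param pulse a `pulse_spec` template.
#' @param factors named list of c(modiolus_factor, bone_factor) pairs.
#' @param baseline optional precomputed default thresholds (from
#'   [target_thresholds()] on `base_map`); its attached fields warm-start
#'   the modified-map solves.
#' @param ... passed to [threshold_search()].
#' @return named list of `sweep_result`.
#' @export
conductivity_sensitivity <- function(base_map, chains,
                                     pulse = pulse_spec("cathodic"),
                                     factors = list(modiolus10 = c(10, 1),
                                                    bone2 = c(1, 2),
                                                    both = c(10, 2)),
                                     baseline = NULL, ...) {
  if (any(vapply(factors, function(f) any(f <= 0), logical(1L)))) {
    stop("conductivity factors must be positive")
  }
  if (is.null(baseline)) baseline <- target_thresholds(base_map, chains, pulse, ...)
  base_fields <- attr(baseline, "fields")
  out <- lapply(names(factors), function(nm) {
    f <- factors[[nm]]
    mod_map <- conductivity_variant(base_map, modiolus_factor = f[1L],
                                    bone_factor = f[2L])
    sweep_result(nm, baseline,
                 target_thresholds(mod_map, chains, pulse,
                                   warm_fields = base_fields, ...))
  })
  names(out) <- names(factors)
  out
}

#' Scala tympani ossification sweep
#'
#' @param base_map a `conductivity_map` with the patent (1.43 S/m) ST.
#' @param chains list of `compartment_chain`.
#' @param st_sigmas decreasing ST conductivities, S/m.
#' @param pulse a `pulse_spec` template.
#' @param baseline optional precomputed default thresholds.
#' @param ... passed to [threshold_search()].
#' @return named list of `sweep_result`, one per conductivity.
#' @export
ossification_sweep <- function(base_map, chains,
                               st_sigmas = unname(ossification_levels()),
                               pulse = pulse_spec("cathodic"),
                               baseline = NULL, ...) {
  if (any(st_sigmas <= 0)) stop("ST conductivities must be positive")
  if (is.null(baseline)) baseline <- target_thresholds(base_map, chains, pulse, ...)
  warm <- attr(baseline, "fields")
  out <- list()
  for (s in st_sigmas) {
    new_map <- apply_ossification(base_map, s)
    new <- target_thresholds(new_map, chains, pulse, warm_fields = warm, ...)
    warm <- attr(new, "fields") # chain along the conductivity ladder
    out[[sprintf("st_%g", s)]] <- sweep_result(sprintf("st_%g", s), baseline, new)
  }
  out
}

#' Correlation of threshold with minimum contact-fiber distance
#'
#' @param thresholds numeric vector of target-contact thresholds, uA.
#' @param distances matching minimum contact-fiber distances, um.
#' @return Pearson correlation coefficient.
#' @export
threshold_distance_correlation <- function(thresholds, distances) {
  ok <- !is.na(thresholds) & !is.na(distances)
  cor(thresholds[ok], distances[ok])
}
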