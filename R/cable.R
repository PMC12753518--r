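# Multi-compartment model of the human type I spiral ganglion cell: a
# peripheral process (10 um unmyelinated terminal, myelinated internodes and
# 2.5 um nodes of Ranvier, 100 um pre-somatic segment), a 20 um spherical
# soma wrapped in three membrane layers, a 5 um post-somatic segment, and a
# central axon of 500 um internodes. Active compartments carry
# temperature-accelerated Hodgkin-Huxley kinetics with a tenfold channel
# density; internodes are passive with sheet-scaled capacitance and
# conductance (40 sheets dendritic, 80 axonal).

#' Membrane and kinetics parameters
#'
#' @param rho_i intracellular resistivity, kOhm cm.
#' @param c_sheet specific membrane capacitance per sheet, uF/cm^2.
#' @param g_sheet specific passive membrane conductance per sheet, mS/cm^2.
#' @param sheets_dendrite,sheets_axon myelin sheet counts of the peripheral
#'   and central internodes.
#' @param soma_layers membrane layers around the soma (capacitance and
#'   conductances divided by this count).
#' @param active_boost channel-density multiplier at nodes, terminal and
#'   pre/post-somatic compartments.
#' @param g_na,g_k,g_l maximal HH conductances, mS/cm^2.
#' @param e_na,e_k,e_l HH reversal potentials in the reduced-voltage
#'   convention (rest = 0), mV.
#' @param k_temp temperature acceleration factor applied to all HH rate
#'   constants; the default 12 yields sub-millisecond action potentials.
#' @param d_dendrite,d_axon,d_soma compartment diameters, um.
#' @param d_thin dendritic diameter of the severely degenerated condition, um.
#' @param n_central_internodes number of central internodes to lay out.
#' @return list of class `membrane_spec`.
#' @export
membrane_spec <- function(rho_i = 0.1, c_sheet = 1, g_sheet = 0.1,
                          sheets_dendrite = 40, sheets_axon = 80,
                          soma_layers = 3, active_boost = 10,
                          g_na = 120, g_k = 36, g_l = 0.3,
                          e_na = 115, e_k = -12, e_l = 10.6,
                          k_temp = 12,
                          d_dendrite = 1.3, d_axon = 2.6, d_soma = 20,
                          d_thin = 0.5, n_central_internodes = 10L) {
  spec <- as.list(environment())
  stopifnot(all(vapply(spec, is.numeric, logical(1L))))
  if (any(unlist(spec[c("c_sheet", "g_sheet", "g_na", "g_k", "g_l",
                        "soma_layers", "active_boost")]) <= 0)) {
    stop("conductances, capacitances and multipliers must be positive")
  }
  class(spec) <- "membrane_spec"
  spec
}

#' Peripheral internode layout from the dendritic length
#'
#' The available span is the dendritic length minus the 10 um terminal and
#' the 100 um pre-somatic segment; it is divided into n internodes separated
#' by n-1 nodes of Ranvier (2.5 um each), choosing n so the effective
#' internode length is closest to the 250 um target (half the central 500 um
#' internode).
#'
#' @param dendrite_length um, must exceed 112.5.
#' @param target target internode length, um.
#' @param n_range allowed internode counts.
#' @return list with `n_internodes` and `effective_length` (um).
#' @export
peripheral_layout <- function(dendrite_length, target = 250,
                              n_range = c(4L, 10L)) {
  if (dendrite_length <= 112.5) {
    stop("dendritic length must exceed 112.5 um (terminal + pre-somatic + node)")
  }
  span <- dendrite_length - 10 - 100
  ns <- seq(n_range[1L], n_range[2L])
  eff <- (span - 2.5 * (ns - 1)) / ns
  ok <- eff > 0
  if (!any(ok)) stop("no feasible internode count for this dendritic length")
  ns <- ns[ok]; eff <- eff[ok]
  i <- which.min(abs(eff - target))
  list(n_internodes = ns[i], effective_length = eff[i])
}

#' Assemble the compartment chain of a fiber
#'
#' Compartments are laid out along the fiber polyline by arc length, so the
#' curvature of internodes enters through the 3D compartment centers used
#' for extracellular sampling.
#'
#' @param anf an `anf_path`.
#' @param spec a `membrane_spec`.
#' @param condition "healthy", "thin_dendrite" (all peripheral diameters
#'   0.5 um) or "no_dendrite" (chain starts at the soma).
#' @param internode_target peripheral internode target length, um (125 for
#'   the halved-internode robustness variant).
#' @param n_range allowed peripheral internode counts.
#' @param seg_max electrical segmentation: anatomical compartments longer
#'   than this are split into equal sub-segments for the cable
#'   discretization (the soma, nodes, terminal and post-somatic compartment
#'   are never split). Halve for discretization-convergence checks.
#' @return object of class `compartment_chain`: per-segment kind, length,
#'   diameter, membrane capacitance (uF), conductances (mS), neighbor axial
#'   conductances (mS), 3D centers and arc positions.
#' @export
assemble_chain <- function(anf, spec = membrane_spec(),
                           condition = c("healthy", "thin_dendrite", "no_dendrite"),
                           internode_target = 250, n_range = c(4L, 10L),
                           seg_max = 50) {
  condition <- match.arg(condition)
  d_dend <- if (condition == "thin_dendrite") spec$d_thin else spec$d_dendrite

  kinds <- character(0); lens <- numeric(0); dias <- numeric(0)
  if (condition != "no_dendrite") {
    lay <- peripheral_layout(anf$dendrite_length, target = internode_target,
                             n_range = n_range)
    kinds <- c("terminal")
    lens <- c(10)
    for (i in seq_len(lay$n_internodes)) {
      kinds <- c(kinds, "p_internode")
      lens <- c(lens, lay$effective_length)
      if (i < lay$n_internodes) {
        kinds <- c(kinds, "p_node")
        lens <- c(lens, 2.5)
      }
    }
    kinds <- c(kinds, "presomatic")
    lens <- c(lens, 100)
    dias <- rep(d_dend, length(kinds))
  }
  kinds <- c(kinds, "soma", "postsomatic")
  lens <- c(lens, spec$d_soma, 5)
  dias <- c(dias, spec$d_soma, spec$d_axon)
  for (i in seq_len(spec$n_central_internodes)) {
    kinds <- c(kinds, "c_internode", "c_node")
    lens <- c(lens, 500, 2.5)
    dias <- c(dias, spec$d_axon, spec$d_axon)
  }

  ## electrical segmentation of long anatomical compartments
  unsplit <- c("terminal", "p_node", "c_node", "soma", "postsomatic")
  nseg <- ifelse(kinds %in% unsplit, 1L, pmax(1L, ceiling(lens / seg_max)))
  comp_id <- rep(seq_along(kinds), nseg)
  kinds <- kinds[comp_id]
  lens <- (lens / nseg)[comp_id]
  dias <- dias[comp_id]

  ## arc positions along the polyline; the peripheral chain starts at the
  ## terminal (arc 0); a no-dendrite chain starts at the soma position
  start <- if (condition == "no_dendrite") anf$dendrite_length else 0
  bounds <- start + c(0, cumsum(lens))
  centers_arc <- (bounds[-1L] + bounds[-length(bounds)]) / 2
  total_arc <- max(polyline_arclength(anf$polyline))
  if (bounds[length(bounds)] > total_arc) {
    stop("fiber polyline too short for the compartment layout")
  }
  centers <- polyline_point_at(anf$polyline, centers_arc)

  ## membrane quantities
  n <- length(kinds)
  area <- ifelse(kinds == "soma", pi * spec$d_soma^2, pi * dias * lens) * 1e-8 # cm^2
  sheets <- ifelse(kinds == "p_internode", spec$sheets_dendrite,
                   ifelse(kinds == "c_internode", spec$sheets_axon, 1))
  active <- kinds %in% c("terminal", "p_node", "presomatic", "postsomatic",
                         "c_node", "soma")
  boost <- ifelse(kinds == "soma", 1 / spec$soma_layers,
                  ifelse(active, spec$active_boost, 0))
  cap <- spec$c_sheet / sheets * area
  cap[kinds == "soma"] <- spec$c_sheet * area[kinds == "soma"] / spec$soma_layers
  gna <- ifelse(active, spec$g_na * boost * area, 0)
  gk <- ifelse(active, spec$g_k * boost * area, 0)
  gl <- ifelse(active, spec$g_l * boost * area, 0)
  gpass <- ifelse(active, 0, spec$g_sheet / sheets * area)

  ## axial conductances between neighboring compartment centers
  rho <- spec$rho_i * 1e7 # kOhm cm -> Ohm um
  rseg <- rho * (lens / 2) / (pi * dias^2 / 4) # Ohm, half-compartment
  raxial <- rseg[-n] + rseg[-1L]
  gaxial <- 1000 / raxial # mS

  structure(list(
    id = anf$id, alpha_deg = anf$alpha_deg, condition = condition,
    kind = kinds, length = lens, diameter = dias, comp_id = comp_id,
    area_cm2 = area, cap_uF = cap, g_na = gna, g_k = gk, g_l = gl,
    g_pass = gpass, g_axial = gaxial,
    centers = centers, arc = centers_arc,
    spec = spec
  ), class = "compartment_chain")
}

#' @export
print.compartment_chain <- function(x, ...) {
  cat(sprintf("Compartment chain %s (%s): %d compartments, %d peripheral nodes\n",
              x$id, x$condition, length(x$kind), sum(x$kind == "p_node")))
  invisible(x)
}

#' Monophasic pulse specification
#'
#' @param polarity "cathodic" or "anodic".
#' @param duration_us pulse duration, us.
#' @param amplitude current magnitude, uA.
#' @param onset_ms pulse onset, ms.
#' @return list of class `pulse_spec`.
#' @export
pulse_spec <- function(polarity = c("cathodic", "anodic"), duration_us = 50,
                       amplitude = 0, onset_ms = 0.1) {
  polarity <- match.arg(polarity)
  if (duration_us <= 0) stop("pulse duration must be positive")
  if (amplitude < 0) stop("amplitude is a magnitude (>= 0)")
  structure(list(polarity = polarity, duration_us = duration_us,
                 amplitude = amplitude, onset_ms = onset_ms),
            class = "pulse_spec")
}

#' Integrate the cable model under extracellular stimulation
#'
#' Backward-Euler time stepping of
#' C_n dV_n/dt = -I_ion,n + sum_m G_nm ((V_m - V_n) + (Ve_m - Ve_n)),
#' with the extracellular potential Ve = signed amplitude x unit-current
#' potential during the pulse window and zero otherwise. The window is
#' extended automatically while a spike is still developing at its end.
#'
#' @param chain a `compartment_chain`.
#' @param ve_unit extracellular potential at the compartment centers for
#'   +1 uA injected, mV (length = number of compartments).
#' @param pulse a `pulse_spec` (its `amplitude` is the current magnitude).
#' @param t_end_ms simulation window, ms.
#' @param dt_ms time step, ms (must be <= 0.002).
#' @param record keep the full voltage trace (always kept: per-compartment
#'   peak summaries, which suffice for spike detection and the spike
#'   initiation site).
#' @param save_gating keep gating-state trajectories (requires `record`).
#' @return object of class `voltage_trace` with per-compartment `vmax`,
#'   `tmax` and `tcross` summaries and, when recorded, `t` (ms) and `v`
#'   (compartments x time, reduced mV), optionally `m`, `h`, `n`.
#' @export
simulate_fiber <- function(chain, ve_unit, pulse, t_end_ms = 1.5,
                           dt_ms = 0.001, record = TRUE, save_gating = FALSE) {
  n <- length(chain$kind)
  if (length(ve_unit) != n) {
    stop(sprintf("ve_unit has length %d but the chain has %d compartments",
                 length(ve_unit), n))
  }
  if (dt_ms > 0.002) stop("dt must not exceed 0.002 ms")
  amp <- pulse$amplitude * if (pulse$polarity == "cathodic") -1 else 1
  t_end <- t_end_ms
  repeat {
    out <- cable_step_cpp(chain$cap_uF, chain$g_na, chain$g_k, chain$g_l,
                          chain$g_pass, chain$g_axial, ve_unit, amp,
                          pulse$onset_ms, pulse$duration_us / 1000, dt_ms,
                          t_end, chain$spec$k_temp, chain$spec$e_na,
                          chain$spec$e_k, chain$spec$e_l, SPIKE_THRESHOLD_MV,
                          record, save_gating)
    rising <- max(out$v_end) > 30 && out$dv_end > 0.01
    if (!rising || t_end >= 6) break
    t_end <- t_end + 1
  }
  structure(list(t = out$t, v = out$v, dt_ms = dt_ms, pulse = pulse,
                 chain_kind = chain$kind,
                 vmax = out$vmax, tmax = out$tmax, tcross = out$tcross,
                 m = out$m, h = out$h, n_gate = out$n),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("Voltage trace: %d compartments (dt %.3g ms), max V %.1f mV\n",
              length(x$vmax), x$dt_ms, max(x$vmax)))
  invisible(x)
}

SPIKE_THRESHOLD_MV <- 60

#' Detect a propagated spike
#'
#' A trace counts as spiking when the reduced membrane voltage exceeds
#' +60 mV at either of the two most central nodes; the latency is the first
#' crossing time.
#'
#' @param trace a `voltage_trace`.
#' @return list with `spiked` (logical) and `latency_ms` (NA if no spike).
#' @export
detect_spike <- function(trace) {
  if (is.null(trace$vmax) && !is.null(trace$v)) {
    trace$vmax <- apply(trace$v, 1L, max)
    trace$tcross <- apply(trace$v, 1L, function(vv) {
      i <- which(vv >= SPIKE_THRESHOLD_MV)[1L]
      if (is.na(i)) NA_real_ else trace$t[i]
    })
  }
  watch <- tail(which(trace$chain_kind == "c_node"), 2L)
  if (all(trace$vmax[watch] < SPIKE_THRESHOLD_MV)) {
    return(list(spiked = FALSE, latency_ms = NA_real_))
  }
  list(spiked = TRUE, latency_ms = min(trace$tcross[watch], na.rm = TRUE))
}

#' Spike initiation site
#'
#' Among the electrically active compartments (terminal, nodes of Ranvier,
#' pre/post-somatic segments, soma) whose voltage exceeds the spike
#' criterion, returns the one whose voltage peak occurs earliest; ties break
#' toward the terminal (lower index). Passive internode segments are
#' excluded: they can be swung above the criterion directly by the
#' extracellular gradient without initiating anything.
#'
#' @param trace a spiking `voltage_trace`.
#' @return list with `index`, `kind` and `peak_time_ms`.
#' @export
find_sis <- function(trace) {
  if (!detect_spike(trace)$spiked) stop("trace contains no spike")
  vmax <- trace$vmax
  tmax <- trace$tmax
  if (is.null(vmax) && !is.null(trace$v)) {
    vmax <- apply(trace$v, 1L, max)
    tmax <- trace$t[apply(trace$v, 1L, which.max)]
  }
  active <- trace$chain_kind %in% c("terminal", "p_node", "presomatic",
                                    "soma", "postsomatic", "c_node")
  over <- which(vmax >= SPIKE_THRESHOLD_MV & active)
  if (!length(over)) over <- which(vmax >= SPIKE_THRESHOLD_MV)
  idx <- over[which.min(tmax[over])] # which.min takes the first (terminal) tie
  list(index = idx, kind = trace$chain_kind[idx], peak_time_ms = tmax[idx])
}
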