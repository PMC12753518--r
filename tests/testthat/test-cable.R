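# Compartment chain assembly and membrane dynamics

test_that("peripheral layout reproduces the internode-count rule", {
  expect_equal(peripheral_layout(2312)$n_internodes, 9L)
  expect_equal(peripheral_layout(2312)$effective_length, 242.4444, tolerance = 1e-4)
  expect_equal(peripheral_layout(1732)$n_internodes, 6L)
  expect_equal(peripheral_layout(1732)$effective_length, 268.25, tolerance = 1e-4)
  expect_equal(peripheral_layout(1320)$n_internodes, 5L)
  expect_equal(peripheral_layout(1320)$effective_length, 240)
  ## counts across the default fiber set stay in the published 5-9 range
  dl <- vapply(default_fibers(), function(f) f$dendrite_length, numeric(1))
  ns <- vapply(dl, function(d) peripheral_layout(d)$n_internodes, integer(1))
  expect_gte(min(ns), 5L)
  expect_lte(max(ns), 9L)
  expect_error(peripheral_layout(100), "112.5")
})

test_that("assembled chain carries the published compartment dimensions", {
  chain <- fixture("chain256", function() assemble_chain(default_fibers()[[10]]))
  expect_identical(chain$kind[1], "terminal")
  expect_equal(chain$length[1], 10)
  expect_equal(unique(chain$length[chain$kind == "p_node"]), 2.5)
  expect_equal(sum(chain$length[chain$kind == "presomatic"]), 100)
  expect_equal(chain$length[chain$kind == "postsomatic"], 5)
  ## each central internode sums to 500 um across its electrical segments
  ci <- chain$kind == "c_internode"
  per_comp <- tapply(chain$length[ci], chain$comp_id[ci], sum)
  expect_true(all(abs(per_comp - 500) < 1e-9))
  expect_equal(unique(chain$diameter[chain$kind == "terminal"]), 1.3)
  expect_equal(unique(chain$diameter[chain$kind == "c_node"]), 2.6)
  expect_equal(chain$diameter[chain$kind == "soma"], 20)
  ## soma to post-somatic center distance
  i_s <- which(chain$kind == "soma")
  i_p <- which(chain$kind == "postsomatic")
  expect_equal(chain$arc[i_p] - chain$arc[i_s], 12.5)
})

test_that("axial resistance of a peripheral node matches the hand value", {
  ## R = 4 rho L / (pi d^2) with rho = 100 Ohm cm, L = 2.5 um, d = 1.3 um
  r_hand <- 4 * 1e6 * 2.5 / (pi * 1.3^2) # Ohm
  expect_equal(r_hand / 1e6, 1.88, tolerance = 0.01)
  ## the chain's neighbor conductance between two nodes includes two half
  ## compartments; verify the half-compartment bookkeeping on a node pair
  chain <- fixture("chain256", function() assemble_chain(default_fibers()[[10]]))
  i <- which(chain$kind == "p_node")[1]
  rseg <- function(j) 1e6 * (chain$length[j] / 2) / (pi * chain$diameter[j]^2 / 4)
  expect_equal(1000 / chain$g_axial[i], rseg(i) + rseg(i + 1L), tolerance = 1e-9)
})

test_that("degenerated conditions alter the peripheral chain as specified", {
  anf <- default_fibers()[[10]]
  thin <- assemble_chain(anf, condition = "thin_dendrite")
  per <- thin$kind %in% c("terminal", "p_internode", "p_node", "presomatic")
  expect_true(all(thin$diameter[per] == 0.5))
  expect_equal(thin$diameter[thin$kind == "soma"], 20)
  none <- assemble_chain(anf, condition = "no_dendrite")
  expect_identical(none$kind[1], "soma")
  expect_false(any(none$kind %in% c("terminal", "p_node", "p_internode",
                                    "presomatic")))
  expect_error(assemble_chain(anf, condition = "exotic"))
})

test_that("the resting state is an equilibrium", {
  chain <- fixture("chain256", function() assemble_chain(default_fibers()[[10]]))
  ve <- point_source_ve(chain)
  tr <- simulate_fiber(chain, ve, pulse_spec("cathodic", amplitude = 0),
                       t_end_ms = 10)
  expect_lt(max(abs(tr$vmax)), 0.1)
})

test_that("cathodic near-terminal stimulation spikes from the terminal", {
  chain <- fixture("chain256", function() assemble_chain(default_fibers()[[10]]))
  ve <- point_source_ve(chain)
  ## strong pulse: propagated overshoot at the last central node
  strong <- simulate_fiber(chain, ve, pulse_spec("cathodic", amplitude = 1000))
  expect_true(detect_spike(strong)$spiked)
  last_node <- max(which(chain$kind == "c_node"))
  expect_gt(strong$vmax[last_node], 80)
  expect_gt(detect_spike(strong)$latency_ms, 0.1)
  ## at threshold: terminal initiation with a somatic delay
  thr <- threshold_search(chain, ve)
  p <- pulse_spec("cathodic", amplitude = 1.01 * thr$threshold_uA)
  tr <- simulate_fiber(chain, ve, p)
  expect_identical(find_sis(tr)$kind, "terminal")
  i_s <- which(chain$kind == "soma")
  ip <- max(which(chain$kind == "p_node"))
  expect_gt(tr$tmax[i_s], tr$tmax[ip])
})

test_that("activating-function polarity matches the pulse polarity", {
  chain <- fixture("chain256", function() assemble_chain(default_fibers()[[10]]))
  ## source placed perpendicular to the local fiber direction at a
  ## mid-dendritic node, so the potential peaks at that compartment
  node_i <- which(chain$kind == "p_node")[3]
  tang <- chain$centers[node_i + 1L, ] - chain$centers[node_i - 1L, ]
  tang <- tang / sqrt(sum(tang^2))
  nrm <- c(tang[2], -tang[1], 0) # horizontal, perpendicular to the fiber
  nrm <- nrm / sqrt(sum(nrm^2))
  ve <- point_source_ve(chain, offset = 300 * nrm,
                        origin = chain$centers[node_i, ])
  ctr <- which.max(ve)
  probe <- function(pol) {
    p <- pulse_spec(pol, amplitude = 10)
    tr <- simulate_fiber(chain, ve, p, t_end_ms = 0.15)
    tr$v[, ncol(tr$v)] # voltage at pulse end
  }
  vc <- probe("cathodic")
  va <- probe("anodic")
  expect_gt(vc[ctr], 0)      # nearest compartment depolarized (cathodic)
  expect_lt(va[ctr], 0)      # reversed for anodic
  ## the flanking active compartments (side lobes of the activating
  ## function) carry the opposite sign; passive internode segments respond
  ## too slowly within the 50 us pulse to show it
  flank <- setdiff(which(chain$kind %in% c("terminal", "p_node")), ctr)
  expect_lt(min(vc[flank]), 0)
  expect_gt(max(va[flank]), 0)
})

test_that("spike detection and SIS behave on constructed traces", {
  kinds <- c("terminal", "p_node", "soma", "c_node", "c_node")
  t <- seq(0, 1, by = 0.01)
  mk <- function(peaks, times) {
    v <- matrix(0, length(kinds), length(t))
    for (i in seq_along(kinds)) {
      v[i, ] <- peaks[i] * exp(-((t - times[i]) / 0.05)^2)
    }
    structure(list(t = t, v = v, chain_kind = kinds, dt_ms = 0.01),
              class = "voltage_trace")
  }
  ## resting trace: no spike
  expect_false(detect_spike(mk(rep(1, 5), rep(0.5, 5)))$spiked)
  ## hand-placed peaks: earliest above-criterion peak wins
  tr <- mk(c(90, 95, 70, 92, 91), c(0.30, 0.20, 0.40, 0.50, 0.55))
  expect_true(detect_spike(tr)$spiked)
  sis <- find_sis(tr)
  expect_identical(sis$index, 2L)
  expect_identical(sis$kind, "p_node")
  expect_error(find_sis(mk(rep(10, 5), rep(0.5, 5))), "no spike")
})

test_that("voltage traces record gating states at equilibrium start", {
  chain <- fixture("chain256", function() assemble_chain(default_fibers()[[10]]))
  ve <- point_source_ve(chain)
  tr <- simulate_fiber(chain, ve, pulse_spec("cathodic", amplitude = 100),
                       t_end_ms = 0.5, save_gating = TRUE)
  ## classic squid-axon resting gating values
  expect_equal(tr$m[1, 1], 0.0529, tolerance = 1e-3)
  expect_equal(tr$h[1, 1], 0.5961, tolerance = 1e-3)
  expect_equal(tr$n_gate[1, 1], 0.3177, tolerance = 1e-3)
})
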