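# Neural-degeneration experiments and robustness variants, on point-source
# fields (homogeneous medium) so the cable-level orderings are isolated from
# the volume conductor.

degen_thresholds <- function(anf, offset_from) {
  conds <- c("healthy", "thin_dendrite", "no_dendrite")
  out <- list()
  for (cond in conds) {
    ch <- assemble_chain(anf, condition = cond)
    ref <- assemble_chain(anf) # source anchored on the healthy morphology
    src <- switch(offset_from,
      terminal = ref$centers[1, ] + c(0, 0, 255),
      mid = ref$centers[which(ref$kind == "p_node")[3], ] + c(0, 0, -300),
      soma = ref$centers[which(ref$kind == "soma"), ] + c(0, 0, -400)
    )
    r <- sqrt(rowSums((ch$centers -
                         matrix(src, nrow(ch$centers), 3, byrow = TRUE))^2))
    out[[cond]] <- threshold_search(ch, point_source_potential(1, 1.43, r))
  }
  out
}

test_that("SIS progresses outward-in with degeneration near the terminal", {
  ## electrode close to the terminal (lateral-wall situation)
  for (fi in c(3, 10, 17, 20, 24)) {
    res <- degen_thresholds(default_fibers()[[fi]], "terminal")
    expect_identical(res$healthy$sis_kind, "terminal")
    expect_true(res$thin_dendrite$sis_kind %in% c("terminal", "p_node"))
    expect_true(res$no_dendrite$sis_kind %in%
                  c("soma", "postsomatic", "c_node"))
    ## thresholds never decrease with degeneration severity at the terminal
    expect_gte(res$thin_dendrite$threshold_uA, res$healthy$threshold_uA)
  }
})

test_that("thin dendrites shift the SIS toward the stimulation site", {
  ## electrode at the third peripheral node, away from the terminal
  for (fi in c(3, 10, 20)) {
    res <- degen_thresholds(default_fibers()[[fi]], "mid")
    expect_gte(res$thin_dendrite$threshold_uA, res$healthy$threshold_uA)
    thin_ch <- assemble_chain(default_fibers()[[fi]], condition = "thin_dendrite")
    sis_arc <- res$thin_dendrite$sis_arc_um
    term_arc <- 0
    ## the thin-dendrite SIS is peripheral and not at the far terminal
    expect_true(res$thin_dendrite$sis_kind %in% c("p_node", "terminal"))
    if (res$thin_dendrite$sis_kind == "p_node") {
      expect_gt(sis_arc, term_arc)
    }
  }
})

test_that("anodic stimulation of distant fibers initiates in central nodes", {
  fibers <- default_fibers()
  for (fi in c(3, 10)) {
    ch <- assemble_chain(fibers[[fi]])
    far <- fibers[[fi + 2]]$polyline[1, ] + c(0, 0, 255)
    r <- sqrt(rowSums((ch$centers -
                         matrix(far, nrow(ch$centers), 3, byrow = TRUE))^2))
    ## far-field gradients in a homogeneous medium are weak; raise the
    ## bracket cap so the search can complete
    res <- threshold_search(ch, point_source_potential(1, 1.43, r),
                            pulse_spec("anodic"), amp_cap = 1e5)
    expect_true(res$converged)
    expect_identical(res$sis_kind, "c_node")
  }
})

test_that("condition reports reference the healthy baseline correctly", {
  ## miniature map-driven run (coarse, single array, few fibers)
  geom <- default_geom()
  anfs <- place_anfs(geom, n = 3L, alphas = c(23, 256, 680))
  cl <- fit_centerline(geom, anfs, "st", "lw")
  arr <- place_contacts(cl)
  map <- voxelize(geom, list(arr), spacing = 480)
  healthy <- run_condition(anfs, map, "healthy")
  expect_equal(healthy$results$pct_increase, rep(0, 3))
  thin <- run_condition(anfs, map, "thin_dendrite", baseline = healthy)
  expect_equal(thin$results$pct_increase,
               100 * (thin$results$threshold_uA - healthy$results$threshold_uA) /
                 healthy$results$threshold_uA)
  expect_true(all(thin$results$pct_increase >= 0))
  expect_error(run_condition(anfs, map, "thin_dendrite"), "baseline")
})

test_that("fixed-length fiber rebuild preserves anchors and sets the arc", {
  geom <- default_geom()
  anfs <- default_fibers()
  fixed <- fixed_dendrite_anfs(geom, anfs[c(1, 13, 25)], 1700)
  for (i in seq_along(fixed)) {
    f <- fixed[[i]]
    orig <- anfs[c(1, 13, 25)][[i]]
    expect_equal(f$dendrite_length, 1700)
    ## terminal anchor unchanged
    expect_equal(f$polyline[1, ], orig$polyline[1, ], tolerance = 1e-6)
    ## the point 1,700 um along the arc is the soma anchor of the geometry
    an <- cochstim:::fiber_anchors(geom, f$alpha_deg)$soma
    th <- f$alpha_deg * pi / 180
    soma3d <- c(an[1] * cos(th), an[1] * sin(th), an[2])
    expect_equal(as.numeric(polyline_point_at(f$polyline, 1700)), soma3d,
                 tolerance = 2)
  }
})
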