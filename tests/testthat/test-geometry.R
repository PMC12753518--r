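# Synthetic cochlear geometry and fiber placement

test_that("spiral geometry satisfies its structural invariants", {
  geom <- default_geom()
  expect_equal(geom$alpha_range, c(0, 690))
  a <- seq(0, 690, by = 5)
  r <- spiral_radius(geom, a)
  expect_true(all(diff(r) < 0))          # radius strictly decreasing
  expect_true(all(diff(spiral_height(geom, a)) >= 0)) # height non-decreasing
  for (duct in c("st", "sm", "sv")) {
    expect_true(all(canal_radius(geom, a, duct) > 0))
  }
  ## cross-sections pairwise disjoint at every sampled angle
  for (pair in list(c("st", "sm"), c("st", "sv"), c("sm", "sv"))) {
    c1 <- canal_center(geom, a, pair[1]); r1 <- canal_radius(geom, a, pair[1])
    c2 <- canal_center(geom, a, pair[2]); r2 <- canal_radius(geom, a, pair[2])
    d <- sqrt(rowSums((c1 - c2)^2))
    expect_true(all(d > r1 + r2))
  }
})

test_that("degenerate or invalid configurations are rejected", {
  expect_error(build_geometry(geometry_config(turns = 0)), "configuration")
  expect_error(build_geometry(geometry_config(basal_radius = -10)), "configuration")
  expect_error(build_geometry(geometry_config(pitch = 0)), "configuration")
})

test_that("geometry generation is pure (identical config, identical output)", {
  g1 <- build_geometry()
  g2 <- build_geometry()
  expect_identical(g1, g2)
  f1 <- place_anfs(g1, seed = 7L)
  f2 <- place_anfs(g2, seed = 7L)
  expect_identical(f1[[13]]$polyline, f2[[13]]$polyline)
})

test_that("default fiber set reproduces the traced-fiber morphometry", {
  fibers <- default_fibers()
  expect_length(fibers, 25L)
  al <- vapply(fibers, function(f) f$alpha_deg, numeric(1))
  ## the named insertion angles are present
  expect_true(all(c(23, 77, 195, 256, 416, 467, 494, 680) %in% round(al)))
  dl <- vapply(fibers, function(f) f$dendrite_length, numeric(1))
  expect_equal(min(dl), 1320)
  expect_equal(median(dl), 1732)
  expect_equal(max(dl), 2312)
  ## the polyline arc lengths realize the assigned dendritic lengths
  for (f in fibers[c(1, 13, 25)]) {
    s <- polyline_arclength(f$polyline)
    expect_gt(max(s), f$dendrite_length + 20 + 5000) # dendrite + soma + axon
    ## soma center lands at the dendritic end of the arc
    expect_equal(f$soma_arc_pos, f$dendrite_length + 10)
  }
})

test_that("single fiber placement at a named angle is labeled accordingly", {
  geom <- default_geom()
  fs <- place_anfs(geom, n = 1L, alphas = 23)
  expect_length(fs, 1L)
  expect_identical(fs[[1]]$id, "ANF23")
  expect_equal(fs[[1]]$alpha_deg, 23)
  expect_error(place_anfs(geom, n = 1L, alphas = 800), "range")
  expect_error(place_anfs(geom, n = 0L), "n must be")
})

test_that("geometry and fiber sets survive the JSON round trip", {
  geom <- default_geom()
  fibers <- place_anfs(geom, n = 3L, alphas = c(23, 256, 680))
  gp <- withr::local_tempfile(fileext = ".json")
  write_geometry_json(geom, gp)
  g2 <- read_geometry_json(gp)
  expect_equal(spiral_radius(g2, c(0, 345, 690)),
               spiral_radius(geom, c(0, 345, 690)))
  fp <- withr::local_tempfile(fileext = ".json")
  write_anfs_json(fibers, fp)
  f2 <- read_anfs_json(fp)
  expect_equal(f2[[2]]$polyline, fibers[[2]]$polyline)
  expect_equal(f2[[2]]$dendrite_length, fibers[[2]]$dendrite_length)
})
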