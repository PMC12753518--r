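# Electrode-array construction

test_that("uncoupled lwST fit holds the 255 um fiber-distance constraint", {
  cl <- lwst_centerline()
  d <- cl$fiber_min_dist
  expect_length(d, 25L)
  expect_lt(abs(median(d) - 255) / 255, 0.05)
  ## constraint satisfaction across fibers
  expect_lt(max(abs(d - 255)) / 255, 0.10)
})

test_that("all four centerlines stay within the array length window", {
  geom <- default_geom()
  fibers <- default_fibers()
  for (combo in list(c("lw", "st"), c("pm", "st"), c("lw", "sv"), c("pm", "sv"))) {
    key <- paste0("cl_", combo[1], combo[2])
    cl <- fixture(key, function() {
      fit_centerline(geom, fibers, combo[2], combo[1])
    })
    len <- max(cl$arclength)
    expect_gte(len, 23000)
    expect_lte(len, 27000)
    expect_lt(abs(median(cl$fiber_min_dist) - 255) / 255, 0.05)
  }
})

test_that("lateral coupling makes the ST/SV pair share radial coordinates", {
  geom <- default_geom()
  fibers <- default_fibers()
  cst <- fixture("cl_lwst_coupled", function() {
    fit_centerline(geom, fibers, "st", "lw", couple_lateral = TRUE)
  })
  csv <- fixture("cl_lwsv_coupled", function() {
    fit_centerline(geom, fibers, "sv", "lw", couple_lateral = TRUE)
  })
  us <- splinefun(cst$control_alphas, cst$control_u, method = "natural")
  uv <- splinefun(csv$control_alphas, csv$control_u, method = "natural")
  expect_equal(us(cst$alpha), uv(cst$alpha), tolerance = 1e-10)
})

test_that("the fit is stable against a perturbed initialization", {
  geom <- default_geom()
  fibers <- default_fibers()
  cl1 <- lwst_centerline()
  cl2 <- fit_centerline(geom, fibers, "st", "lw", relax = 0.35)
  expect_lt(max(sqrt(rowSums((cl1$points - cl2$points)^2))), 120)
})

test_that("carrier taper is monotone with exact end radii", {
  cl <- lwst_centerline()
  a <- seq(0, cl$alpha_max, by = 5)
  r <- carrier_radius(cl, a)
  expect_equal(r[1], 300)
  expect_equal(r[length(r)], 150)
  expect_true(all(diff(r) < 0))
})

test_that("contacts are placed on the carrier surface facing their targets", {
  arr <- lwst_array()
  fibers <- default_fibers()
  expect_equal(nrow(arr$contacts), 25L)
  expect_identical(arr$contacts$id[1], "EL23")
  ## default orientation in ST is +z (toward the fibers)
  expect_true(all(arr$contacts$oz == 1))
  ## each contact is the nearest one to its same-angle fiber
  for (i in c(1, 9, 17, 25)) {
    d <- vapply(arr$contacts$id, function(cid) {
      min_distance_profile(arr, fibers[[i]], cid, spacing = 25)$min_dist
    }, numeric(1))
    expect_equal(unname(which.min(d)), i)
  }
  ## empty contact list gives a carrier-only array
  empty <- place_contacts(lwst_centerline(), alphas = numeric(0))
  expect_identical(nrow(empty$contacts), 0L)
  expect_error(place_contacts(lwst_centerline(), alphas = 800), "tip")
})

test_that("axis-facing contacts sit farther from the fibers on lw arrays", {
  fibers <- default_fibers()
  arr_def <- lwst_array()
  arr_alt <- place_contacts(lwst_centerline(), orientation_mode = "alternative")
  d_def <- vapply(seq_along(fibers), function(i) {
    min_distance_profile(arr_def, fibers[[i]], arr_def$contacts$id[i])$min_dist
  }, numeric(1))
  d_alt <- vapply(seq_along(fibers), function(i) {
    min_distance_profile(arr_alt, fibers[[i]], arr_alt$contacts$id[i])$min_dist
  }, numeric(1))
  expect_true(all(d_alt >= d_def))
})

test_that("distance profiles match direct geometric computation", {
  ## toy three-point fiber and a hand-placed contact
  fiber <- structure(list(
    id = "toy", alpha_deg = 0,
    polyline = rbind(c(0, 0, 0), c(100, 0, 0), c(100, 100, 0)),
    dendrite_length = 150, soma_arc_pos = 160
  ), class = "anf_path")
  arr <- lwst_array()
  arr$contacts <- data.frame(id = "ELX", alpha_deg = 0,
                             x = 100, y = 0, z = -40,
                             ox = 0, oy = 0, oz = 1, radius = 150, height = 50)
  prof <- min_distance_profile(arr, fiber, "ELX", spacing = 100)
  expect_equal(prof$min_dist, 40)
  expect_equal(prof$argmin_arc, 100)
  ## translating the fiber away increases the minimum accordingly
  fiber2 <- fiber
  fiber2$polyline[, 3] <- fiber2$polyline[, 3] + 100
  prof2 <- min_distance_profile(arr, fiber2, "ELX", spacing = 100)
  expect_equal(prof2$min_dist, 140)
  expect_error(min_distance_profile(arr, fiber, "EL999"), "unknown")
})
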