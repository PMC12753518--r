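# Conductivity map construction

test_that("default conductivities carry the published domain values", {
  sig <- default_conductivities()
  expect_equal(unname(sig["st"]), 1.43)
  expect_equal(unname(sig["sv"]), 1.43)
  expect_equal(unname(sig["sm"]), 1.67)
  expect_equal(unname(sig["modiolus"]), 0.0334)
  expect_equal(unname(sig["bone"]), 0.016)
  expect_equal(unname(sig["contact"]), 1000)
  expect_lte(unname(sig["carrier"]), 1e-6) # insulator, kept non-singular
})

test_that("voxel map labels every voxel and assigns domain conductivities", {
  geom <- default_geom()
  map <- fixture("map420", function() {
    voxelize(default_geom(), list(lwst_array()), spacing = 420)
  })
  expect_true(all(map$label >= 1L & map$label <= 8L))
  ## per-domain sigma values
  expect_true(all(map$sigma[map$label == map$legend["modiolus"]] == 0.0334))
  expect_true(all(map$sigma[map$label == map$legend["st"]] == 1.43))
  expect_true(all(map$sigma[map$label == map$legend["contact"]] == 1000))
  ## all contacts rasterized
  expect_length(map$contact_voxels, 25L)
  expect_true(all(lengths(map$contact_voxels) > 0))
  ## exterior padding at least one cochlear diameter on all sides
  bb <- geometry_bbox(geom)
  expect_gte(-map$xs[1], bb$xy_radius + 2 * bb$xy_radius)
})

test_that("ossification levels rewrite the scala tympani conductivity", {
  map <- fixture("map420", function() {
    voxelize(default_geom(), list(lwst_array()), spacing = 420)
  })
  st <- map$label == map$legend["st"]
  expect_true(any(st))
  for (lv in names(ossification_levels())) {
    m2 <- apply_ossification(map, lv)
    expect_true(all(m2$sigma[st] == ossification_levels()[[lv]]))
  }
  m3 <- apply_ossification(map, "complete")
  expect_true(all(m3$sigma[st] == 0.03))
  ## other domains untouched
  expect_equal(m3$sigma[map$label == map$legend["sv"]],
               map$sigma[map$label == map$legend["sv"]])
  expect_error(apply_ossification(map, "everything"), "unknown")
})

test_that("conductivity variants scale only their domains", {
  map <- fixture("map420", function() {
    voxelize(default_geom(), list(lwst_array()), spacing = 420)
  })
  m10 <- conductivity_variant(map, modiolus_factor = 10)
  sel <- map$label == map$legend["modiolus"]
  expect_equal(unique(m10$sigma[sel]), 0.334)
  expect_equal(m10$sigma[!sel], map$sigma[!sel])
  b2 <- conductivity_variant(map, bone_factor = 2)
  bone <- map$label %in% map$legend[c("bone", "exterior")]
  expect_true(all(b2$sigma[bone] == 0.032))
  expect_equal(b2$sigma[!bone], map$sigma[!bone])
  expect_error(conductivity_variant(map, modiolus_factor = 0), "positive")
})

test_that("labeled duct volumes converge toward the analytic solid volume", {
  geom <- default_geom()
  v_analytic <- duct_volume(geom, "st")
  m1 <- voxelize(geom, list(), spacing = 320)
  m2 <- voxelize(geom, list(), spacing = 160)
  v1 <- domain_volume(m1, "st")
  v2 <- domain_volume(m2, "st")
  expect_lt(abs(v2 - v1) / v1, 0.10)       # < 10% change per halving
  expect_lt(abs(v2 - v_analytic) / v_analytic, 0.10)
})

test_that("a spacing too coarse for the contacts is rejected", {
  expect_error(voxelize(default_geom(), list(lwst_array()), spacing = 2000),
               "too coarse|no voxels")
  expect_error(voxelize(default_geom(), list(), spacing = -5), "positive")
})
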