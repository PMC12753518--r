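# Extracellular field computation

test_that("point-source potential follows I/(4 pi sigma r)", {
  expect_equal(point_source_potential(1, 1.43, 255), 0.2183, tolerance = 5e-4)
  ## 1/r and 1/sigma scalings are exact
  expect_equal(point_source_potential(1, 1.43, 2550),
               point_source_potential(1, 1.43, 255) / 10)
  expect_equal(point_source_potential(1, 2 * 1.43, 255),
               point_source_potential(1, 1.43, 255) / 2)
  expect_equal(point_source_potential(3, 1.43, 255),
               3 * point_source_potential(1, 1.43, 255))
  expect_error(point_source_potential(1, 1.43, 0), "singular")
  expect_error(point_source_potential(1, -1, 100), "positive")
})

test_that("FDM solution matches the analytic point source in the test shell", {
  fx <- uniform_fixture()
  h <- fx$map$spacing
  set.seed(42)
  for (i in 1:200) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    r <- runif(1, 5 * h, fx$n / 4 * h)
    ve <- sample_potential(fx$field, matrix(fx$center + dir * r, 1))
    expect_lt(abs(ve / point_source_potential(1, 1.43, r) - 1), 0.05)
  }
})

test_that("discrete current is conserved through closed boxes", {
  fx <- uniform_fixture()
  for (half in c(3L, 6L, 9L)) {
    flux <- flux_through_box(fx$field, fx$map,
                             rep(20L - half, 3L), rep(20L + half, 3L))
    expect_lt(abs(flux - 1), 1e-6)
  }
})

test_that("solution is reciprocal under source/probe exchange", {
  fx <- uniform_fixture()
  n <- fx$n
  a <- fx$src
  b <- (28L - 1L) + (24L - 1L) * n + (22L - 1L) * n * n + 1L
  fa <- solve_field(fx$map, a)
  fb <- solve_field(fx$map, b)
  expect_equal(fa$v[b], fb$v[a], tolerance = 1e-6)
})

test_that("field scales linearly with conductivity and current", {
  n <- 24L
  map <- uniform_map(n, 120, sigma = 0.5)
  src <- (12L - 1L) + (12L - 1L) * n + (12L - 1L) * n * n + 1L
  f1 <- solve_field(map, src)
  map10 <- map
  map10$sigma <- map$sigma * 10
  f10 <- solve_field(map10, src)
  expect_equal(as.numeric(f10$v), as.numeric(f1$v) / 10, tolerance = 1e-6)
  ## scaling the injected current at sampling time is linear by definition
  p <- matrix(c(map$xs[4], map$ys[18], map$zs[9]), 1)
  expect_equal(2 * sample_potential(f1, p), sample_potential(f1, p) * 2)
})

test_that("pcg and sparse-Cholesky solves agree within the residual contract", {
  n <- 20L
  map <- uniform_map(n, 150, sigma = 1.43)
  map$sigma[1:6, 1:8, 1:8] <- 0.016 # heterogeneous block
  src <- (10L - 1L) + (10L - 1L) * n + (10L - 1L) * n * n + 1L
  f1 <- solve_field(map, src, method = "pcg")
  f2 <- solve_field(map, src, method = "cholesky")
  expect_lt(max(abs(f1$v - f2$v)) / max(abs(f1$v)), 1e-6)
  expect_lte(f1$meta$residual, 1e-8)
})

test_that("sampling interpolates exactly on nodes and linear fields", {
  fx <- uniform_fixture()
  map <- fx$map
  ## grid nodes reproduce grid values
  pts <- rbind(c(map$xs[3], map$ys[17], map$zs[25]),
               c(map$xs[30], map$ys[8], map$zs[12]))
  expect_equal(sample_potential(fx$field, pts),
               c(fx$field$v[3, 17, 25], fx$field$v[30, 8, 12]))
  ## midpoint of two nodes on a linear synthetic field -> arithmetic mean
  lin <- fx$field
  lin$v <- array(rep(map$xs, times = 40 * 40), dim = map$dim)
  mid <- matrix(c((map$xs[5] + map$xs[6]) / 2, map$ys[7], map$zs[9]), 1)
  expect_equal(sample_potential(lin, mid), (map$xs[5] + map$xs[6]) / 2)
  ## order preserved and length bookkeeping
  q <- matrix(rep(fx$center, 4), 4, byrow = TRUE) + cbind(1:4 * 100, 0, 0)
  expect_length(sample_potential(fx$field, q), 4L)
  expect_error(sample_potential(fx$field, matrix(c(1e6, 0, 0), 1)), "outside")
})

test_that("carrier profile is normalized with its peak at the active contact", {
  fx <- uniform_fixture()
  ## a straight synthetic centerline through the source
  cl <- list(points = cbind(seq(-1800, 1800, by = 60) + fx$center[1],
                            fx$center[2], fx$center[3]),
             alpha = seq(0, 690, length.out = 61), alpha_max = 690,
             scala = "st", style = "lw")
  class(cl) <- "centerline"
  prof <- potential_along_carrier(fx$field, cl, active_alpha = 345)
  expect_equal(max(prof$profile), 1)
  ## decays away from the peak on both sides in a homogeneous medium
  pk <- which.max(prof$profile)
  expect_true(all(diff(prof$profile[1:pk]) > 0))
  expect_true(all(diff(prof$profile[pk:length(prof$profile)]) < 0))
  zero <- fx$field
  zero$v <- array(0, fx$map$dim)
  expect_error(potential_along_carrier(zero, cl), "zero field")
})
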