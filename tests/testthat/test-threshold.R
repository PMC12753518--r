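# Threshold search and threshold matrices

test_that("bisection threshold matches a fine linear amplitude sweep", {
  chain <- fixture("chain256", function() assemble_chain(default_fibers()[[10]]))
  ve <- point_source_ve(chain)
  res <- threshold_search(chain, ve)
  expect_true(res$converged)
  expect_gt(res$threshold_uA, 0)
  oracle <- sweep_threshold(chain, ve, lo = 0.85 * res$threshold_uA,
                            hi = 1.2 * res$threshold_uA)
  expect_lt(abs(res$threshold_uA - oracle) / oracle, 0.01)
})

test_that("threshold scales inversely with the field strength", {
  chain <- fixture("chain256", function() assemble_chain(default_fibers()[[10]]))
  ve <- point_source_ve(chain)
  r1 <- threshold_search(chain, ve)
  r2 <- threshold_search(chain, 2 * ve)
  expect_equal(r2$threshold_uA, r1$threshold_uA / 2, tolerance = 1e-9)
})

test_that("threshold is stable under time-step halving and re-segmentation", {
  chain <- fixture("chain256", function() assemble_chain(default_fibers()[[10]]))
  ve <- point_source_ve(chain)
  r1 <- threshold_search(chain, ve)
  r_dt <- threshold_search(chain, ve, dt_ms = 0.0005)
  expect_lt(abs(r_dt$threshold_uA - r1$threshold_uA) / r1$threshold_uA, 0.02)
  fine <- assemble_chain(default_fibers()[[10]], seg_max = 25)
  r_seg <- threshold_search(fine, point_source_ve(fine))
  expect_lt(abs(r_seg$threshold_uA - r1$threshold_uA) / r1$threshold_uA, 0.02)
})

test_that("threshold grows monotonically with electrode distance", {
  ## straight fiber in a homogeneous medium
  geom <- default_geom()
  anf <- place_anfs(geom, n = 1L, alphas = 256)[[1]]
  chain <- assemble_chain(anf)
  thr <- vapply(seq(100, 1000, by = 150), function(d) {
    ve <- point_source_ve(chain, offset = c(0, 0, d))
    threshold_search(chain, ve)$threshold_uA
  }, numeric(1))
  expect_true(all(diff(thr) > 0))
})

test_that("non-excitable configurations are masked, not errors", {
  chain <- fixture("chain256", function() assemble_chain(default_fibers()[[10]]))
  ve <- point_source_ve(chain) * 1e-7 # essentially no field
  res <- threshold_search(chain, ve, amp_cap = 1000)
  expect_false(res$converged)
  expect_true(is.na(res$threshold_uA))
})

test_that("polarity effect follows its defining formula", {
  expect_equal(polarity_effect(100, 100), 0)
  expect_equal(polarity_effect(100, 200), -6.0206, tolerance = 1e-4)
  expect_equal(polarity_effect(200, 100), -polarity_effect(100, 200))
  expect_error(polarity_effect(-5, 10), "positive")
  expect_error(polarity_effect(10, 0), "positive")
})

test_that("threshold matrix composes individual searches", {
  fibers <- default_fibers()[c(5, 18)]
  chains <- lapply(fibers, assemble_chain)
  ## two-contact toy: voxel sources near each fiber terminal in a uniform box
  n <- 56L
  map <- uniform_map(n, 150, sigma = 1.43)
  vox_near <- function(p) {
    ii <- vapply(1:3, function(ax) {
      which.min(abs(list(map$xs, map$ys, map$zs)[[ax]] - p[ax]))
    }, integer(1))
    (ii[1] - 1L) + (ii[2] - 1L) * n + (ii[3] - 1L) * n * n + 1L
  }
  fields <- list(
    ELA = solve_field(map, vox_near(fibers[[1]]$polyline[1, ] + c(0, 0, -300))),
    ELB = solve_field(map, vox_near(fibers[[2]]$polyline[1, ] + c(0, 0, -300)))
  )
  tm <- threshold_matrix(chains, fields)
  expect_identical(dim(tm$thresholds), c(2L, 2L))
  direct <- vapply(1:2, function(j) {
    vapply(1:2, function(i) {
      threshold_search(chains[[i]],
                       chain_potentials(fields[[j]], chains[[i]]))$threshold_uA
    }, numeric(1))
  }, numeric(2))
  expect_equal(unname(tm$thresholds), direct)
  ## each contact excites its own fiber at the lowest current
  expect_equal(unname(apply(tm$thresholds, 2, which.min)), c(1L, 2L))
  expect_error(threshold_matrix(chains, list()), "missing fields")
})
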