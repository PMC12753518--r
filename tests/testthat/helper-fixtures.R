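# Shared fixtures, built once per test session. Everything is generated in
# code; the default geometry and fiber set are the study conditions, while
# solver grids are kept small where the check permits.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, producer) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, producer(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

default_geom <- function() fixture("geom", function() build_geometry())

default_fibers <- function() {
  fixture("fibers", function() place_anfs(default_geom()))
}

lwst_centerline <- function() {
  fixture("lwst_cl", function() {
    fit_centerline(default_geom(), default_fibers(), "st", "lw")
  })
}

lwst_array <- function() {
  fixture("lwst_array", function() place_contacts(lwst_centerline()))
}

## uniform-medium verification field: 40^3 voxels at 120 um, 1.43 S/m, a
## single-voxel source at the center, solved with analytic (free-space)
## boundary values
uniform_fixture <- function() {
  fixture("uniform_field", function() {
    n <- 40L
    map <- uniform_map(n, 120, sigma = 1.43)
    src <- (20L - 1L) + (20L - 1L) * n + (20L - 1L) * n * n + 1L
    field <- solve_field(map, src, boundary = "free")
    list(n = n, map = map, src = src, field = field,
         center = c(map$xs[20], map$ys[20], map$zs[20]))
  })
}

## point-source unit potential at the compartment centers of a chain, for a
## source placed at `offset` from the terminal (um); the default sits above
## the terminal (off-fiber, where an electrode facing it would be)
point_source_ve <- function(chain, offset = c(0, 0, 255), sigma = 1.43,
                            origin = NULL) {
  src <- if (is.null(origin)) chain$centers[1L, ] + offset else origin + offset
  r <- sqrt(rowSums((chain$centers -
                       matrix(src, nrow(chain$centers), 3L, byrow = TRUE))^2))
  point_source_potential(1, sigma, r)
}

## brute-force threshold oracle: linear amplitude sweep at 0.5% steps
sweep_threshold <- function(chain, ve, pulse = pulse_spec("cathodic"),
                            lo, hi) {
  amps <- lo * 1.005^(0:ceiling(log(hi / lo) / log(1.005)))
  for (a in amps) {
    p <- pulse
    p$amplitude <- a
    if (detect_spike(simulate_fiber(chain, ve, p, record = FALSE))$spiked) {
      return(a)
    }
  }
  NA_real_
}
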