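test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(c(3, 4, 5), 1)), 0)
  two <- rbind(c(0, 0, 0), c(6, 0, 0))
  expect_equal(radius_of_gyration(two), 3)          # d / 2
  rod <- make_fixture("rod", list(n = 50, a = 2))
  expect_equal(radius_of_gyration(rod$points), rod$expected$rg)
  expect_equal(rod$expected$rg, 2 * sqrt((50^2 - 1) / 12))
})

test_that("structure factor limits: single node, coherent low-q, two-node
           closed form", {
  sq1 <- structure_factor(list(matrix(c(1, 2, 3), 1)), q = c(0.1, 0.5, 2),
                          n_directions = 16)
  expect_equal(sq1$profile$S, rep(1, 3), tolerance = 1e-12)

  fx <- make_fixture("gaussian_chain", list(n = 64), seed = 3)
  N <- nrow(fx$points)
  rg <- radius_of_gyration(fx$points)
  q0 <- 2 * pi / (100 * rg)
  sq <- structure_factor(list(fx$points), q = q0, n_directions = 128)
  expect_equal(sq$profile$S, N, tolerance = 0.01)   # S(q -> 0) -> N within 1%

  # two nodes at distance r: spherical average S = 1 + sin(qr)/(qr)
  r <- 7
  pts <- rbind(c(0, 0, 0), c(r, 0, 0))
  qs <- c(0.3, 0.8, 1.7)
  sq2 <- structure_factor(list(pts), q = qs, n_directions = 4000, seed = 2)
  expect_equal(sq2$profile$S, 1 + sin(qs * r) / (qs * r), tolerance = 0.05)
})

test_that("effective dimension is exact on a pure power law", {
  q <- exp(seq(log(0.05), log(2), length.out = 30))
  sq <- structure(list(profile = data.frame(q = q, S = q^-2, se = 0),
                       N = 100, rg = 10), class = "bfm_sq")
  f <- fit_effective_dimension(sq, window = range(q))
  expect_equal(f$De, 2, tolerance = 1e-10)
  expect_error(fit_effective_dimension(sq, window = c(5, 10)), "fewer than 4")
})

test_that("effective dimension on the Debye (ideal-chain) form is 2", {
  rg <- 12
  q <- exp(seq(log(2 / rg), log(8 / rg), length.out = 20))
  x <- (q * rg)^2
  S <- 500 * 2 * (exp(-x) - 1 + x) / x^2
  sq <- structure(list(profile = data.frame(q = q, S = S, se = 0),
                       N = 500, rg = rg), class = "bfm_sq")
  f <- fit_effective_dimension(sq, window = range(q))
  expect_equal(f$De, 2, tolerance = 0.1)
})

test_that("synthetic rod, Gaussian chain and sphere recover D_e = 1, 2, 3", {
  targets <- c(rod = 1, gaussian_chain = 2, sphere_cloud = 3)
  for (kind in names(targets)) {
    # average S(q) over several independent clouds of the same geometry
    fxs <- lapply(1:8, function(s)
      make_fixture(kind, list(), seed = s))
    sq <- structure_factor(lapply(fxs, `[[`, "points"),
                           q = exp(seq(log(fxs[[1]]$expected$window[1]),
                                       log(fxs[[1]]$expected$window[2]),
                                       length.out = 16)),
                           n_directions = 512, seed = 4)
    f <- fit_effective_dimension(sq, window = fxs[[1]]$expected$window)
    expect_equal(f$De, unname(targets[kind]), tolerance = 0.2,
                 info = kind)
  }
})

test_that("center-of-mass displacement: static, diffusive and ballistic", {
  static <- list(matrix(5, nrow = 40, ncol = 3))
  rc <- rms_com_displacement(static, dt = 10)
  expect_equal(rc$series$rc, rep(0, 39))

  set.seed(7)
  walks <- lapply(1:40, function(i)
    apply(matrix(stats::rnorm(3 * 300), ncol = 3), 2, cumsum))
  rc <- rms_com_displacement(walks, dt = 1)
  expect_equal(rc$exponent, 0.5, tolerance = 0.05)

  ball <- list(outer(1:100, c(1, 2, -1)))
  rc <- rms_com_displacement(ball, dt = 1)
  expect_equal(rc$exponent, 1, tolerance = 1e-6)
})

test_that("residue profiles reduce ledgers and energies correctly", {
  # hand-built two-sample ensemble of a 3-residue chain, grain 1
  mk_run <- function(en, att, acc) {
    structure(list(
      series = data.frame(t = c(50, 100), rg = c(1, 1), energy = c(0, 0),
                          com_x = 0, com_y = 0, com_z = 0),
      node_energies = en, attempts = att, accepts = acc,
      steps = 100L, dump_interval = 50L), class = "bfm_run")
  }
  ens <- structure(list(
    runs = list(
      mk_run(rbind(c(1, 2, 3), c(3, 4, 5)),
             att = rbind(c(10, 10, 10), c(30, 20, 25)),
             acc = rbind(c(10, 10, 10), c(30, 20, 25))),
      mk_run(rbind(c(0, 0, 0), c(2, 2, 2)),
             att = rbind(c(8, 8, 8), c(16, 24, 28)),
             acc = rbind(c(4, 2, 0), c(8, 6, 5)))),
    config = bfm_config(T = 1, fs = 0, steps = 100, samples = 2,
                        lattice = lattice_spec(16)),
    sequence = "MAR", grain_map = expand_sequence("MAR", 1)),
    class = "bfm_ensemble")
  pr <- residue_profiles(ens)$profile
  # equilibrium window = frame 2 only
  expect_equal(pr$energy_mean, c(mean(c(3, 2)), mean(c(4, 2)), mean(c(5, 2))))
  # sample 1: attempts == accepts -> mobility 1; sample 2: 0.5, 0.25, 0.25
  expect_equal(pr$mobility_mean,
               c(mean(c(1, 0.5)), mean(c(1, 0.25)), mean(c(1, 0.25))))
  expect_true(all(pr$mobility_mean >= 0 & pr$mobility_mean <= 1))
})

test_that("peak location: interior argmax, refinement, boundary flag", {
  fs <- c(0, 1, 2, 5, 10)
  pk <- locate_peak(fs, c(1, 3, 7, 4, 2), refine = FALSE)
  expect_equal(pk$x_max, 2)
  expect_false(pk$boundary)
  pk2 <- locate_peak(fs, c(1, 2, 3, 4, 5))
  expect_true(pk2$boundary)
  # parabolic refinement recovers an off-grid vertex
  x <- c(1, 2, 3, 4, 5)
  y <- -(x - 2.6)^2
  pk3 <- locate_peak(x, y)
  expect_equal(pk3$x_max, 2.6, tolerance = 1e-9)
})

test_that("solvent scan plumbing reports the grid, errors and flags", {
  cfg <- bfm_config(T = 0.05, fs = 0, steps = 200, samples = 2, seed = 2,
                    dump_interval = 50, audit_interval = 100,
                    lattice = lattice_spec(16))
  sc <- solvent_scan("MARKQTAR", T = 0.05, fs_grid = c(0, 1, 2), cfg)
  expect_equal(sc$scan$fs, c(0, 1, 2))
  expect_true(all(is.finite(sc$scan$rg)))
  expect_type(sc$boundary, "logical")
  expect_error(solvent_scan("MA", 0.05, c(1, 2), cfg), "3")
})
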