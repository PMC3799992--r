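# a chain snaking through every anchor of a 4x4x4 grid with spacing 2 on an
# L = 8 periodic lattice: every unit move of every node violates excluded
# volume, so the state is completely frozen
frozen_snake <- function() {
  coords <- matrix(0L, 64, 3)
  i <- 1
  for (zi in 0:3) {
    ys <- if (zi %% 2 == 0) 0:3 else 3:0
    for (yi in ys) {
      xs <- if ((zi * 4 + which(ys == yi)) %% 2 == 1) 0:3 else 3:0
      for (xi in xs) {
        coords[i, ] <- c(2L * xi, 2L * yi, 2L * zi)
        i <- i + 1
      }
    }
  }
  manual_chain(coords, rep("A", 64), L = 8)
}

test_that("a fully caged configuration never accepts a move", {
  ch <- frozen_snake()
  expect_silent(validate_chain(ch))
  r <- run_chain(ch, interaction_model(fs = 0), steps = 50, T = 10,
                 seed = 1, dump_interval = 10, audit_interval = 25)
  last <- nrow(r$accepts)
  expect_equal(sum(r$accepts[last, ]), 0)
  expect_gt(sum(r$attempts[last, ]), 0)
  expect_identical(r$chain$unwrapped, ch$unwrapped)
})

test_that("identical seeds give bit-identical trajectories", {
  cfg <- bfm_config(T = 0.03, fs = 2, steps = 200, samples = 2, seed = 5,
                    dump_interval = 20, audit_interval = 100,
                    lattice = lattice_spec(16))
  fx <- make_fixture("random_seq", list(n = 10), seed = 1)
  a <- run_ensemble(fx$sequence, cfg)
  b <- run_ensemble(fx$sequence, cfg)
  expect_identical(a$runs[[1]]$series, b$runs[[1]]$series)
  expect_identical(a$runs[[2]]$frames, b$runs[[2]]$frames)
  # replicas differ from each other
  expect_false(identical(a$runs[[1]]$series$rg, a$runs[[2]]$series$rg))
})

test_that("trivial ensemble contract: 2 steps, dump 1, later-half window", {
  cfg <- bfm_config(T = 0.05, fs = 0, steps = 2, samples = 1, seed = 3,
                    dump_interval = 1, audit_interval = 2,
                    lattice = lattice_spec(16))
  ens <- run_ensemble("MARK", cfg)
  expect_equal(nrow(ens$runs[[1]]$series), 2)
  expect_equal(equilibrium_frames(ens$runs[[1]]), 2L)
})

test_that("at very high T acceptance equals the purely geometric rate", {
  # no-energy oracle: a model whose couplings are all zero
  aa <- amino_acids()
  zero <- matrix(0, 20, 20, dimnames = list(aa, aa))
  m_zero <- interaction_model(fs = 0, contact = zero,
                              normalize_contact = FALSE)
  m_hot <- interaction_model(fs = 0)
  seqs <- strrep("A", 16)
  ch <- initialize_chain(seqs, 1, lattice_spec(32), seed = 2)
  r0 <- run_chain(ch, m_zero, 2000, T = 1, seed = 9, dump_interval = 2000,
                  audit_interval = 1000)
  r1 <- run_chain(ch, m_hot, 2000, T = 1e8, seed = 9, dump_interval = 2000,
                  audit_interval = 1000)
  acc0 <- sum(r0$accepts[1, ]) / sum(r0$attempts[1, ])
  acc1 <- sum(r1$accepts[1, ]) / sum(r1$attempts[1, ])
  # at T -> Inf every geometrically legal move is accepted in both runs;
  # the two realizations differ only by sampling noise
  expect_equal(acc1, acc0, tolerance = 0.05)
  expect_gt(acc0, 0.1)
})

test_that("the enumerable two-node system equilibrates to the Boltzmann
           distribution", {
  model <- interaction_model(fs = 1)
  bv <- bond_vectors()
  E <- vapply(seq_len(nrow(bv)), function(i) {
    ch <- manual_chain(rbind(c(4L, 4L, 4L), c(4L, 4L, 4L) + bv[i, ]),
                       c("M", "A"), L = 8)
    oracle_energy(ch, model)$total
  }, numeric(1))
  temp <- diff(range(E)) / 2
  cls <- apply(bv, 1, function(d) paste(sort(abs(d)), collapse = ""))
  w <- exp(-E / temp)
  p_cls <- tapply(w, cls, sum) / sum(w)

  ch <- manual_chain(rbind(c(4L, 4L, 4L), c(6L, 4L, 4L)), c("M", "A"), L = 8)
  r <- run_chain(ch, model, steps = 1e5, T = temp, seed = 17,
                 dump_interval = 50, audit_interval = 5e4)
  dvec <- t(vapply(r$frames, function(f) f[2, ] - f[1, ], integer(3)))
  obs_cls <- apply(dvec, 1, function(d) paste(sort(abs(d)), collapse = ""))
  expect_true(all(rowSums(dvec^2) %in% c(4, 5, 6, 9, 10)))
  obs <- table(factor(obs_cls, levels = names(p_cls)))
  cs <- stats::chisq.test(obs, p = as.numeric(p_cls))
  expect_gt(cs$p.value, 0.01)
})

test_that("incremental energy tracks full recomputation through long runs", {
  fx <- make_fixture("random_seq", list(n = 10), seed = 12)
  ch <- initialize_chain(fx$sequence, 1, lattice_spec(16), seed = 12)
  m <- interaction_model(fs = 3)
  r <- run_chain(ch, m, steps = 2e4, T = 0.05, seed = 12,
                 dump_interval = 2e3, audit_interval = 1e3)
  expect_lt(r$energy_drift, 1e-9)
  expect_true(r$geometry_ok)
  # the running energy at the end equals an independent recomputation
  expect_equal(r$final_energy, total_energy(r$chain, m), tolerance = 1e-9)
})

test_that("bond window and excluded volume hold over a million sweeps", {
  ch <- initialize_chain(strrep("G", 10), 1, lattice_spec(16), seed = 8)
  m <- interaction_model(fs = 0)
  r <- run_chain(ch, m, steps = 1e6, T = 0.05, seed = 8,
                 dump_interval = 1e5, audit_interval = 1e4,
                 store_frames = FALSE)
  expect_true(r$geometry_ok)       # 100 full-state audits, zero violations
  expect_lt(r$energy_drift, 1e-9)
  expect_silent(validate_chain(r$chain))
})

test_that("mobility rises with temperature", {
  fx <- make_fixture("random_seq", list(n = 14), seed = 20)
  acc <- vapply(c(0.010, 0.020, 0.040), function(T) {
    cfg <- bfm_config(T = T, fs = 0, steps = 2000, samples = 3, seed = 30,
                      dump_interval = 500, audit_interval = 1000,
                      lattice = lattice_spec(32))
    ens <- run_ensemble(fx$sequence, cfg, store_frames = FALSE)
    mean(vapply(ens$runs, function(r) {
      la <- nrow(r$accepts)
      sum(r$accepts[la, ]) / sum(r$attempts[la, ])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
})

test_that("athermal ensemble <R_g> matches the static Rosenbluth SAW oracle", {
  aa <- amino_acids()
  zero <- matrix(0, 20, 20, dimnames = list(aa, aa))
  m_zero <- interaction_model(fs = 0, contact = zero,
                              normalize_contact = FALSE)
  n <- 14L
  cfg <- bfm_config(T = 1, fs = 0, steps = 4000, samples = 8, seed = 101,
                    dump_interval = 200, audit_interval = 2000,
                    lattice = lattice_spec(32))
  ens <- run_ensemble(strrep("A", n), cfg, model = m_zero,
                      store_frames = FALSE)
  oracle <- oracle_saw_rg(n, n_walks = 800, seed = 55)
  expect_equal(ens$rg_mean, oracle, tolerance = 3 * ens$rg_se / oracle)
})
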