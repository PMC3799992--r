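test_that("contact matrix and solvent table satisfy their load-time contracts", {
  m <- mj_matrix()
  expect_equal(dim(m), c(20, 20))
  expect_identical(m, t(m))
  expect_equal(length(unique(as.vector(m[upper.tri(m, diag = TRUE)]))) <= 210,
               TRUE)
  hp <- hydropathy_table()
  expect_true(all(hp$eps_i[hp$class == "H"] > 0))
  expect_true(all(hp$eps_i[hp$class %in% c("P", "E")] < 0))
  expect_true(all(abs(hp$eps_i) <= 1))
})

test_that("engine energies match the brute-force footprint oracle", {
  for (fs in c(0, 5)) {
    model <- interaction_model(fs = fs)
    for (s in 1:3) {
      fx <- make_fixture("random_seq", list(n = 12), seed = s)
      ch <- initialize_chain(fx$sequence, 1, lattice_spec(16), seed = s)
      o <- oracle_energy(ch, model)
      expect_equal(residue_energy(ch, model), o$en, tolerance = 1e-12)
      expect_equal(total_energy(ch, model), o$total, tolerance = 1e-12)
      # sum over nodes double-counts pairs once each, solvent once
      expect_equal(sum(o$en), 2 * o$pair + o$solvent, tolerance = 1e-12)
      expect_equal(total_energy(ch, model), o$pair + o$solvent,
                   tolerance = 1e-12)
    }
  }
})

test_that("isolated nodes behave as the shell sums dictate", {
  # single free node, solvent decoupled: zero energy
  ch <- manual_chain(rbind(c(5, 5, 5)), "I", L = 16)
  expect_equal(residue_energy(ch, interaction_model(fs = 0)), 0)
  # hydrophobic node in pure solvent: strictly positive, equals the direct
  # 92-offset shell sum minus its own cube-footprint blocking
  m <- interaction_model(fs = 2)
  sh <- interaction_shell()
  own <- as.matrix(expand.grid(0:1, 0:1, 0:1))[-1, ]
  expected <- sum(pair_potential(2 * m$eps_solv["I"], rowSums(sh^2))) -
    sum(pair_potential(2 * m$eps_solv["I"], rowSums(own^2)))
  expect_gt(expected, 0)
  expect_equal(residue_energy(ch, m), expected, tolerance = 1e-12)
  # translation invariance: moving an isolated node costs nothing
  expect_equal(delta_energy(ch, 1, c(6, 5, 5), m), 0)
})

test_that("two-node energies match hand-summed values at several separations", {
  m <- interaction_model(fs = 3)
  for (bond in list(c(2, 0, 0), c(2, 1, 0), c(3, 0, 0), c(3, 1, 0))) {
    ch <- manual_chain(rbind(c(8, 8, 8), c(8, 8, 8) + bond), c("F", "K"),
                       L = 24)
    o <- oracle_energy(ch, m)
    expect_equal(residue_energy(ch, m), o$en, tolerance = 1e-12)
  }
})

test_that("incremental delta equals full recompute over many random moves", {
  model <- interaction_model(fs = 4)
  fx <- make_fixture("random_seq", list(n = 10), seed = 6)
  ch <- initialize_chain(fx$sequence, 1, lattice_spec(16), seed = 6)
  set.seed(42)
  worst <- 0
  n_checked <- 0
  for (trial in 1:400) {
    node <- sample.int(10, 1)
    pm <- propose_move(ch, node)
    if (!pm$legal) next
    dE <- delta_energy(ch, node, pm$candidate, model)
    moved <- ch$unwrapped
    moved[node, ] <- pm$candidate
    ch2 <- with_positions(ch, moved)
    dfull <- total_energy(ch2, model) - total_energy(ch, model)
    worst <- max(worst, abs(dE - dfull))
    n_checked <- n_checked + 1
    if (trial %% 3 == 0) ch <- ch2   # walk the state around
  }
  expect_gt(n_checked, 100)
  expect_lt(worst, 1e-9)
  # identity move costs nothing
  expect_equal(delta_energy(ch, 1, ch$unwrapped[1, ], model), 0)
})

test_that("energy is invariant under chain reversal, translation and the
           lattice symmetries", {
  m_solv <- interaction_model(fs = 2)
  m_dry <- interaction_model(fs = 0)
  fx <- make_fixture("random_seq", list(n = 9), seed = 8)
  ch <- initialize_chain(fx$sequence, 1, lattice_spec(32), seed = 8)
  E_solv <- total_energy(ch, m_solv)
  E_dry <- total_energy(ch, m_dry)
  # reversal
  rev_ch <- manual_chain(ch$unwrapped[9:1, ], rev(ch$node_types), L = 32)
  expect_equal(total_energy(rev_ch, m_solv), E_solv, tolerance = 1e-12)
  # translation
  sh <- with_positions(ch, sweep(ch$unwrapped, 2, c(5L, -3L, 11L), "+"))
  expect_equal(total_energy(sh, m_solv), E_solv, tolerance = 1e-12)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  for (p in perms) {
    # solvated energy: invariant under the 6 axis permutations (the solvent
    # shell is anchored at a cube corner, so reflections are not symmetries
    # of the solvated model)
    tr <- oracle_cubic_symmetry(ch$unwrapped, p, c(1, 1, 1))
    expect_equal(total_energy(with_positions(ch, tr), m_solv), E_solv,
                 tolerance = 1e-12)
    # unsolvated pair energy: invariant under the full 48-op point group
    for (i in seq_len(nrow(signs))) {
      tr <- oracle_cubic_symmetry(ch$unwrapped, p, signs[i, ])
      expect_equal(total_energy(with_positions(ch, tr), m_dry), E_dry,
                   tolerance = 1e-12)
    }
  }
})

test_that("fs = 0 reduces exactly to the unsolvated model", {
  fx <- make_fixture("random_seq", list(n = 10), seed = 5)
  ch <- initialize_chain(fx$sequence, 1, lattice_spec(16), seed = 5)
  m0 <- interaction_model(fs = 0)
  o <- oracle_energy(ch, m0)
  expect_equal(o$solvent, 0)
  expect_equal(total_energy(ch, m0), o$pair, tolerance = 1e-12)
})

test_that("metropolis acceptance follows the Boltzmann rule", {
  expect_true(all(metropolis_accept(rep(-1, 50), T = 0.01)))
  set.seed(1)
  # dE = T: acceptance converges to exp(-1)
  acc <- mean(metropolis_accept(rep(0.02, 1e5), T = 0.02))
  expect_equal(acc, exp(-1), tolerance = 0.015)
  set.seed(2)
  expect_lt(mean(metropolis_accept(rep(1, 2000), T = 0.01)), 1e-3)
})
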