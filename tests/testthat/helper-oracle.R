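# Independent brute-force oracles, deliberately implemented with none of the
# engine's incremental machinery: explicit cube-footprint occupancy sets,
# direct shell sums, minimum-image arithmetic in plain R.

oracle_min_image <- function(d, L) {
  d <- d %% L
  d[d > L / 2] <- d[d > L / 2] - L
  d
}

# total energy, per-node energies and the pair/solvent split
oracle_energy <- function(chain, model) {
  L <- chain$L
  pos <- chain$positions %% L
  N <- nrow(pos)
  types <- chain$node_types
  fs <- model$fs
  esolv <- model$eps_solv
  occ <- new.env(hash = TRUE)
  dlt <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (k in seq_len(N)) {
    sites <- sweep(dlt, 2, pos[k, ], "+") %% L
    for (s in paste(sites[, 1], sites[, 2], sites[, 3]))
      assign(s, TRUE, envir = occ)
  }
  shell <- interaction_shell()
  shell_r2 <- rowSums(shell^2)
  en <- numeric(N)
  pair_tot <- 0
  solv_tot <- 0
  for (n in seq_len(N)) {
    e_pair <- 0
    for (j in seq_len(N)) {
      if (j == n || abs(j - n) == 1) next
      d <- oracle_min_image(pos[j, ] - pos[n, ], L)
      r2 <- sum(d^2)
      if (r2 <= 8)
        e_pair <- e_pair + pair_potential(model$contact[types[n], types[j]], r2)
    }
    e_solv <- 0
    for (s in seq_len(nrow(shell))) {
      site <- (pos[n, ] + shell[s, ]) %% L
      if (!exists(paste(site[1], site[2], site[3]), envir = occ))
        e_solv <- e_solv + pair_potential(fs * esolv[types[n]], shell_r2[s])
    }
    pair_tot <- pair_tot + e_pair
    solv_tot <- solv_tot + e_solv
    en[n] <- e_pair + e_solv
  }
  list(en = en, pair = pair_tot / 2, solvent = solv_tot,
       total = pair_tot / 2 + solv_tot)
}

# move legality by exhaustive definition: bond window on adjacent bonds plus
# pairwise Chebyshev >= 2 against every other node
oracle_move_legal <- function(chain, node, cand_unwrapped) {
  L <- chain$L
  pos <- chain$positions
  cand <- cand_unwrapped %% L
  for (j in seq_len(nrow(pos))) {
    if (j == node) next
    d <- abs(oracle_min_image(pos[j, ] - cand, L))
    if (max(d) < 2) return(FALSE)
  }
  for (j in c(node - 1L, node + 1L)) {
    if (j < 1 || j > nrow(pos)) next
    d <- chain$unwrapped[j, ] - cand_unwrapped
    if (!validate_bond(d)) return(FALSE)
  }
  TRUE
}

# apply one of the 48 cubic point-group operations to unwrapped coordinates
oracle_cubic_symmetry <- function(pos, perm, signs) {
  sweep(pos[, perm, drop = FALSE], 2, signs, "*")
}

# replace a chain's coordinates (recomputing wrapped from unwrapped)
with_positions <- function(chain, unwrapped) {
  chain$unwrapped <- unwrapped
  chain$positions <- unwrapped %% chain$L
  chain
}

# Rosenbluth-weighted static sampler of the uniform self-avoiding ensemble
# with the bond-fluctuation move set: unbiased <R_g> oracle for the athermal
# equilibrium chain.
oracle_saw_rg <- function(n_nodes, n_walks, L = 32L, seed = 1L) {
  set.seed(seed)
  bv <- bond_vectors()
  rg <- w <- numeric(0)
  for (walk in seq_len(n_walks)) {
    pos <- matrix(0L, n_nodes, 3)
    weight <- 1
    dead <- FALSE
    for (k in 2:n_nodes) {
      cand <- sweep(bv, 2, pos[k - 1, ], "+")
      legal <- vapply(seq_len(nrow(cand)), function(i) {
        d <- abs(sweep(pos[1:(k - 1), , drop = FALSE], 2, cand[i, ]))
        all(apply(d, 1, max) >= 2)
      }, logical(1))
      nl <- sum(legal)
      if (nl == 0L) { dead <- TRUE; break }
      weight <- weight * nl
      pick <- which(legal)[sample.int(nl, 1L)]
      pos[k, ] <- cand[pick, ]
    }
    if (dead) next
    rg <- c(rg, radius_of_gyration(pos))
    w <- c(w, weight)
  }
  sum(w * rg) / sum(w)
}

# small deterministic chain states built by hand (wrapped == unwrapped)
manual_chain <- function(unwrapped, types, L = 32L) {
  unwrapped <- as.matrix(unwrapped)
  storage.mode(unwrapped) <- "integer"
  gm <- list(node_types = types,
             node_residue = seq_along(types),
             residue_nodes = as.list(seq_along(types)),
             grain = 1L)
  bfmsim:::new_bfm_chain(unwrapped %% L, unwrapped, gm,
                         paste(types, collapse = ""), L)
}
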