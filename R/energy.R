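#' Per-node interaction energies
#'
#' Energy of each node with everything inside the interaction range:
#' non-bonded chain nodes within \eqn{r_c} (contact-matrix couplings,
#' covalently bonded neighbours excluded) plus all empty lattice sites within
#' \eqn{r_c} (solvent coupling \eqn{f_s \epsilon_i}).  Distances use the
#' minimum image.  Summing over nodes counts each residue-residue pair twice
#' and each solvent term once.
#'
#' @param chain A `bfm_chain`.
#' @param model A `bfm_model`.
#' @param node Optional single node index (1-based) to return just that
#'   node's energy.
#' @return Numeric vector of node energies (or a single value).
#' @export
residue_energy <- function(chain, model, node = NULL) {
  arr <- .model_arrays(model)
  en <- cpp_node_energies(chain$L, .type_index(chain$node_types),
                          chain$positions, arr$epsPair, arr$epsSolv,
                          model$fs)
  if (is.null(node)) en else en[node]
}

#' Total system energy
#'
#' Residue-residue pair energies (each pair once) plus all residue-solvent
#' shell terms.
#' @inheritParams residue_energy
#' @return Single numeric value.
#' @export
total_energy <- function(chain, model) {
  arr <- .model_arrays(model)
  cpp_total_energy(chain$L, .type_index(chain$node_types), chain$positions,
                   arr$epsPair, arr$epsSolv, model$fs)
}

#' Incremental energy difference of a single-node move
#'
#' The total-system energy change if `node` moved to `candidate`, computed
#' incrementally from the terms involving the moving node and the
#' solvent-occupancy changes of its cube footprint -- the same path the
#' Metropolis engine uses.  Equals the full-recompute difference to within
#' round-off.
#'
#' @inheritParams residue_energy
#' @param node Node index (1-based).
#' @param candidate Integer triple (unwrapped or wrapped coordinates).
#' @return Single numeric value.
#' @export
delta_energy <- function(chain, node, candidate, model) {
  arr <- .model_arrays(model)
  cpp_delta_energy(chain$L, .type_index(chain$node_types), chain$positions,
                   node - 1L, as.integer(candidate %% chain$L),
                   arr$epsPair, arr$epsSolv, model$fs)
}

#' Metropolis acceptance
#'
#' Accepts a move of energy difference `dE` with probability
#' \eqn{\min(1, e^{-\Delta E / T})}, drawing from R's RNG.
#'
#' @param dE Energy difference(s).
#' @param T Temperature in reduced units (> 0).
#' @return Logical vector of verdicts.
#' @export
metropolis_accept <- function(dE, T) {
  stopifnot(T > 0)
  dE <= 0 | stats::runif(length(dE)) < exp(-dE / T)
}
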