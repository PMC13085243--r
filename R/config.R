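#' Run configuration and hyperparameters
#'
#' Collects the reward weights, PPO hyperparameters, generation budget and
#' architecture knobs of a run. Defaults follow the study conditions where
#' stated (token budget 6, 3000 epochs, entropy-regularized PPO) and
#' standard PPO practice elsewhere; every value is a knob.
#'
#' @param alpha,beta Non-negative weights of the chemical and diversity
#'   rewards in the total reward.
#' @param gamma Discount factor in (0, 1].
#' @param epsilon PPO clip width (> 0).
#' @param c_e Entropy-bonus weight.
#' @param K Top-K memory capacity.
#' @param n_div Trailing batch size for the diversity reward.
#' @param L Maximum number of P-SMILES tokens per state.
#' @param epochs Training epochs.
#' @param episodes_per_epoch Episodes generated per epoch.
#' @param batch_size Trajectories per PPO update batch.
#' @param ppo_epochs Gradient passes per sampled batch.
#' @param lr Adam learning rate.
#' @param d_model,n_layers,n_heads Transformer width, depth and head count.
#' @param mode Which isomerization gap is maximized: \code{"EZ"} (E_Z - E_E),
#'   \code{"trans_cis"} (E_cis - E_trans) or \code{"cis_trans"}
#'   (E_trans - E_cis).
#' @param constraint \code{"none"} or \code{"R2_H"}: with \code{"R2_H"},
#'   generations whose beta carbon carries a second substituent are
#'   invalidated after the fact (the space of combinations is unchanged,
#'   only the density of valid states drops).
#' @param fidelity Energy fidelity: \code{"toy"} or \code{"forcefield"}
#'   (tight-binding and external engines attach through adapters).
#' @param seed Integer seed for all run randomness.
#' @param empty_fp_similarity Similarity assigned when two fingerprints are
#'   both empty (boundary convention; default 1).
#' @return A list of class \code{psrl_config}.
#' @export
psrl_config <- function(alpha = 1, beta = 1, gamma = 0.99, epsilon = 0.2,
                        c_e = 0.01, K = 10L, n_div = 10L, L = 6L,
                        epochs = 3000L, episodes_per_epoch = 10L,
                        batch_size = 32L, ppo_epochs = 4L, lr = 3e-4,
                        d_model = 64L, n_layers = 2L, n_heads = 4L,
                        mode = c("EZ", "trans_cis", "cis_trans"),
                        constraint = c("none", "R2_H"),
                        fidelity = c("toy", "forcefield"),
                        seed = 1L, empty_fp_similarity = 1) {
  mode <- match.arg(mode)
  constraint <- match.arg(constraint)
  fidelity <- match.arg(fidelity)
  stopifnot(alpha >= 0, beta >= 0, gamma > 0, gamma <= 1, epsilon > 0,
            K >= 1, n_div >= 1, L >= 1, d_model %% n_heads == 0)
  structure(list(
    alpha = alpha, beta = beta, gamma = gamma, epsilon = epsilon, c_e = c_e,
    K = as.integer(K), n_div = as.integer(n_div), L = as.integer(L),
    epochs = as.integer(epochs),
    episodes_per_epoch = as.integer(episodes_per_epoch),
    batch_size = as.integer(batch_size), ppo_epochs = as.integer(ppo_epochs),
    lr = lr, d_model = as.integer(d_model), n_layers = as.integer(n_layers),
    n_heads = as.integer(n_heads), mode = mode, constraint = constraint,
    fidelity = fidelity, seed = as.integer(seed),
    empty_fp_similarity = empty_fp_similarity
  ), class = "psrl_config")
}

#' @export
print.psrl_config <- function(x, ...) {
  cat("<psrl_config> mode:", x$mode, " L:", x$L, " fidelity:", x$fidelity,
      "\n  alpha:", x$alpha, " beta:", x$beta, " gamma:", x$gamma,
      " eps:", x$epsilon, " c_e:", x$c_e, "\n  K:", x$K, " n_div:", x$n_div,
      " epochs:", x$epochs, "x", x$episodes_per_epoch, "episodes\n")
  invisible(x)
}

#' Read a run configuration from a YAML file
#' @param path Path to a YAML file whose keys match [psrl_config()] arguments.
#' @return A \code{psrl_config}.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(psrl_config, vals)
}
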