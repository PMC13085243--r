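# Rewards: the isomerization-energy chemical reward (with its validity
# cascade and cache), the Tanimoto-complement diversity reward, the piecewise
# total reward, discount-based reward normalization and the top-K memory.

#' Isomerization energy gap
#'
#' Signed energy difference between geometrical isomers, in the convention
#' of the selected task: \code{EZ} returns \eqn{E_Z - E_E};
#' \code{cis_trans} returns \eqn{E_{trans} - E_{cis}}; \code{trans_cis}
#' returns \eqn{E_{cis} - E_{trans}}.
#'
#' @param e_first Energy (kcal/mol) of the E (equivalently trans) isomer.
#' @param e_second Energy of the Z (equivalently cis) isomer.
#' @param mode \code{"EZ"}, \code{"cis_trans"} or \code{"trans_cis"}.
#' @return The gap in kcal/mol.
#' @examples
#' isomerization_gap(-18, -10, "EZ")   # 8
#' @export
isomerization_gap <- function(e_first, e_second,
                              mode = c("EZ", "cis_trans", "trans_cis")) {
  mode <- match.arg(mode)
  stopifnot(is.finite(e_first), is.finite(e_second))
  switch(mode,
         EZ = e_second - e_first,
         cis_trans = e_first - e_second,   # E_trans - E_cis
         trans_cis = e_second - e_first)   # E_cis - E_trans
}

#' Tanimoto similarity of two bit sets
#'
#' \eqn{S(a,b) = |a \cap b| / |a \cup b|} over fingerprint bit sets.
#'
#' @param a,b Integer vectors of set bit positions.
#' @param empty_similarity Value returned when both sets are empty
#'   (identical absence of features; default 1, configurable).
#' @return Similarity in [0, 1].
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4))   # 0.5
#' @export
tanimoto <- function(a, b, empty_similarity = 1) {
  u <- length(union(a, b))
  if (u == 0) return(empty_similarity)
  length(intersect(a, b)) / u
}

#' Diversity reward
#'
#' One minus the maximum Tanimoto similarity between a state's fingerprint
#' and the fingerprints of the trailing batch of previously generated valid
#' molecules. An empty reference batch yields 1 (no reference means maximal
#' novelty).
#'
#' @param fp Fingerprint bit set of the current state.
#' @param batch_fps List of fingerprint bit sets (the last n valid
#'   generations).
#' @param empty_similarity Passed to [tanimoto()].
#' @return Reward in [0, 1].
#' @export
diversity_reward <- function(fp, batch_fps, empty_similarity = 1) {
  if (!length(batch_fps)) return(1)
  1 - max(vapply(batch_fps, tanimoto, numeric(1), a = fp,
                 empty_similarity = empty_similarity))
}

#' Piecewise total reward
#'
#' The shared reward of all policies: -1 when the episode terminates empty
#' (T = 0) or over budget (T > L); 0 at non-terminal steps and for invalid
#' terminal states; \eqn{\alpha r_c + \beta r_d} for valid terminal states
#' (each term passed through its normalizer when scalers are supplied).
#'
#' @param t Current step; \code{T} the terminal step; \code{L} the token
#'   budget.
#' @param T Terminal step index.
#' @param L Maximum token budget.
#' @param valid Validity of the terminal state.
#' @param r_c,r_d Raw chemical and diversity rewards (ignored unless valid
#'   terminal).
#' @param hp A [psrl_config()] (for \code{alpha}, \code{beta}).
#' @param scaler_c,scaler_d Optional [reward_scaler()]s applied to r_c, r_d.
#' @return The scalar total reward.
#' @export
total_reward <- function(t, T, L, valid = FALSE, r_c = NA_real_,
                         r_d = NA_real_, hp = psrl_config(),
                         scaler_c = NULL, scaler_d = NULL) {
  stopifnot(t <= T)
  if (t == T && (T == 0 || T > L)) return(-1)
  if (t < T || !valid) return(0)
  rc <- if (!is.null(scaler_c)) scaler_c$scale(r_c) else r_c
  rd <- if (!is.null(scaler_d)) scaler_d$scale(r_d) else r_d
  hp$alpha * rc + hp$beta * rd
}

#' Discount-based reward normalization
#'
#' Online scaler after the discount-based reward scaling scheme: a running
#' discounted accumulator \eqn{R \leftarrow \gamma R + r} feeds a running
#' variance estimate, and each raw reward is divided by the accumulator's
#' standard deviation (no mean subtraction of the reward itself). The first
#' samples are scaled by the guard \eqn{\max(\sigma, 10^{-8})}, a documented
#' warm-up behaviour.
#'
#' @param gamma Discount factor of the accumulator.
#' @param eps Lower guard on the standard deviation.
#' @return An object with methods \code{$scale(r)} (update then scale) and
#'   \code{$sd()}.
#' @export
reward_scaler <- function(gamma = 0.99, eps = 1e-8) {
  env <- new.env(parent = emptyenv())
  env$acc <- 0; env$n <- 0; env$mean <- 0; env$m2 <- 0
  scale <- function(r) {
    env$acc <- gamma * env$acc + r
    env$n <- env$n + 1
    delta <- env$acc - env$mean
    env$mean <- env$mean + delta / env$n
    env$m2 <- env$m2 + delta * (env$acc - env$mean)
    r / max(sqrt(env$m2 / env$n), eps)
  }
  sd_fun <- function() sqrt(env$m2 / max(env$n, 1))
  structure(list(scale = scale, sd = sd_fun, env = env),
            class = "reward_scaler")
}

# ---------------------------------------------------------------------------
# Top-K memory

#' Top-K memory of the best states
#'
#' Keeps the K best-rewarded unique states found so far (unique by the
#' canonical-SMILES cache key; a duplicate keeps its better score). The
#' minimum entry is evicted first.
#'
#' @param K Capacity.
#' @return A \code{topk_memory} object (environment-backed).
#' @export
topk_memory <- function(K = 10L) {
  env <- new.env(parent = emptyenv())
  env$K <- as.integer(K)
  env$df <- data.frame(key = character(0), state = character(0),
                       r_t = numeric(0), stringsAsFactors = FALSE)
  structure(list(env = env), class = "topk_memory")
}

#' @export
print.topk_memory <- function(x, ...) {
  cat("<topk_memory>", nrow(x$env$df), "/", x$env$K, "entries\n")
  if (nrow(x$env$df)) print(utils::head(x$env$df, 5))
  invisible(x)
}

#' Insert a state into the top-K memory
#'
#' Inserts when capacity is unused or the score beats the current minimum;
#' dedupes by key keeping the better score. The resulting memory always
#' equals sort-descending-and-truncate of the best score per unique state.
#'
#' @param memory A [topk_memory()].
#' @param state State text.
#' @param r_t Its total reward.
#' @param key Deduplication key (canonical SMILES pair; defaults to the
#'   state text).
#' @return The memory, invisibly (it is updated in place).
#' @export
topk_update <- function(memory, state, r_t, key = state) {
  df <- memory$env$df
  hit <- match(key, df$key)
  if (!is.na(hit)) {
    if (r_t > df$r_t[hit]) df$r_t[hit] <- r_t
  } else if (nrow(df) < memory$env$K) {
    df <- rbind(df, data.frame(key = key, state = state, r_t = r_t,
                               stringsAsFactors = FALSE))
  } else if (r_t > min(df$r_t)) {
    df <- df[-which.min(df$r_t), ]
    df <- rbind(df, data.frame(key = key, state = state, r_t = r_t,
                               stringsAsFactors = FALSE))
  }
  memory$env$df <- df[order(-df$r_t), ]
  invisible(memory)
}

#' Membership test on the top-K memory
#' @param memory A [topk_memory()].
#' @param key Deduplication key.
#' @return \code{TRUE} when a state with this key is held.
#' @export
topk_member <- function(memory, key) key %in% memory$env$df$key

# ---------------------------------------------------------------------------
# Chemical reward cascade

#' Reward cache
#' @return An environment-backed cache keyed by canonical SMILES pair.
#' @export
reward_cache <- function() {
  env <- new.env(parent = emptyenv())
  env$hits <- 0L; env$engine_calls <- 0L
  structure(list(env = env), class = "reward_cache")
}

#' Chemical reward of a state
#'
#' Runs the validity-and-energy routine for both isomers of a state and
#' computes the isomerization gap. Stages, in order: well-formedness
#' (\code{syntax}), decodability under the grammar (\code{decode}),
#' distinctness of the isomer pair (\code{isomer_identity}), the optional
#' single-substituent constraint (\code{constraint}), the heteroatom chain
#' filter (\code{heteroatom_chain}), valence sanity (\code{valence}),
#' closed-shell parity (\code{closed_shell}), then the energy stages of the
#' selected fidelity (for \code{toy}: a direct graph evaluation; for
#' \code{forcefield}: 3D embedding with MMFF94 pre-optimization,
#' connectivity preservation, energy evaluation and the InChIKey identity
#' round-trip). Any failing stage short-circuits the rest. Results are
#' cached by the canonical SMILES pair: a state already scored is returned
#' with \code{cached = TRUE} and zero engine calls.
#'
#' @param state A \code{psmiles_state} or character scalar.
#' @param scaffold A [scaffold_styrene()].
#' @param engine An [energy_engine()] (its fidelity selects the pipeline).
#' @param cache A [reward_cache()] (optional but recommended).
#' @param hp A [psrl_config()] (mode and constraint).
#' @return A \code{reward_breakdown} list: \code{r_c}, \code{valid},
#'   \code{failure_stage} (\code{NA} when valid), \code{cached},
#'   \code{key}, \code{e_smiles}, \code{z_smiles}, \code{energies}.
#' @export
chemical_reward <- function(state, scaffold = scaffold_styrene(),
                            engine = toy_engine(), cache = NULL,
                            hp = psrl_config()) {
  if (is.character(state)) state <- tokenize(state)
  out <- function(valid, stage = NA_character_, r_c = NA_real_,
                  key = NA_character_, e = NA_character_, z = NA_character_,
                  energies = c(NA_real_, NA_real_), cached = FALSE) {
    structure(list(r_c = r_c, valid = valid, failure_stage = stage,
                   cached = cached, key = key, e_smiles = e, z_smiles = z,
                   energies = energies, state = state$text),
              class = "reward_breakdown")
  }
  if (!is_well_formed(state)) return(out(FALSE, "syntax"))
  dec <- tryCatch(decode_to_smiles(state, scaffold),
                  error = function(e) NULL)
  if (is.null(dec)) return(out(FALSE, "decode"))
  can_e <- tryCatch(canonical_smiles(dec$e), error = function(e) NA_character_)
  can_z <- tryCatch(canonical_smiles(dec$z), error = function(e) NA_character_)
  if (is.na(can_e) || is.na(can_z)) return(out(FALSE, "decode"))
  key <- paste(can_e, can_z, sep = "||")
  if (!is.null(cache) && !is.null(cache$env[[key]])) {
    cache$env$hits <- cache$env$hits + 1L
    res <- cache$env[[key]]
    res$cached <- TRUE
    res$state <- state$text
    return(res)
  }
  run <- function() {
    if (!dec$stereo || identical(can_e, can_z))
      return(out(FALSE, "isomer_identity", key = key, e = can_e, z = can_z))
    if (hp$constraint == "R2_H" && length(dec$sub_roots) > 1L)
      return(out(FALSE, "constraint", key = key, e = can_e, z = can_z))
    if (!heteroatom_chain_filter(dec$graph))
      return(out(FALSE, "heteroatom_chain", key = key, e = can_e, z = can_z))
    if (!valence_sanity(dec$graph))
      return(out(FALSE, "valence", key = key, e = can_e, z = can_z))
    if (!is_closed_shell(mol_composition(dec$graph)))
      return(out(FALSE, "closed_shell", key = key, e = can_e, z = can_z))
    if (engine$fidelity == "toy") {
      ctx <- isomer_contexts(dec)
      if (!is.null(cache)) cache$env$engine_calls <- cache$env$engine_calls + 2L
      e_E <- engine$evaluate(ctx$E); e_Z <- engine$evaluate(ctx$Z)
    } else {
      geoms <- list()
      for (iso in c("e", "z")) {
        g <- tryCatch(embed_and_preoptimize(dec[[iso]]),
                      error = function(e) NULL)
        if (is.null(g))
          return(out(FALSE, "embed", key = key, e = can_e, z = can_z))
        ref <- with_explicit_hydrogens(dec$graph)
        per <- tryCatch(perceive_graph(g), error = function(e) NULL)
        if (is.null(per) || !connectivity_preserved(ref, per))
          return(out(FALSE, "connectivity", key = key, e = can_e, z = can_z))
        geoms[[iso]] <- g
      }
      if (!is.null(cache)) cache$env$engine_calls <- cache$env$engine_calls + 2L
      e_E <- tryCatch(engine$evaluate(geoms$e), error = function(e) NA_real_)
      e_Z <- tryCatch(engine$evaluate(geoms$z), error = function(e) NA_real_)
      if (is.na(e_E) || is.na(e_Z))
        return(out(FALSE, "energy", key = key, e = can_e, z = can_z))
      ok <- tryCatch(identity_roundtrip(dec$e, geoms$e) &&
                     identity_roundtrip(dec$z, geoms$z),
                     error = function(e) FALSE)
      if (!ok)
        return(out(FALSE, "identity_roundtrip", key = key,
                   e = can_e, z = can_z))
    }
    gap <- isomerization_gap(e_E, e_Z, hp$mode)
    out(TRUE, NA_character_, r_c = gap, key = key, e = can_e, z = can_z,
        energies = c(E = e_E, Z = e_Z))
  }
  res <- run()
  if (!is.null(cache)) cache$env[[key]] <- res
  res
}

#' @export
print.reward_breakdown <- function(x, ...) {
  if (x$valid)
    cat("<reward_breakdown> valid, r_c =", format(x$r_c), "kcal/mol",
        if (x$cached) "(cached)", "\n")
  else
    cat("<reward_breakdown> invalid at stage:", x$failure_stage, "\n")
  invisible(x)
}
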