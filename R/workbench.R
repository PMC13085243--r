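# Reproducibility harness: full characterization of bounded spaces with a
# chosen engine, the random-search baseline, and the agent-vs-random
# comparison on spaces whose exact optimum is known.

#' Characterize a bounded chemical space
#'
#' Scores every state of the bounded space through the full validity
#' cascade with the given engine and reports the census (total, well-formed,
#' grammar-valid, chemically valid), the full gap distribution over valid
#' states, and the argmax. Unique molecules are counted by the canonical
#' SMILES pair of the decoded isomers (the reward-cache key). Deterministic
#' and independent of enumeration order.
#'
#' @param max_tokens Token budget of the space.
#' @param engine An [energy_engine()] (graph fidelities only).
#' @param hp A [psrl_config()] (mode and constraint are honoured; the
#'   \code{R2_H} constraint reduces the valid count, never the total).
#' @param scaffold A [scaffold_styrene()].
#' @param cap Enumeration budget (see [enumerate_space()]).
#' @return A list of class \code{space_characterization}: \code{counts},
#'   \code{records} (data.frame per state), \code{molecules} (data.frame
#'   per unique molecule with \code{key}, \code{r_c}), \code{argmax}
#'   (best unique molecule row), \code{argmax_unique} (is the best r_c
#'   attained by a single molecule?).
#' @export
characterize_space <- function(max_tokens, engine = toy_engine(),
                               hp = psrl_config(L = max_tokens),
                               scaffold = scaffold_styrene(), cap = 2e6) {
  sp <- enumerate_space(max_tokens = max_tokens, validity = "syntax",
                        cap = cap)
  cache <- reward_cache()
  n <- nrow(sp)
  valid <- logical(n); r_c <- rep(NA_real_, n)
  stage <- character(n); key <- rep(NA_character_, n)
  wf <- logical(n)
  for (k in seq_len(n)) {
    st <- sp$state[k]
    wf[k] <- is_well_formed(st)
    rb <- chemical_reward(st, scaffold, engine, cache, hp)
    valid[k] <- rb$valid
    r_c[k] <- rb$r_c
    stage[k] <- if (is.na(rb$failure_stage)) "valid" else rb$failure_stage
    key[k] <- rb$key
  }
  records <- data.frame(state = sp$state, token_count = sp$token_count,
                        well_formed = wf,
                        syntactic_valid = sp$syntactic_valid,
                        valid = valid, r_c = r_c, stage = stage, key = key,
                        stringsAsFactors = FALSE)
  vrec <- records[records$valid, ]
  mols <- do.call(rbind, lapply(split(vrec, vrec$key), function(d)
    data.frame(key = d$key[1L], state = d$state[1L], r_c = d$r_c[1L],
               n_states = nrow(d), stringsAsFactors = FALSE)))
  rownames(mols) <- NULL
  arg <- if (!is.null(mols) && nrow(mols)) mols[which.max(mols$r_c), ] else NULL
  counts <- c(total = attr(sp, "total"),
              well_formed = sum(wf),
              syntactic_valid = sum(sp$syntactic_valid),
              chemically_valid = sum(valid),
              unique_molecules = if (is.null(mols)) 0L else nrow(mols))
  structure(list(counts = counts, records = records, molecules = mols,
                 argmax = arg,
                 argmax_unique = !is.null(arg) &&
                   sum(abs(mols$r_c - arg$r_c) < 1e-12) == 1L,
                 max_tokens = max_tokens, mode = hp$mode,
                 constraint = hp$constraint),
            class = "space_characterization")
}

#' @export
print.space_characterization <- function(x, ...) {
  cat("<space_characterization> L =", x$max_tokens, " mode:", x$mode, "\n")
  print(x$counts)
  if (!is.null(x$argmax))
    cat("argmax: \"", x$argmax$state, "\" r_c = ",
        format(x$argmax$r_c, digits = 6),
        if (x$argmax_unique) " (unique)" else " (tied)", "\n", sep = "")
  invisible(x)
}

#' Random-search baseline
#'
#' Expected number of valid generations before sampling the best solution
#' when drawing the valid states in uniformly random order without
#' repetition: the reporting convention \code{"paper_half"} returns
#' \eqn{\lfloor n/2 \rfloor} (half of the total solutions); the exact mean
#' rank of one marked item in a random permutation,
#' \code{"exact_expectation"}, is \eqn{(n+1)/2}.
#'
#' @param valid_count Number of valid states in the space (>= 1).
#' @param mode \code{"paper_half"} or \code{"exact_expectation"}.
#' @return Expected number of draws.
#' @examples
#' random_search_baseline(134)    # 67
#' random_search_baseline(1628)   # 814
#' @export
random_search_baseline <- function(valid_count,
                                   mode = c("paper_half",
                                            "exact_expectation")) {
  mode <- match.arg(mode)
  stopifnot(valid_count >= 1)
  if (valid_count == 1) return(1)
  switch(mode,
         paper_half = floor(valid_count / 2),
         exact_expectation = (valid_count + 1) / 2)
}

#' Compare the RL agent with the random-search baseline
#'
#' Characterizes a bounded toy space, then runs independent seeded
#' trainings counting the unique valid molecules generated before the
#' known space optimum first appears, and reports mean and standard
#' deviation against the random-search baseline.
#'
#' @param space A [characterize_space()] result (the argmax must exist).
#' @param config A [psrl_config()] template; its seed is replaced by each
#'   entry of \code{seeds}.
#' @param seeds Integer vector (>= 3 replicas recommended).
#' @param engine Engine used for scoring during training.
#' @return A list of class \code{search_comparison}: per-seed unique-valid
#'   draw counts (\code{NA} when the optimum was not found within the
#'   epoch budget), their mean/sd, and both baselines.
#' @export
compare_search <- function(space, config, seeds = 1:3,
                           engine = toy_engine()) {
  stopifnot(inherits(space, "space_characterization"),
            !is.null(space$argmax))
  draws <- integer(0); fits <- list()
  for (s in seeds) {
    cfg <- config
    cfg$seed <- as.integer(s)
    fit <- psrl_train(cfg, engine = engine, target_key = space$argmax$key)
    draws <- c(draws, fit$target_hit)
    fits[[as.character(s)]] <- fit
  }
  found <- !is.na(draws)
  structure(list(
    draws = draws, seeds = seeds, found = found,
    mean_draws = if (any(found)) mean(draws[found]) else NA_real_,
    sd_draws = if (sum(found) > 1) stats::sd(draws[found]) else NA_real_,
    baseline_half = random_search_baseline(space$counts[["unique_molecules"]],
                                           "paper_half"),
    baseline_exact = random_search_baseline(space$counts[["unique_molecules"]],
                                            "exact_expectation"),
    valid_count = space$counts[["unique_molecules"]],
    argmax = space$argmax, fits = fits
  ), class = "search_comparison")
}

#' @export
print.search_comparison <- function(x, ...) {
  cat("<search_comparison> optimum \"", x$argmax$state, "\"\n", sep = "")
  cat("  unique valid draws per seed:", paste(x$draws, collapse = ", "), "\n")
  cat("  mean ", format(x$mean_draws, digits = 4), " +/- ",
      format(x$sd_draws, digits = 3), " vs random-search baseline ",
      x$baseline_half, " (exact ", format(x$baseline_exact, digits = 4),
      ")\n", sep = "")
  invisible(x)
}

#' Write an enumeration or characterization report
#'
#' Tab-separated per-state table plus a JSON summary of the census.
#'
#' @param x A \code{space_characterization} or \code{space_enumeration}.
#' @param file Path of the TSV to write; the JSON summary goes to
#'   \code{paste0(file, ".json")}.
#' @return \code{file}, invisibly.
#' @export
write_space_report <- function(x, file) {
  if (inherits(x, "space_characterization")) {
    utils::write.table(x$records, file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    jsonlite::write_json(
      list(counts = as.list(x$counts),
           argmax = if (!is.null(x$argmax)) as.list(x$argmax) else NULL,
           max_tokens = x$max_tokens, mode = x$mode),
      paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(x, file, sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(total = attr(x, "total"), valid = sum(x$syntactic_valid),
           max_tokens = attr(x, "max_tokens")),
      paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
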