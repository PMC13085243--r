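# Isomerization gaps, diversity, total reward, normalization, top-K memory
# and the cached chemical-reward cascade.

test_that("isomerization gap follows the task convention", {
  expect_equal(isomerization_gap(-18, -10, "EZ"), 8)
  expect_equal(isomerization_gap(3, 3, "trans_cis"), 0)
  set.seed(1)
  for (k in 1:20) {
    e1 <- rnorm(1); e2 <- rnorm(1)
    expect_equal(isomerization_gap(e1, e2, "cis_trans"),
                 -isomerization_gap(e1, e2, "trans_cis"))
  }
})

test_that("tanimoto similarity over bit sets", {
  expect_equal(tanimoto(c(1, 5, 9), c(1, 5, 9)), 1)
  expect_equal(tanimoto(1:3, 4:6), 0)
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto(integer(0), integer(0)), 1)
  expect_equal(tanimoto(integer(0), integer(0), empty_similarity = 0), 0)
})

test_that("diversity reward is the Tanimoto complement over the batch", {
  fp <- c(1, 2, 3)
  expect_equal(diversity_reward(fp, list(fp)), 0)
  expect_equal(diversity_reward(fp, list()), 1)
  expect_equal(diversity_reward(fp, list(c(2, 3, 4))), 0.5)
  expect_equal(diversity_reward(fp, list(c(2, 3, 4), fp)), 0)
  r <- diversity_reward(structural_keys("C"),
                        list(structural_keys("CC"), structural_keys("F")))
  expect_true(r >= 0 && r <= 1)
})

test_that("total reward covers every branch of the piecewise definition", {
  hp <- psrl_config(alpha = 1, beta = 0)
  expect_equal(total_reward(0, 0, 6, FALSE, hp = hp), -1)          # empty end
  expect_equal(total_reward(7, 7, 6, TRUE, 1, 1, hp), -1)          # over budget
  expect_equal(total_reward(2, 5, 6, TRUE, 1, 1, hp), 0)           # non-terminal
  expect_equal(total_reward(5, 5, 6, FALSE, hp = hp), 0)           # invalid end
  expect_equal(total_reward(5, 5, 6, TRUE, 2.5, 0.9, hp), 2.5)     # alpha only
  hp2 <- psrl_config(alpha = 2, beta = 3)
  expect_equal(total_reward(4, 4, 6, TRUE, 1.5, 0.5, hp2), 2 * 1.5 + 3 * 0.5)
})

test_that("reward normalization scales by the discounted-return sd", {
  sc <- reward_scaler(gamma = 0)
  # degenerate variance warm-up: guard keeps the output finite but large
  first <- sc$scale(3)
  expect_true(is.finite(first) && abs(first) > 1e6)
  # after many iid samples the scale approaches the accumulator sd
  set.seed(11)
  gamma <- 0.9
  sc2 <- reward_scaler(gamma = gamma)
  r <- rnorm(1e4, 0, 2)
  out <- vapply(r, sc2$scale, numeric(1))
  # closed form: Var of the AR(1) accumulator = sigma^2 / (1 - gamma^2)
  expect_equal(sc2$sd(), 2 / sqrt(1 - gamma^2), tolerance = 0.05)
  expect_equal(stats::sd(utils::tail(out, 1000)),
               2 / (2 / sqrt(1 - gamma^2)), tolerance = 0.1)
  # magnitude is invariant to a sign flip of the stream
  sc3 <- reward_scaler(gamma = gamma)
  out3 <- vapply(-r, sc3$scale, numeric(1))
  expect_equal(abs(out3), abs(out), tolerance = 1e-8)
})

test_that("top-K memory equals sort-and-truncate under any insertion order", {
  mem <- topk_memory(2)
  topk_update(mem, "a", 1); topk_update(mem, "b", 3); topk_update(mem, "c", 2)
  expect_equal(mem$env$df$r_t, c(3, 2))
  topk_update(mem, "c", 0.5)                      # worse duplicate: unchanged
  expect_equal(sort(mem$env$df$r_t), c(2, 3))
  topk_update(mem, "c", 5)                        # better duplicate: replaced
  expect_equal(mem$env$df$r_t, c(5, 3))
  # oracle: every insertion order of four scored states
  items <- list(list(k = "a", r = 1.5), list(k = "b", r = -1),
                list(k = "c", r = 2.5), list(k = "a", r = 2.0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  oracle <- function(its, K) {
    best <- tapply(vapply(its, `[[`, numeric(1), "r"),
                   vapply(its, `[[`, character(1), "k"), max)
    c(utils::head(sort(best, decreasing = TRUE), K))
  }
  for (ord in perms(seq_along(items))) {
    m <- topk_memory(3)
    for (i in ord) topk_update(m, items[[i]]$k, items[[i]]$r)
    want <- oracle(items, 3)
    expect_equal(stats::setNames(m$env$df$r_t, m$env$df$key), want)
  }
})

test_that("chemical reward caches by canonical pair with zero extra calls", {
  cache <- reward_cache()
  r1 <- chemical_reward("C", cache = cache)
  expect_true(r1$valid); expect_false(r1$cached)
  calls <- cache$env$engine_calls
  r2 <- chemical_reward("C", cache = cache)
  expect_true(r2$cached)
  expect_equal(cache$env$engine_calls, calls)
  expect_equal(r2$r_c, r1$r_c)
  # "(C)" decodes to the same monosubstituted molecule as "C": shared entry
  r3 <- chemical_reward("(C)", cache = cache)
  expect_true(r3$cached)
  expect_equal(cache$env$engine_calls, calls)
})

test_that("the cascade reports the failing stage in order", {
  stages <- c("C(" = "syntax", "CE" = "decode", "(C)C" = "isomer_identity",
              "OO" = "heteroatom_chain", "FF" = "valence")
  for (s in names(stages)) {
    rb <- chemical_reward(s)
    expect_false(rb$valid)
    expect_equal(rb$failure_stage, unname(stages[s]))
  }
  # electron-parity stage: odd-valence elements (H, N, F) always pair up in
  # a valence-saturated neutral molecule, so decodable valence-sane states
  # are necessarily closed-shell -- the stage guards the pipeline but can
  # only fire for exotic inputs
  sp2 <- enumerate_space(max_tokens = 2)
  for (s in sp2$state[sp2$syntactic_valid]) {
    g <- decode_to_smiles(s)$graph
    if (valence_sanity(g)) expect_true(is_closed_shell(mol_composition(g)))
  }
  # the single-substituent constraint invalidates branched graft atoms only
  hp <- psrl_config(constraint = "R2_H")
  expect_equal(chemical_reward("(C)N", hp = hp)$failure_stage, "constraint")
  expect_true(chemical_reward("CN", hp = hp)$valid)
})

test_that("toy-engine rewards equal direct formula evaluation on a fixture", {
  fixture <- c("C", "CF", "ONC", "C(EC)F", "(F)N")
  for (s in fixture) {
    rb <- chemical_reward(s)
    expect_true(rb$valid)
    expect_equal(rb$r_c, toy_gap_direct(s), tolerance = 1e-12)
  }
  # hand check one value end to end: state "CF", E_Z - E_E =
  # (ster(C)/2 + ster(F)/3) + (elec(C)/2 + elec(F)/3)
  expect_equal(chemical_reward("CF")$r_c,
               (0.9 / 2 + 0.45 / 3) + (0.1 / 2 + 0.8 / 3))
})

test_that("zero-weight toy engines give zero gaps; order antisymmetry holds", {
  zero <- toy_engine(steric = c(C = 0, N = 0, O = 0, F = 0),
                     electronic = c(C = 0, N = 0, O = 0, F = 0),
                     common = c(0, 0, 0))
  rb <- chemical_reward("CF", engine = zero)
  expect_equal(rb$r_c, 0)
  eng <- toy_engine()
  ctx <- psmilesRL:::isomer_contexts(decode_to_smiles("CF"))
  gap_ez <- isomerization_gap(eng$evaluate(ctx$E), eng$evaluate(ctx$Z), "EZ")
  gap_ct <- isomerization_gap(eng$evaluate(ctx$E), eng$evaluate(ctx$Z),
                              "cis_trans")
  gap_tc <- isomerization_gap(eng$evaluate(ctx$E), eng$evaluate(ctx$Z),
                              "trans_cis")
  expect_equal(gap_ct, -gap_tc)
  expect_equal(gap_ez, gap_tc)
})
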