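# Grammar, tokenization, combinatorics and decoding of P-SMILES states.

test_that("tokenization is a greedy longest match and round-trips", {
  s <- tokenize("C(EC)F")
  expect_equal(s$tokens, c("C", "(", "E", "C", ")", "F"))
  expect_equal(s$token_count, 6L)
  # the aromatic digraph is one symbol per occurrence
  s2 <- tokenize("Ca1CCCCCa1")
  expect_equal(sum(s2$tokens == "a1"), 2L)
  expect_equal(s2$token_count, 8L)
  expect_equal(tokenize("")$token_count, 0L)
  expect_error(tokenize("X"), "UnknownToken")
  # round trip over the full 2-token space
  sp <- enumerate_space(max_tokens = 2, validity = "none")
  expect_true(all(vapply(sp$state, function(x) render(tokenize(x)) == x,
                         logical(1))))
})

test_that("count_combinations matches the closed form and edge cases", {
  expect_equal(count_combinations(11, 6), 1948716)
  expect_equal(count_combinations(11, 7), 21435887)
  expect_equal(count_combinations(7, 0), 0)
  expect_equal(count_combinations(1, 3), 3)
})

test_that("enumeration streams every sequence exactly once", {
  for (L in 1:3) {
    sp <- enumerate_space(max_tokens = L, validity = "none")
    expect_equal(nrow(sp), count_combinations(11, L))
    expect_equal(anyDuplicated(sp$state), 0L)
  }
  expect_error(enumerate_space(max_tokens = 7, cap = 1e6), "BudgetError")
})

test_that("syntactic validity follows the grammar", {
  expect_true(is_syntactically_valid("C(EC)F"))
  expect_true(is_syntactically_valid("CECC(EC)F"))
  expect_true(is_syntactically_valid("CONECF"))
  expect_true(is_syntactically_valid("Ca1CCCCCa1"))   # phenyl substituent
  expect_true(is_syntactically_valid("1CCC1"))        # ring onto the graft atom
  expect_false(is_syntactically_valid("(("))
  expect_false(is_syntactically_valid("CE"))          # dangling bond
  expect_false(is_syntactically_valid("C()C"))        # empty branch
  expect_false(is_syntactically_valid("C1CC"))        # unpaired ring label
  expect_false(is_syntactically_valid("Ca1Ca1"))      # aromatic ring not 6
  expect_false(is_syntactically_valid("CEZC"))        # consecutive bonds
  expect_false(is_syntactically_valid("X"))           # unknown symbol
})

test_that("well-formedness is the weaker bracket-level check", {
  expect_true(is_well_formed("CE"))        # dangling bond passes here
  expect_true(is_well_formed("C()C"))      # empty branch passes here
  expect_false(is_well_formed("C("))
  expect_false(is_well_formed(")C"))
  expect_false(is_well_formed("C1CC"))
  expect_false(is_well_formed("Ca1CC"))
  # strict grammar validity implies well-formedness on a full small space
  sp <- enumerate_space(max_tokens = 3)
  wf <- vapply(sp$state, is_well_formed, logical(1))
  expect_true(all(wf[sp$syntactic_valid]))
})

test_that("valid states decode; rendering is deterministic", {
  sp <- enumerate_space(max_tokens = 3)
  valid <- sp$state[sp$syntactic_valid]
  for (s in valid) {
    d <- expect_no_error(decode_to_smiles(s))
    d2 <- decode_to_smiles(s)
    expect_identical(d$e, d2$e)
    expect_identical(d$z, d2$z)
  }
  expect_error(decode_to_smiles("C("), "DecodeError")
})

test_that("decoding grafts the state onto the styrene scaffold", {
  d <- decode_to_smiles("C")
  expect_equal(d$e, "c1ccccc1/C=C/C")
  expect_equal(d$z, "c1ccccc1/C=C\\C")
  expect_true(d$stereo)
  # the best-reported 6-token state is a branched fluorinated diene
  d2 <- decode_to_smiles("C(EC)F")
  expect_match(d2$e, "C\\(=C\\)F", fixed = FALSE)
  expect_equal(length(d2$graph$elem), 8L + 3L)   # scaffold + C, C, F
  # a full-molecule rendering reproduces the reporting notation
  expect_equal(full_psmiles("C(EC)F", "E"), "Ca1C(CCCCa1)CECC(EC)F")
  # a state whose whole text is one long substituent decodes to a
  # phenyl-bearing fluoro-diene
  d3 <- decode_to_smiles("Ca1C(CCCCa1)CECC(EC)F")
  expect_match(d3$e, "c.c\\(cccc.\\)", fixed = FALSE)
  expect_match(d3$e, "F")
  # both substituents identical: the two isomers coincide after
  # canonicalization
  d4 <- decode_to_smiles("(C)C")
  expect_equal(canonical_smiles(d4$e), canonical_smiles(d4$z))
  # empty state: scaffold only, no stereo pair
  d5 <- decode_to_smiles("")
  expect_false(d5$stereo)
})

test_that("decoded SMILES parse in the chemistry toolkit", {
  sp <- enumerate_space(max_tokens = 3)
  valid <- sp$state[sp$syntactic_valid]
  some <- valid[seq(1, length(valid), by = 7)]
  for (s in some) {
    d <- decode_to_smiles(s)
    expect_no_error(canonical_smiles(d$e))
    expect_no_error(canonical_smiles(d$z))
  }
})

test_that("the strict-grammar census DP agrees with brute enumeration", {
  for (L in 1:4) {
    sp <- enumerate_space(max_tokens = L)
    expect_equal(count_syntactic_valid(L)$valid, sum(sp$syntactic_valid))
  }
})

test_that("the well-formedness census DP agrees with brute counting", {
  for (L in 1:4) {
    sp <- enumerate_space(max_tokens = L, validity = "none")
    bf <- sum(vapply(sp$state, is_well_formed, logical(1)))
    expect_equal(count_well_formed(L)$valid, bf)
  }
})
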