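# Chemical validity cascade: heteroatom chains, valences, electron parity,
# graph isomorphism, 3D embedding and identity round-trips.

test_that("heteroatom chain filter bans acyclic O-O and N-N only", {
  expect_false(heteroatom_chain_filter("OO"))     # peroxide chain
  expect_false(heteroatom_chain_filter("CNNC"))   # hydrazine-like chain
  expect_true(heteroatom_chain_filter("CO"))
  expect_true(heteroatom_chain_filter("ON"))      # O-N is allowed
  # ring-internal O-O is exempt: build a 1,2-dioxolane-like graph by hand
  ring <- mk_graph(c("O", "O", "C", "C", "C"),
                   c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 1))
  expect_true(heteroatom_chain_filter(ring))
  # same bond without the ring closure is banned
  chain <- mk_graph(c("O", "O", "C", "C", "C"),
                    c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_false(heteroatom_chain_filter(chain))
})

test_that("valence sanity enforces neutral valences", {
  penta <- mk_graph(c("C", "F", "F", "F", "F", "F"),
                    rep(1, 5), 2:6)
  expect_false(valence_sanity(penta))
  expect_true(valence_sanity(decode_to_smiles("C")$graph))    # styrene deriv
  expect_false(valence_sanity("FF"))     # divalent fluorine
  expect_false(valence_sanity("#C"))     # overloads the graft carbon
  expect_true(valence_sanity("ECEC"))    # cumulated double bonds are fine
  expect_true(valence_sanity("C#N"))
})

test_that("closed-shell parity equals direct electron enumeration", {
  expect_true(is_closed_shell(c(H = 2, O = 1)))    # water, 10 electrons
  expect_false(is_closed_shell(c(C = 1, H = 3)))   # methyl radical, 9
  expect_false(is_closed_shell(c(H = 1)))          # lone hydrogen atom
  expect_error(is_closed_shell(c(Xx = 1)), "UnknownElement")
  z <- c(H = 1, C = 6, N = 7, O = 8, F = 9)
  set.seed(7)
  for (k in 1:50) {
    comp <- stats::setNames(sample(0:4, 5, replace = TRUE), names(z))
    comp <- comp[comp > 0]
    if (!length(comp)) next
    # oracle: enumerate every electron one atom at a time
    electrons <- sum(unlist(mapply(rep, z[names(comp)], comp)))
    expect_equal(is_closed_shell(comp), electrons %% 2 == 0)
  }
})

test_that("connectivity check matches a brute-force permutation oracle", {
  g <- decode_to_smiles("CC")$graph
  expect_true(connectivity_preserved(g, g))
  # removing an edge splits ethane-like graphs
  eth <- mk_graph(c("C", "C", "H", "H", "H", "H", "H", "H"),
                  c(1, 1, 1, 1, 2, 2, 2), c(2, 3, 4, 5, 6, 7, 8))
  cut <- mk_graph(eth$elem, eth$bonds$i[-1], eth$bonds$j[-1])
  expect_false(connectivity_preserved(eth, cut))
  set.seed(42)
  for (k in 1:25) {
    n <- sample(4:8, 1)
    g1 <- random_graph(n, extra_edge = k %% 3 == 0)
    p <- sample(n)
    g2 <- permute_graph(g1, p)
    expect_true(connectivity_preserved(g1, g2))
    expect_equal(connectivity_preserved(g1, g2), brute_isomorphic(g1, g2))
    # a perturbed copy (one element changed) must disagree
    g3 <- g2; g3$elem[1] <- if (g3$elem[1] == "C") "N" else "C"
    expect_equal(connectivity_preserved(g1, g3), brute_isomorphic(g1, g3))
  }
})

test_that("embedding produces MMFF94-quality geometries", {
  gm <- embed_and_preoptimize("C")      # methane
  d <- as.matrix(stats::dist(gm$coords))
  ch <- d[1, gm$elems == "H"]
  expect_true(all(ch > 1.05 & ch < 1.15))
  ge <- embed_and_preoptimize("CC")     # ethane
  de <- as.matrix(stats::dist(ge$coords))
  cc <- de[1, 2]
  expect_true(cc > 1.45 && cc < 1.60)
  expect_equal(ge$provenance, "MM-optimized")
})

test_that("bond perception from coordinates recovers the graph", {
  g <- embed_and_preoptimize("CCO")
  per <- perceive_graph(g)
  ref <- psmilesRL:::with_explicit_hydrogens(
    mk_graph(c("C", "C", "O"), c(1, 2), c(2, 3)))
  expect_true(connectivity_preserved(ref, per))
})

test_that("identity round-trip detects isomerization and tautomers", {
  d <- decode_to_smiles("CC")
  ge <- embed_and_preoptimize(d$e)
  expect_true(identity_roundtrip(d$e, ge))
  # the relaxed E geometry is not the Z structure
  expect_false(identity_roundtrip(d$z, ge))
  # hand-built tautomer pair: acetaldehyde vs vinyl alcohol
  expect_false(identical(inchikey("CC=O"), inchikey("C=CO")))
})
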