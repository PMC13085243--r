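# Shared fixtures: small configurations, hand-built graphs, and brute-force
# oracles kept independent of the implementation paths they check.

tiny_config <- function(...) {
  args <- list(L = 4L, d_model = 8L, n_layers = 1L, n_heads = 2L, epochs = 3L,
               episodes_per_epoch = 4L, batch_size = 4L, ppo_epochs = 1L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(psrl_config, args)
}

# benchmark settings for the search-comparison study (small nets, fast
# updates; see the methods vignette for the rationale)
benchmark_config <- function(seed = 1L) {
  psrl_config(L = 4, d_model = 8, n_layers = 1, n_heads = 2, epochs = 700,
              episodes_per_epoch = 20, batch_size = 16, ppo_epochs = 2,
              lr = 3e-3, c_e = 0.1, seed = seed)
}

# build a molgraph by hand
mk_graph <- function(elem, bonds_i, bonds_j, order = NULL,
                     aromatic = rep(FALSE, length(elem))) {
  structure(list(elem = elem, aromatic = aromatic,
                 bonds = data.frame(i = bonds_i, j = bonds_j,
                                    order = if (is.null(order))
                                      rep(1L, length(bonds_i)) else order)),
            class = "molgraph")
}

# brute-force element-labelled graph isomorphism by permutation search
# (independent oracle for connectivity_preserved; <= 8 atoms)
brute_isomorphic <- function(g1, g2) {
  n <- length(g1$elem)
  if (n != length(g2$elem)) return(FALSE)
  adj <- function(g) {
    A <- matrix(FALSE, n, n)
    for (k in seq_len(nrow(g$bonds))) {
      A[g$bonds$i[k], g$bonds$j[k]] <- TRUE
      A[g$bonds$j[k], g$bonds$i[k]] <- TRUE
    }
    A
  }
  A1 <- adj(g1); A2 <- adj(g2)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (p in perms(seq_len(n))) {
    if (all(g1$elem == g2$elem[p]) && all(A1 == A2[p, p])) return(TRUE)
  }
  FALSE
}

# random element-labelled connected graph on n atoms (tree + optional extra
# edge), for property tests
random_graph <- function(n, extra_edge = FALSE) {
  elem <- sample(c("C", "N", "O", "H"), n, replace = TRUE)
  bi <- integer(0); bj <- integer(0)
  for (k in 2:n) { bi <- c(bi, sample(k - 1L, 1L)); bj <- c(bj, k) }
  if (extra_edge && n >= 4) {
    repeat {
      a <- sample(n, 2L)
      if (!any((bi == min(a) & bj == max(a)))) {
        bi <- c(bi, min(a)); bj <- c(bj, max(a)); break
      }
    }
  }
  mk_graph(elem, bi, bj)
}

# permute the atom labels of a graph
permute_graph <- function(g, p) {
  inv <- order(p)
  mk_graph(g$elem[p],
           inv[g$bonds$i], inv[g$bonds$j],
           order = g$bonds$order, aromatic = g$aromatic[p])
}

# direct evaluation of the default toy formula, written independently of
# isomer_contexts / toy_engine internals: walks the decoded state text
toy_gap_direct <- function(state_text, mode = "EZ") {
  d <- decode_to_smiles(state_text)
  p <- d$parse
  roots <- p$sub_roots
  # breadth-first from each root over tree parents
  subtree <- function(root) {
    ids <- root; depths <- 1L
    repeat {
      fresh <- setdiff(which(p$parent %in% ids), ids)
      if (!length(fresh)) break
      depths <- c(depths, vapply(fresh, function(a) {
        depths[match(p$parent[a], ids)] + 1L
      }, integer(1)))
      ids <- c(ids, fresh)
    }
    data.frame(elem = p$elem[ids], d = depths)
  }
  s1 <- if (length(roots) >= 1) subtree(roots[1]) else data.frame(elem = character(0), d = integer(0))
  s2 <- if (length(roots) >= 2) subtree(roots[2]) else data.frame(elem = character(0), d = integer(0))
  ster <- c(C = 0.9, N = 0.75, O = 0.6, F = 0.45)
  elec <- c(C = 0.1, N = 0.3, O = 0.5, F = 0.8)
  en <- function(cis, trans)
    sum(ster[cis$elem] / (1 + cis$d)) - sum(elec[trans$elem] / (1 + trans$d)) +
      0.15 * length(p$elem) + 0.4 * sum(p$pbond == 2L) - 0.25 * sum(p$pbond == 3L)
  e_E <- en(s2, s1)   # E: first-written substituent anti (trans side)
  e_Z <- en(s1, s2)
  switch(mode, EZ = e_Z - e_E, cis_trans = e_E - e_Z, trans_cis = e_Z - e_E)
}
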