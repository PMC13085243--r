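# Chemical validity stages of the reward routine, operating on decoded
# molecular graphs (class "molgraph": elem, aromatic, bonds(i, j, order);
# order 4 denotes an aromatic bond) and on 3D geometries.

.atomic_number <- c(H = 1L, C = 6L, N = 7L, O = 8L, F = 9L, Cl = 17L)
.valence      <- c(C = 4L, N = 3L, O = 2L, F = 1L)
.covalent_radius <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57)

# effective bond-order sum at each atom (aromatic bond counts 1.5)
bond_order_sums <- function(graph) {
  n <- length(graph$elem)
  s <- numeric(n)
  if (nrow(graph$bonds)) {
    o <- ifelse(graph$bonds$order == 4L, 1.5, graph$bonds$order)
    for (k in seq_len(nrow(graph$bonds))) {
      s[graph$bonds$i[k]] <- s[graph$bonds$i[k]] + o[k]
      s[graph$bonds$j[k]] <- s[graph$bonds$j[k]] + o[k]
    }
  }
  s
}

# implicit hydrogen count per atom under standard valences; negative values
# signal a valence violation
implicit_hydrogens <- function(graph) {
  .valence[graph$elem] - round(bond_order_sums(graph))
}

#' Molecular composition of a decoded graph
#'
#' Element counts including implicit hydrogens filled to standard valences.
#'
#' @param graph A \code{molgraph}.
#' @return Named integer vector of element counts (including \code{H}).
#' @export
mol_composition <- function(graph) {
  h <- sum(pmax(implicit_hydrogens(graph), 0))
  tab <- table(graph$elem)
  out <- c(stats::setNames(as.integer(tab), names(tab)), H = as.integer(h))
  out[out > 0]
}

#' Valence sanity of a decoded molecule
#'
#' Checks standard neutral-atom valences (C 4, N 3, O 2, F 1) against the
#' bond orders of the decoded graph, with aromatic bonds counting 1.5 and
#' aromatic nitrogens taken as pyridine-type (no substituent, no hydrogen).
#' This stands behind the basic-chemical-rules stage of the validity cascade.
#'
#' @param graph A \code{molgraph} (or a P-SMILES state / character scalar,
#'   decoded on the fly; undecodable states are simply not sane).
#' @return \code{TRUE} or \code{FALSE}; never throws.
#' @examples
#' valence_sanity(decode_to_smiles("C")$graph)   # TRUE
#' valence_sanity("FF")                          # FALSE (divalent fluorine)
#' @export
valence_sanity <- function(graph) {
  if (!inherits(graph, "molgraph")) {
    d <- tryCatch(decode_to_smiles(graph), error = function(e) NULL)
    if (is.null(d)) return(FALSE)
    graph <- d$graph
  }
  h <- implicit_hydrogens(graph)
  if (any(is.na(h)) || any(h < 0)) return(FALSE)
  # aromatic atoms: exactly two aromatic bonds each; aromatic N bears nothing
  if (any(graph$aromatic)) {
    arom_deg <- numeric(length(graph$elem))
    ab <- graph$bonds[graph$bonds$order == 4L, ]
    for (k in seq_len(nrow(ab))) {
      arom_deg[ab$i[k]] <- arom_deg[ab$i[k]] + 1
      arom_deg[ab$j[k]] <- arom_deg[ab$j[k]] + 1
    }
    if (any(graph$aromatic & arom_deg != 2)) return(FALSE)
    if (any(!graph$aromatic & arom_deg > 0)) return(FALSE)
    arN <- which(graph$aromatic & graph$elem == "N")
    if (length(arN)) {
      deg <- table(factor(c(graph$bonds$i, graph$bonds$j),
                          levels = seq_along(graph$elem)))
      if (any(deg[arN] > 2)) return(FALSE)
    }
  }
  TRUE
}

#' Heteroatom chain filter
#'
#' A molecule is rejected when it contains an oxygen-oxygen or
#' nitrogen-nitrogen bond outside a ring; ring-internal O-O or N-N bonds are
#' not penalized by this rule.
#'
#' @param graph A \code{molgraph} (or state/character, decoded on the fly).
#' @return \code{TRUE} when the molecule passes (no acyclic O-O/N-N bond).
#' @examples
#' heteroatom_chain_filter("CO")    # TRUE
#' heteroatom_chain_filter("OO")    # FALSE (peroxide chain)
#' @export
heteroatom_chain_filter <- function(graph) {
  if (!inherits(graph, "molgraph")) {
    d <- tryCatch(decode_to_smiles(graph), error = function(e) NULL)
    if (is.null(d)) return(FALSE)
    graph <- d$graph
  }
  b <- graph$bonds
  bad <- which((graph$elem[b$i] == "O" & graph$elem[b$j] == "O") |
               (graph$elem[b$i] == "N" & graph$elem[b$j] == "N"))
  if (!length(bad)) return(TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = b$i, to = b$j), directed = FALSE,
    vertices = data.frame(name = seq_along(graph$elem)))
  for (k in bad) {
    # the bond is in a ring iff removing it keeps its ends connected
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(b$i[k], b$j[k])))
    if (igraph::distances(g2, v = as.character(b$i[k]),
                          to = as.character(b$j[k])) == Inf)
      return(FALSE)
  }
  TRUE
}

#' Closed-shell parity check
#'
#' A neutral molecule is formally closed-shell when its total electron count
#' \eqn{\sum_i n_i Z_i} (atomic numbers weighted by element counts, implicit
#' hydrogens included) is even.
#'
#' @param composition Named integer vector of element counts (as returned by
#'   [mol_composition()]), or a \code{molgraph}.
#' @param total_charge Must be 0; only neutral species are supported.
#' @return \code{TRUE} (even electron count) or \code{FALSE}.
#' @examples
#' is_closed_shell(c(H = 2, O = 1))   # TRUE  (10 electrons)
#' is_closed_shell(c(C = 1, H = 3))   # FALSE (9 electrons, methyl radical)
#' @export
is_closed_shell <- function(composition, total_charge = 0) {
  stopifnot(total_charge == 0)
  if (inherits(composition, "molgraph"))
    composition <- mol_composition(composition)
  z <- .atomic_number[names(composition)]
  if (any(is.na(z)))
    stop("UnknownElement: ", paste(names(composition)[is.na(z)], collapse = ", "),
         call. = FALSE)
  sum(z * as.numeric(composition)) %% 2 == 0
}

#' Element-labelled graph isomorphism (connectivity preservation)
#'
#' Verifies that two molecular graphs are isomorphic as element-labelled
#' graphs with all bonds collapsed to single edges, the criterion used to
#' detect connectivity changes across a geometry optimization. VF2 via
#' igraph; a brute-force permutation oracle backs this in the test suite.
#'
#' @param before,after \code{molgraph} objects (bond orders are ignored).
#' @return \code{TRUE} or \code{FALSE}.
#' @export
connectivity_preserved <- function(before, after) {
  stopifnot(inherits(before, "molgraph"), inherits(after, "molgraph"))
  if (length(before$elem) != length(after$elem)) return(FALSE)
  elems <- sort(unique(c(before$elem, after$elem)))
  mk <- function(g) {
    ig <- igraph::graph_from_data_frame(
      unique(data.frame(from = pmin(g$bonds$i, g$bonds$j),
                        to = pmax(g$bonds$i, g$bonds$j))),
      directed = FALSE,
      vertices = data.frame(name = seq_along(g$elem)))
    igraph::V(ig)$color <- match(g$elem, elems)
    ig
  }
  igraph::isomorphic(mk(before), mk(after), method = "vf2")
}

# ---------------------------------------------------------------------------
# Geometry stages (Open Babel stands behind the embedding/optimization and
# identity interfaces).


ob_convert <- function(from, to, text, gen3d = FALSE) {
  args <- list(from, to, text)
  if (gen3d) args$options <- data.frame(names = "gen3d", args = "")
  out <- tryCatch(
    do.call(ChemmineOB::convertFormat, args),
    error = function(e) "")
  if (!nzchar(out)) stop("PerceptionError: Open Babel conversion failed",
                         call. = FALSE)
  out
}

#' Canonical SMILES via the chemistry toolkit
#' @param smiles A SMILES string.
#' @return Canonical SMILES (character scalar).
#' @export
canonical_smiles <- function(smiles) {
  sub("\t.*$", "", sub("\n.*$", "", ob_convert("SMI", "CAN", smiles)))
}

#' InChIKey of a structure
#' @param smiles A SMILES string.
#' @return The InChIKey (character scalar).
#' @export
inchikey <- function(smiles) {
  trimws(sub("\n.*$", "", ob_convert("SMI", "INCHIKEY", smiles)))
}

# parse an XYZ block into a Geometry
read_xyz_text <- function(text, provenance = "unknown") {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  elems <- vapply(rows, `[`, character(1), 1L)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  structure(list(elems = elems, coords = coords, provenance = provenance),
            class = "geometry")
}

write_xyz_text <- function(geom, comment = "") {
  paste(c(length(geom$elems), comment,
          sprintf("%-2s %12.6f %12.6f %12.6f", geom$elems,
                  geom$coords[, 1], geom$coords[, 2], geom$coords[, 3])),
        collapse = "\n")
}

#' Embed a molecule in 3D and pre-optimize with MMFF94
#'
#' Generates Cartesian coordinates from a SMILES string and relaxes them
#' with the MMFF94 force field (Open Babel's 3D builder, which is
#' deterministic for a given input).
#'
#' @param smiles SMILES string.
#' @return A \code{geometry} object: \code{elems}, \code{coords} (Angstrom),
#'   \code{provenance = "MM-optimized"}.
#' @export
embed_and_preoptimize <- function(smiles) {
  xyz <- tryCatch(ob_convert("SMI", "XYZ", smiles, gen3d = TRUE),
                  error = function(e) NULL)
  if (is.null(xyz) || length(strsplit(xyz, "\n")[[1]]) < 3)
    stop("EmbedError: no 3D embedding found for ", smiles, call. = FALSE)
  read_xyz_text(xyz, provenance = "MM-optimized")
}

#' Perceive a molecular graph from 3D coordinates
#'
#' Distance-based bond detection: two atoms are bonded when their distance
#' does not exceed \code{tol} times the sum of their covalent radii. Bond
#' orders are not perceived (all edges single), matching the collapsed-graph
#' comparison of [connectivity_preserved()].
#'
#' @param geom A \code{geometry}.
#' @param tol Cutoff factor on the covalent-radius sum (default 1.25).
#' @return A \code{molgraph} with heavy atoms and hydrogens as written.
#' @export
perceive_graph <- function(geom, tol = 1.25) {
  n <- length(geom$elems)
  r <- .covalent_radius[geom$elems]
  if (any(is.na(r)))
    stop("UnknownElement in geometry: ",
         paste(unique(geom$elems[is.na(r)]), collapse = ","), call. = FALSE)
  d <- as.matrix(stats::dist(geom$coords))
  cutoff <- outer(r, r, "+") * tol
  adj <- d <= cutoff & upper.tri(d)
  idx <- which(adj, arr.ind = TRUE)
  structure(list(elem = geom$elems,
                 aromatic = rep(FALSE, n),
                 bonds = data.frame(i = idx[, 1], j = idx[, 2], order = 1L)),
            class = "molgraph")
}

# graph with explicit hydrogens and bonds collapsed to single edges, for
# comparison against geometry-perceived graphs
with_explicit_hydrogens <- function(graph) {
  h <- pmax(implicit_hydrogens(graph), 0)
  elem <- graph$elem
  bonds <- data.frame(i = graph$bonds$i, j = graph$bonds$j, order = 1L)
  for (a in seq_along(h)) {
    if (h[a] > 0) for (k in seq_len(h[a])) {
      elem <- c(elem, "H")
      bonds <- rbind(bonds, data.frame(i = a, j = length(elem), order = 1L))
    }
  }
  structure(list(elem = elem, aromatic = rep(FALSE, length(elem)),
                 bonds = bonds), class = "molgraph")
}

#' Identity round-trip via InChIKey
#'
#' Compares the InChIKey of the originally decoded structure with the
#' InChIKey of the structure perceived from a final geometry; a mismatch
#' reveals a change in connectivity, bond orders or isomerism during the
#' optimization pipeline.
#'
#' @param state_smiles SMILES of the decoded state.
#' @param final_geometry A \code{geometry}.
#' @return \code{TRUE} when the InChIKeys coincide.
#' @export
identity_roundtrip <- function(state_smiles, final_geometry) {
  k1 <- inchikey(state_smiles)
  smi2 <- sub("\t.*$", "",
              sub("\n.*$", "",
                  ob_convert("XYZ", "CAN", write_xyz_text(final_geometry))))
  k2 <- inchikey(smi2)
  identical(k1, k2)
}
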