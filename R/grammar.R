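# Grammar and decoding of P-SMILES states.
#
# A state is a SMILES-like suffix grafted onto the beta carbon of the
# scaffold's exocyclic double bond.  The grammar is sequential: atoms chain
# from the attachment point, E/Z/# set the next bond's type (E/Z carry the
# double-bond geometry), "(" opens a branch, "1" is an aliphatic ring-closure
# digit and the digraph "a1" an aromatic ring-closure label whose paired
# atoms, together with the enclosed six-membered ring, are aromatized.

# Internal parse of a state's symbol sequence into a substituent graph.
# Atom index 0 denotes the attachment atom (the scaffold beta carbon).
# Returns list(ok, reason, ...) -- never throws for grammar violations.
ps_parse <- function(tokens) {
  fail <- function(reason) list(ok = FALSE, reason = reason)
  elem <- character(0)           # state atoms, written order
  parent <- integer(0)           # tree parent (0 = attachment)
  pbond <- integer(0)            # bond order to tree parent
  pgeom <- character(0)          # geometry tag of that bond ("E"/"Z"/NA)
  aromatic <- logical(0)
  bi <- integer(0); bj <- integer(0); bo <- integer(0)
  cur <- 0L
  pending <- NULL                # "E","Z","#"
  stack <- integer(0)            # branch parents
  stack_n <- integer(0)          # atom count at branch open
  open1 <- NA_integer_           # open "1" marker atom
  opena <- NA_integer_           # open "a1" marker atom
  last <- ""                     # previous token
  tree_path <- function(i, j) {
    # atom path from i to j through the spanning tree (0 = attachment)
    anc <- function(a) { out <- a; while (a != 0L) { a <- parent[a]; out <- c(out, a) }; out }
    ai <- anc(i); aj <- anc(j)
    common <- ai[ai %in% aj][1L]
    c(ai[seq_len(match(common, ai))], rev(aj[seq_len(match(common, aj) - 1L)]))
  }
  for (tok in tokens) {
    if (tok %in% c("C", "N", "O", "F")) {
      o <- 1L; g <- NA_character_
      if (!is.null(pending)) {
        o <- if (pending == "#") 3L else 2L
        if (pending %in% c("E", "Z")) g <- pending
        pending <- NULL
      }
      elem <- c(elem, tok); aromatic <- c(aromatic, FALSE)
      parent <- c(parent, cur); pbond <- c(pbond, o); pgeom <- c(pgeom, g)
      cur <- length(elem)
    } else if (tok %in% c("E", "Z", "#")) {
      if (!is.null(pending)) return(fail("consecutive bond symbols"))
      pending <- tok
    } else if (tok == "(") {
      if (!is.null(pending)) return(fail("branch after bond symbol"))
      if (last == "(") return(fail("empty branch opening"))
      stack <- c(stack, cur); stack_n <- c(stack_n, length(elem))
    } else if (tok == ")") {
      if (!length(stack)) return(fail("unmatched branch close"))
      if (!is.null(pending)) return(fail("dangling bond at branch close"))
      k <- length(stack)
      if (length(elem) == stack_n[k]) return(fail("empty branch"))
      cur <- stack[k]
      stack <- stack[-k]; stack_n <- stack_n[-k]
    } else if (tok %in% c("1", "a1")) {
      if (!is.null(pending)) return(fail("ring label after bond symbol"))
      if (last == "(") return(fail("ring label at branch opening"))
      if (tok == "a1" && (cur == 0L || !elem[cur] %in% c("C", "N")))
        return(fail("aromatic label on non-aromatizable atom"))
      open <- if (tok == "1") open1 else opena
      if (is.na(open)) {
        if (tok == "1") open1 <- cur else opena <- cur
      } else {
        if (open == cur) return(fail("ring closure onto same atom"))
        adjacent <- (open != 0L && parent[open] == cur && pbond[open] >= 1L) ||
                    (cur != 0L && parent[cur] == open) ||
                    any(bi == min(open, cur) & bj == max(open, cur))
        if (adjacent) return(fail("two-membered ring"))
        path <- tree_path(open, cur)
        if (tok == "1") {
          if (length(path) < 3L) return(fail("ring smaller than three atoms"))
          bi <- c(bi, min(open, cur)); bj <- c(bj, max(open, cur)); bo <- c(bo, 1L)
          open1 <- NA_integer_
        } else {
          if (length(path) != 6L) return(fail("aromatic ring is not six-membered"))
          if (any(path == 0L)) return(fail("aromatic ring through attachment"))
          if (!all(elem[path] %in% c("C", "N")))
            return(fail("non-aromatizable atom in aromatic ring"))
          if (any(aromatic[path])) return(fail("fused aromatic labels"))
          # ring path bonds must be written single; they become aromatic
          for (k in seq_len(5L)) {
            child <- if (parent[path[k]] == path[k + 1L]) path[k] else path[k + 1L]
            if (pbond[child] != 1L)
              return(fail("multiple bond inside aromatic ring"))
            pbond[child] <- 4L
          }
          bi <- c(bi, min(open, cur)); bj <- c(bj, max(open, cur)); bo <- c(bo, 4L)
          aromatic[path] <- TRUE
          opena <- NA_integer_
        }
      }
    } else {
      return(fail(paste0("unknown symbol '", tok, "'")))
    }
    last <- tok
  }
  if (!is.null(pending)) return(fail("dangling bond at end of state"))
  if (length(stack)) return(fail("unclosed branch"))
  if (!is.na(open1) || !is.na(opena)) return(fail("unpaired ring label"))
  list(ok = TRUE, reason = NA_character_,
       elem = elem, aromatic = aromatic,
       parent = parent, pbond = pbond, pgeom = pgeom,
       ring_i = bi, ring_j = bj, ring_o = bo,
       sub_roots = which(parent == 0L),
       beta_ring_closure = any(bi == 0L))
}

#' Syntactic validity of a P-SMILES state
#'
#' Pure grammar check: the state must be expressible as a legal SMILES
#' continuation of the scaffold attachment point. Bond symbols must be
#' followed by an atom, branches must be nonempty and properly nested, ring
#' labels must pair (the aromatic label \code{a1} must close a six-membered
#' carbon/nitrogen ring written with single bonds), and no bond symbol may
#' dangle at the end. No valence, 3D or energetic criterion is applied here.
#'
#' @param state A \code{psmiles_state} or a character scalar (tokenized on
#'   the fly; untokenizable text is simply invalid).
#' @param vocab A [psmiles_vocab()].
#' @return \code{TRUE} or \code{FALSE}; never throws for grammar violations.
#' @examples
#' is_syntactically_valid("C(EC)F")   # TRUE
#' is_syntactically_valid("((")       # FALSE
#' @export
is_syntactically_valid <- function(state, vocab = psmiles_vocab()) {
  if (is.character(state)) {
    state <- tryCatch(tokenize(state, vocab), error = function(e) NULL)
    if (is.null(state)) return(FALSE)
  }
  ps_parse(state$tokens)$ok
}

#' The styrene scaffold
#'
#' The fixed backbone carrying the isomerizing double bond: a phenyl ring
#' conjugated to an exocyclic C=C. Generated substituents are grafted at the
#' beta carbon; the alpha carbon keeps the aryl group and one hydrogen. The
#' E isomer places the first-written substituent anti to the aryl group, the
#' Z isomer syn (a labelling convention: the first-written group plays the
#' role of the higher-priority substituent).
#'
#' @param name Scaffold identifier (only \code{"styrene"} is built in).
#' @return An object of class \code{scaffold_spec}.
#' @export
scaffold_styrene <- function(name = "styrene") {
  structure(list(
    name = name,
    backbone_psmiles = "Ca1C(CCCCa1)C%sC",  # %s is the E/Z symbol
    n_backbone_atoms = 8L,                   # 6 ring + alpha + beta
    alpha = 7L, beta = 8L
  ), class = "scaffold_spec")
}

#' @export
print.scaffold_spec <- function(x, ...) {
  cat("<scaffold_spec>", x$name, "- backbone",
      sprintf(x$backbone_psmiles, "E/Z"), "\n")
  invisible(x)
}

# Build the full molecular graph (scaffold + substituent) from a parse.
# Returns a "molgraph": elem, aromatic, bonds (i, j, order; 4 = aromatic).
compose_graph <- function(parse, scaffold = scaffold_styrene()) {
  nb <- scaffold$n_backbone_atoms
  elem <- c(rep("C", nb), parse$elem)
  aromatic <- c(rep(TRUE, 6L), FALSE, FALSE, parse$aromatic)
  bonds <- data.frame(
    i = c(1:5, 6L, 2L, scaffold$alpha),
    j = c(2:6, 1L, scaffold$alpha, scaffold$beta),
    order = c(rep(4L, 6L), 1L, 2L))
  n <- length(parse$elem)
  if (n) {
    tp <- ifelse(parse$parent == 0L, scaffold$beta, parse$parent + nb)
    bonds <- rbind(bonds, data.frame(i = tp, j = seq_len(n) + nb,
                                     order = ifelse(parse$pbond == 4L, 4L,
                                                    parse$pbond)))
  }
  if (length(parse$ring_i)) {
    ri <- ifelse(parse$ring_i == 0L, scaffold$beta, parse$ring_i + nb)
    rj <- ifelse(parse$ring_j == 0L, scaffold$beta, parse$ring_j + nb)
    bonds <- rbind(bonds, data.frame(i = ri, j = rj, order = parse$ring_o))
  }
  structure(list(elem = elem, aromatic = aromatic, bonds = bonds),
            class = "molgraph")
}

# Render the substituent SMILES from the token stream.  Two passes: first
# assign directional markers ("/" or "\\") to the writing slot just before
# selected atom letters, then emit.  `first_marker` is the marker claimed by
# the scaffold stereo bond for the first substituent atom (or NULL).
render_substituent <- function(tokens, parse, first_marker = NULL) {
  n <- length(parse$elem)
  atom_tok <- which(tokens %in% c("C", "N", "O", "F"))
  atom_of_tok <- integer(length(tokens))
  atom_of_tok[atom_tok] <- seq_len(n)
  tok_of_atom <- atom_tok
  marker <- rep(NA_character_, max(n, 1L))
  if (!is.null(first_marker) && n >= 1L) marker[1L] <- first_marker
  flip <- function(m) if (m == "/") "\\" else "/"
  # pass 1: internal stereo double bonds, written order
  for (y in seq_len(n)) {
    g <- parse$pgeom[y]
    if (is.na(g)) next
    x <- parse$parent[y]
    if (x == 0L) next                       # cumulated at the attachment
    if (parse$pbond[x] != 1L) next          # pred bond must be single
    k <- tok_of_atom[y]
    if (k == length(tokens)) next
    if (!tokens[k + 1L] %in% c("C", "N", "O", "F")) next
    s <- atom_of_tok[k + 1L]
    if (parse$parent[s] != y || parse$pbond[s] != 1L) next
    pm <- marker[x]
    if (is.na(pm)) { pm <- "/"; marker[x] <- pm }
    marker[s] <- if (g == "E") pm else flip(pm)
  }
  # pass 2: emit
  digit_for <- c("1" = "2", "a1" = "3")
  out <- character(0)
  for (k in seq_along(tokens)) {
    tok <- tokens[k]
    if (tok %in% c("C", "N", "O", "F")) {
      a <- atom_of_tok[k]
      if (!is.na(marker[a])) out <- c(out, marker[a])
      out <- c(out, if (parse$aromatic[a]) tolower(tok) else tok)
    } else if (tok %in% c("E", "Z")) {
      out <- c(out, "=")
    } else if (tok %in% c("1", "a1")) {
      out <- c(out, digit_for[[tok]])
    } else {
      out <- c(out, tok)                    # "#", "(", ")"
    }
  }
  paste(out, collapse = "")
}

#' Decode a P-SMILES state into the two isomer SMILES
#'
#' Grafts the state onto the scaffold's beta carbon and renders standard
#' SMILES for both geometrical isomers: the E isomer places the first-written
#' substituent anti to the aryl group, the Z isomer syn. The rendering is
#' deterministic (byte-identical for identical states). Directional bond
#' markers are emitted only where the geometry is chemically defined (a
#' reference neighbour exists on each side, the flanking bonds are single,
#' and the beta carbon is not itself part of a ring or cumulated system);
#' otherwise the plain double bond is written, the two renderings coincide,
#' and the state has no distinct isomer pair.
#'
#' @param state A \code{psmiles_state} or character scalar.
#' @param scaffold A [scaffold_styrene()] spec.
#' @param vocab A [psmiles_vocab()].
#' @return List with \code{e} and \code{z} (SMILES strings), \code{graph}
#'   (the shared \code{molgraph}; the two isomers differ only in geometry),
#'   \code{sub_roots} (state atom indices bonded to the beta carbon, written
#'   order), \code{stereo} (logical: do the two renderings differ?), and
#'   \code{parse} (the internal parse record).
#' @examples
#' decode_to_smiles("C")$e       # E-propenylbenzene
#' @export
decode_to_smiles <- function(state, scaffold = scaffold_styrene(),
                             vocab = psmiles_vocab()) {
  if (is.character(state)) state <- tokenize(state, vocab)
  parse <- ps_parse(state$tokens)
  if (!parse$ok)
    stop("DecodeError: ", parse$reason, call. = FALSE)
  graph <- compose_graph(parse, scaffold)
  stereo_ok <- length(parse$sub_roots) >= 1L &&
    all(parse$pbond[parse$sub_roots] == 1L) &&
    !parse$beta_ring_closure
  render_iso <- function(iso) {
    if (!stereo_ok)
      return(paste0("c1ccccc1C=C", render_substituent(state$tokens, parse)))
    # "/" places the first-written substituent anti to the aryl group, in
    # both the chain form Ph/C=C/S1 and the branch form Ph/C=C(/S1)S2
    m <- if (iso == "E") "/" else "\\"
    paste0("c1ccccc1/C=C", render_substituent(state$tokens, parse, m))
  }
  e <- render_iso("E"); z <- render_iso("Z")
  list(e = e, z = z, graph = graph,
       sub_roots = parse$sub_roots,
       stereo = !identical(e, z),
       parse = parse)
}

#' Full-molecule P-SMILES rendering
#'
#' Writes the complete molecule (backbone plus state) in P-SMILES notation,
#' as used for reporting: e.g. the state \code{"C(EC)F"} on the styrene
#' scaffold renders \code{"Ca1C(CCCCa1)CECC(EC)F"} for the E isomer.
#'
#' @param state A \code{psmiles_state} or character scalar.
#' @param isomer \code{"E"} or \code{"Z"}.
#' @param scaffold A [scaffold_styrene()] spec.
#' @return Character scalar.
#' @export
full_psmiles <- function(state, isomer = c("E", "Z"),
                         scaffold = scaffold_styrene()) {
  isomer <- match.arg(isomer)
  if (is.character(state)) state <- tokenize(state)
  paste0(sprintf(scaffold$backbone_psmiles, isomer), state$text)
}
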