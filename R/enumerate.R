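# Exhaustive enumeration of bounded token spaces and a transfer-style
# dynamic program that counts syntactically valid states without
# materializing the space.

#' Enumerate a bounded P-SMILES space
#'
#' Streams every nonempty symbol sequence of length at most \code{max_tokens}
#' exactly once, in lexicographic order over symbol indices, labelling each
#' with a validity predicate.
#'
#' @param vocab A [psmiles_vocab()].
#' @param max_tokens Maximum sequence length.
#' @param validity One of \code{"syntax"} (label with
#'   [is_syntactically_valid()]), \code{"none"} (label everything TRUE), or a
#'   predicate function over a state string.
#' @param cap Enumeration budget; if the projected size
#'   [count_combinations()] exceeds it, a \code{BudgetError} is raised.
#' @return A data.frame of class \code{space_enumeration} with columns
#'   \code{state}, \code{token_count}, \code{syntactic_valid}, and attributes
#'   \code{total} and \code{max_tokens}.
#' @examples
#' sp <- enumerate_space(max_tokens = 2)
#' nrow(sp)      # 132 = 11 + 11^2
#' @export
enumerate_space <- function(vocab = psmiles_vocab(), max_tokens,
                            validity = "syntax", cap = 2e6) {
  total <- count_combinations(vocab$size, max_tokens)
  if (total > cap)
    stop("BudgetError: enumeration of ", total,
         " sequences exceeds the cap of ", cap, call. = FALSE)
  pred <- if (is.function(validity)) validity
          else if (identical(validity, "none")) function(s) TRUE
          else function(s) is_syntactically_valid(s, vocab)
  states <- character(0); lens <- integer(0)
  v <- vocab$size
  for (l in seq_len(max_tokens)) {
    # lexicographic over symbol indices: build v^l strings, first index slowest
    grid <- matrix("", nrow = v^l, ncol = l)
    for (pos in seq_len(l)) {
      reps <- v^(l - pos)
      grid[, pos] <- rep(vocab$alphabet, each = reps, length.out = v^l)
    }
    states <- c(states, apply(grid, 1L, paste, collapse = ""))
    lens <- c(lens, rep.int(l, v^l))
  }
  valid <- vapply(states, pred, logical(1), USE.NAMES = FALSE)
  out <- data.frame(state = states, token_count = lens,
                    syntactic_valid = valid, stringsAsFactors = FALSE)
  attr(out, "total") <- total
  attr(out, "max_tokens") <- max_tokens
  class(out) <- c("space_enumeration", class(out))
  out
}

# ---------------------------------------------------------------------------
# Transfer dynamic program over the grammar automaton.
#
# Symbols collapse into behavioural classes: C/N (aromatizable atoms, x2),
# O/F (other atoms, x2), E/Z/# (bond symbols, x3), "1", "a1", "(", ")".
# The automaton state tracks exactly what the parser needs about the future:
# a pending bond, the last-was-"(" flag, the class of the current atom, the
# open-branch frames (with snapshots for restoring ring-label distances),
# and for each open ring label its tree distance to the current atom plus,
# for the aromatic label, whether the connecting path can still be
# aromatized.  Identical automaton states are merged with summed weights,
# which keeps the count of live states small at any length.

census_new_state <- function() {
  list(pend = FALSE, lp = FALSE, cur = "S",
       frames = list(), fd = numeric(0), fs = logical(0),
       m1 = NULL, ma = NULL)
}

census_digest <- function(st) {
  fr <- if (length(st$frames))
    paste(vapply(st$frames, function(f)
      paste(f$par, f$ne, paste(f$fd, collapse = ","),
            paste(f$fs, collapse = ","),
            census_marker_digest(f$m1), census_marker_digest(f$ma),
            sep = ";"), character(1)), collapse = "|")
  else ""
  paste(st$pend, st$lp, st$cur,
        paste(st$fd, collapse = ","), paste(st$fs, collapse = ","),
        census_marker_digest(st$m1), census_marker_digest(st$ma),
        fr, sep = "#")
}

census_marker_digest <- function(m) {
  if (is.null(m)) return(".")
  paste(m$d, m$bd, paste(m$mf, collapse = ","),
        if (!is.null(m$pathok)) m$pathok else "",
        if (!is.null(m$mpok)) paste(m$mpok, collapse = ",") else "",
        sep = ":")
}

# One-symbol transition; returns the new state or NULL when dead.
census_step <- function(st, cls) {
  if (cls %in% c("A", "X")) {                      # atom (C/N or O/F)
    single <- !st$pend
    prev <- st$cur
    ext_ok <- single && prev == "A"
    if (!is.null(st$m1)) st$m1$d <- st$m1$d + 1
    if (!is.null(st$ma)) {
      st$ma$d <- st$ma$d + 1
      st$ma$pathok <- st$ma$pathok && ext_ok
    }
    if (length(st$fd)) { st$fd <- st$fd + 1; st$fs <- st$fs & ext_ok }
    if (length(st$frames)) st$frames[[length(st$frames)]]$ne <- TRUE
    st$cur <- cls
    st$pend <- FALSE; st$lp <- FALSE
    st
  } else if (cls == "B") {                         # E / Z / #
    if (st$pend) return(NULL)
    st$pend <- TRUE; st$lp <- FALSE
    st
  } else if (cls == "(") {
    if (st$pend || st$lp) return(NULL)
    st$frames[[length(st$frames) + 1L]] <-
      list(par = st$cur, ne = FALSE, fd = st$fd, fs = st$fs,
           m1 = st$m1, ma = st$ma)
    st$fd <- c(st$fd, 0); st$fs <- c(st$fs, TRUE)
    st$lp <- TRUE
    st
  } else if (cls == ")") {
    k <- length(st$frames)
    if (!k || st$pend || st$lp) return(NULL)
    f <- st$frames[[k]]
    if (!f$ne) return(NULL)
    st$cur <- f$par
    st$fd <- f$fd; st$fs <- f$fs
    st$m1 <- census_restore_marker(st$m1, f$m1, k)
    st$ma <- census_restore_marker(st$ma, f$ma, k)
    st$frames[[k]] <- NULL
    st$lp <- FALSE
    st
  } else if (cls == "1") {
    if (st$pend || st$lp) return(NULL)
    if (is.null(st$m1)) {
      st$m1 <- list(d = 0, bd = length(st$frames), mf = st$fd)
    } else {
      if (st$m1$d < 2) return(NULL)                # same atom / two-ring
      st$m1 <- NULL
    }
    st$lp <- FALSE
    st
  } else if (cls == "a1") {
    if (st$pend || st$lp) return(NULL)
    if (st$cur != "A") return(NULL)                # needs an aromatizable atom
    if (is.null(st$ma)) {
      st$ma <- list(d = 0, bd = length(st$frames), mf = st$fd,
                    pathok = TRUE, mpok = st$fs)
    } else {
      if (st$ma$d != 5 || !st$ma$pathok) return(NULL)
      st$ma <- NULL
    }
    st$lp <- FALSE
    st
  } else stop("bad class")
}

census_restore_marker <- function(m, snap, k) {
  if (is.null(m)) return(NULL)
  if (k > m$bd) return(snap)                       # marker predates the frame
  m$d <- m$mf[k]                                   # marker born inside it
  if (!is.null(m$pathok)) m$pathok <- m$mpok[k]
  m
}

census_is_final <- function(st)
  !st$pend && !length(st$frames) && is.null(st$m1) && is.null(st$ma)

#' Count syntactically valid states by dynamic programming
#'
#' Counts the grammar-valid symbol sequences of each length up to
#' \code{max_tokens} by a transfer dynamic program over the grammar
#' automaton, without enumerating the space. Agreement with brute-force
#' enumeration is part of the test suite. Supported up to length 8 (beyond
#' that, interactions between multiple closed rings are not tracked).
#'
#' @param max_tokens Maximum sequence length (<= 8).
#' @return A list with \code{per_length} (valid counts by length),
#'   \code{valid} (cumulative count), and \code{total}
#'   (= [count_combinations()] of the 11-symbol alphabet).
#' @examples
#' count_syntactic_valid(4)$valid
#' @export
count_syntactic_valid <- function(max_tokens) {
  stopifnot(max_tokens >= 1, max_tokens <= 8)
  classes <- c("A", "X", "B", "1", "a1", "(", ")")
  mult    <- c(  2,   2,   3,   1,    1,   1,   1)
  start <- census_new_state()
  states <- list(start); weights <- c(1)
  names(states) <- census_digest(start)
  per_length <- numeric(max_tokens)
  for (l in seq_len(max_tokens)) {
    nxt <- list(); wts <- numeric(0)
    for (s in seq_along(states)) {
      st <- states[[s]]; w <- weights[s]
      for (ci in seq_along(classes)) {
        ns <- census_step(st, classes[ci])
        if (is.null(ns)) next
        key <- census_digest(ns)
        pos <- match(key, names(nxt))
        if (is.na(pos)) {
          nxt[[key]] <- ns; wts <- c(wts, w * mult[ci])
        } else {
          wts[pos] <- wts[pos] + w * mult[ci]
        }
      }
    }
    states <- nxt; weights <- wts
    per_length[l] <- sum(weights[vapply(states, census_is_final, logical(1))])
  }
  list(per_length = per_length, valid = sum(per_length),
       total = count_combinations(11, max_tokens))
}

# ---------------------------------------------------------------------------
# Conversion-level well-formedness (the census notion of syntactic validity).

#' Well-formedness of a P-SMILES state
#'
#' The weak, conversion-level syntax check applied as the first stage of the
#' reward routine: parentheses must be balanced (a branch is never closed
#' before it opens and all branches are closed at the end) and each ring
#' label (\code{1} and \code{a1}) must occur an even number of times. No
#' other rule is applied; in particular dangling bond symbols and empty
#' branches pass. States failing the stricter decodable grammar
#' ([is_syntactically_valid()]) are weeded out further down the validity
#' cascade, mirroring the split between a converter-level syntax check and a
#' chemistry-toolkit parse.
#'
#' @param state A \code{psmiles_state} or character scalar.
#' @param vocab A [psmiles_vocab()].
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' is_well_formed("C(")    # FALSE (unclosed branch)
#' is_well_formed("CC=")   # TRUE at this level (dies later in the cascade)
#' @export
is_well_formed <- function(state, vocab = psmiles_vocab()) {
  if (is.character(state)) {
    state <- tryCatch(tokenize(state, vocab), error = function(e) NULL)
    if (is.null(state)) return(FALSE)
  }
  depth <- 0L
  for (tok in state$tokens) {
    if (tok == "(") depth <- depth + 1L
    else if (tok == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    }
  }
  depth == 0L &&
    sum(state$tokens == "1") %% 2L == 0L &&
    sum(state$tokens == "a1") %% 2L == 0L
}

#' Count well-formed states by dynamic programming
#'
#' Counts the [is_well_formed()] symbol sequences of length up to
#' \code{max_tokens} over the 11-symbol alphabet by an exact transfer matrix
#' over (branch depth, ring-label parities). This is the syntactic-validity
#' census of a bounded space: 3,770 at 4 tokens and 2,430,845 at 7 tokens.
#'
#' @param max_tokens Maximum sequence length.
#' @return A list with \code{per_length}, \code{valid} (cumulative) and
#'   \code{total} (all combinations).
#' @examples
#' count_well_formed(4)$valid    # 3770
#' @export
count_well_formed <- function(max_tokens) {
  stopifnot(max_tokens >= 1)
  L <- max_tokens
  st <- array(0, dim = c(L + 1L, 2L, 2L))
  st[1L, 1L, 1L] <- 1
  per <- numeric(L)
  for (l in seq_len(L)) {
    ns <- array(0, dim = c(L + 1L, 2L, 2L))
    for (d in 0:L) for (p1 in 0:1) for (pa in 0:1) {
      w <- st[d + 1L, p1 + 1L, pa + 1L]
      if (w == 0) next
      ns[d + 1L, p1 + 1L, pa + 1L] <- ns[d + 1L, p1 + 1L, pa + 1L] + w * 7  # 4 atoms + 3 bonds
      if (d < L) ns[d + 2L, p1 + 1L, pa + 1L] <- ns[d + 2L, p1 + 1L, pa + 1L] + w
      if (d > 0) ns[d, p1 + 1L, pa + 1L] <- ns[d, p1 + 1L, pa + 1L] + w
      ns[d + 1L, 2L - p1, pa + 1L] <- ns[d + 1L, 2L - p1, pa + 1L] + w
      ns[d + 1L, p1 + 1L, 2L - pa] <- ns[d + 1L, p1 + 1L, 2L - pa] + w
    }
    st <- ns
    per[l] <- st[1L, 1L, 1L]
  }
  list(per_length = per, valid = sum(per),
       total = count_combinations(11, max_tokens))
}
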