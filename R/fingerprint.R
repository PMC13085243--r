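# Structural fingerprints for the diversity reward.  Fingerprints are bit
# SETS: integer vectors of set bit positions.  Two schemes satisfy the
# contract: a compact in-process structural-key dictionary computed on the
# decoded graph (default for toy-fidelity runs, no subprocess per molecule)
# and the 166-bit MACCS keys through the Open Babel CLI.

#' Compact structural-key fingerprint
#'
#' A fixed dictionary of structural-feature bits (element counts, bond
#' patterns, ring and branching features, substituent composition at small
#' depths) evaluated on a decoded molecular graph. MACCS-style structural
#' keys at desk scale: deterministic, in-process and fast enough to
#' fingerprint full bounded spaces.
#'
#' @param decoded Result of [decode_to_smiles()] (or a state / character
#'   scalar, decoded on the fly).
#' @return Sorted integer vector of set bit positions (the bit set).
#' @export
structural_keys <- function(decoded) {
  if (!inherits(decoded, "list") || is.null(decoded$parse))
    decoded <- decode_to_smiles(decoded)
  p <- decoded$parse
  g <- decoded$graph
  elem <- p$elem
  bits <- integer(0)
  set <- function(b, cond) if (isTRUE(cond)) bits <<- c(bits, b)
  cnt <- function(e) sum(elem == e)
  # composition keys 1-16
  set(1L, cnt("N") >= 1); set(2L, cnt("N") >= 2)
  set(3L, cnt("O") >= 1); set(4L, cnt("O") >= 2)
  set(5L, cnt("F") >= 1); set(6L, cnt("F") >= 2); set(7L, cnt("F") >= 3)
  set(8L, cnt("C") >= 1); set(9L, cnt("C") >= 3); set(10L, cnt("C") >= 5)
  n <- length(elem)
  set(11L, n >= 2); set(12L, n >= 4); set(13L, n >= 6); set(14L, n >= 8)
  set(15L, sum(p$pbond == 2L) >= 1); set(16L, sum(p$pbond == 2L) >= 2)
  # bond-pattern keys 17-40 (tree bonds of the substituent)
  pair <- function(a, b, o) {
    any(vapply(seq_len(n), function(k) {
      pa <- p$parent[k]
      pe <- if (pa == 0L) "C" else elem[pa]     # attachment atom is carbon
      p$pbond[k] == o && ((elem[k] == a && pe == b) || (elem[k] == b && pe == a))
    }, logical(1)))
  }
  set(17L, pair("C", "F", 1L)); set(18L, pair("C", "O", 1L))
  set(19L, pair("C", "N", 1L)); set(20L, pair("O", "N", 1L))
  set(21L, pair("C", "C", 2L)); set(22L, pair("C", "O", 2L))
  set(23L, pair("C", "N", 2L)); set(24L, sum(p$pbond == 3L) >= 1)
  set(25L, pair("C", "C", 3L)); set(26L, pair("C", "N", 3L))
  h <- implicit_hydrogens(g)
  ns <- length(g$elem) - length(elem)            # scaffold offset
  set(27L, any(elem == "O" & h[seq_len(n) + ns] > 0))   # hydroxyl
  set(28L, any(elem == "N" & h[seq_len(n) + ns] > 0))   # amine H
  deg <- tabulate(c(p$parent[p$parent != 0L], seq_len(n)), nbins = max(n, 1L))
  set(29L, any(deg >= 3)); set(30L, any(deg >= 4))
  set(31L, length(p$ring_i) >= 1)                       # any extra ring
  set(32L, any(p$aromatic))                             # aromatic substituent
  set(33L, p$beta_ring_closure)
  # substituent-shape keys 41-56: element at depths 1..3 on each side
  roots <- p$sub_roots
  side <- function(r) if (length(roots) >= r)
    substituent_atoms(p, roots[r]) else list(elem = character(0), depth = integer(0))
  base <- 40L
  for (r in 1:2) {
    s <- side(r)
    for (d in 1:3) {
      at <- s$elem[s$depth == d]
      for (e in c("C", "N", "O", "F"))
        set(base + (r - 1L) * 12L + (d - 1L) * 4L + match(e, c("C", "N", "O", "F")),
            e %in% at)
    }
  }
  set(65L, length(roots) >= 2)
  sort(unique(bits))
}

#' MACCS 166-bit fingerprint via Open Babel
#'
#' Computes the MACCS structural keys of a SMILES string by calling the
#' \command{obabel} command-line tool and parsing its hexadecimal output.
#'
#' @param smiles A SMILES string.
#' @return Sorted integer vector of set bit positions (1-based).
#' @export
maccs_fingerprint <- function(smiles) {
  if (Sys.which("obabel") == "")
    stop("EngineUnavailable: obabel not on PATH", call. = FALSE)
  out <- suppressWarnings(
    system2("obabel", c(paste0("-:", shQuote(smiles, type = "sh")), "-ofpt",
                        "-xfMACCS", "-xh"),
            stdout = TRUE, stderr = FALSE))
  hex <- grep("^[0-9a-fA-F ]+$", out, value = TRUE)
  words <- unlist(strsplit(paste(hex, collapse = " "), "\\s+"))
  words <- words[nzchar(words)]
  bits <- integer(0)
  # Open Babel prints 32-bit words, most significant first
  nwords <- length(words)
  for (w in seq_along(words)) {
    v <- strtoi(substring(words[w], 1:8, 1:8), 16L)
    for (nib in 1:8) {
      for (b in 0:3) {
        if (bitwAnd(v[nib], bitwShiftL(1L, 3L - b)) != 0L)
          bits <- c(bits, (nwords - w) * 32L + (8L - nib) * 4L + (4L - b))
      }
    }
  }
  sort(bits)
}

#' Hexadecimal serialization of a bit set (for run logs)
#' @param bits Integer vector of set bit positions (1-based).
#' @param nbits Total fingerprint width.
#' @return Character scalar of hex digits, most significant first.
#' @export
fingerprint_hex <- function(bits, nbits = 166L) {
  words <- ceiling(nbits / 4)
  v <- integer(words)
  for (b in bits) {
    w <- words - ((b - 1L) %/% 4L)
    v[w] <- bitwOr(v[w], bitwShiftL(1L, (b - 1L) %% 4L))
  }
  paste(sprintf("%x", v), collapse = "")
}
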