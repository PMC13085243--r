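#' The P-SMILES generation alphabet
#'
#' P-SMILES is a compact SMILES-derived encoding for substituents grafted onto
#' a fixed scaffold. Every structural moiety is written with at most two
#' characters: single-character symbols for atoms (C, N, O, F), bond types
#' (\code{E}, \code{Z} for the two double-bond geometries, \code{#} for a
#' triple bond), the aliphatic ring-closure digit \code{1} and the two branch
#' delimiters \code{(} and \code{)}; plus the two-character digraph \code{a1},
#' an aromatic ring-closure label used in pairs like a SMILES ring digit.
#'
#' The generation alphabet therefore has 11 symbols. Sequences of at most
#' \code{L} symbols span the bounded chemical spaces used throughout the
#' package: \eqn{\sum_{l=1}^{L} 11^l} combinations.
#'
#' @return An object of class \code{psmiles_vocab}: a list with elements
#'   \code{single} (the nine one-character symbols), \code{double} (the
#'   digraphs, here only \code{"a1"}), \code{alphabet} (all 11 symbols in
#'   enumeration order), \code{atoms}, \code{bonds}, and \code{size}.
#' @examples
#' v <- psmiles_vocab()
#' v$size                      # 11
#' count_combinations(v$size, 6)
#' @export
psmiles_vocab <- function() {
  single <- c("E", "Z", "1", "#", "C", "N", "O", "F", "(", ")")
  double <- "a1"
  alphabet <- c(single, double)
  structure(list(
    single   = single,
    double   = double,
    alphabet = alphabet,
    atoms    = c("C", "N", "O", "F"),
    bonds    = c("E", "Z", "#"),
    size     = length(alphabet)
  ), class = "psmiles_vocab")
}

#' @export
print.psmiles_vocab <- function(x, ...) {
  cat("P-SMILES vocabulary:", x$size, "symbols\n")
  cat("  singles:", paste(x$single, collapse = " "), "\n")
  cat("  digraphs:", paste(x$double, collapse = " "), "\n")
  invisible(x)
}

#' Tokenize a P-SMILES string
#'
#' Segments a character string into vocabulary symbols by greedy longest
#' match (the digraph \code{a1} is matched before the single characters).
#' Tokenization is purely lexical: pairing of ring labels and branch
#' delimiters is checked later by [is_syntactically_valid()].
#'
#' @param text Character scalar, the rendered P-SMILES state (may be \code{""}).
#' @param vocab A [psmiles_vocab()] object.
#' @return An object of class \code{psmiles_state}: list with \code{text},
#'   \code{tokens} (character vector of symbols in order) and
#'   \code{token_count}.
#' @examples
#' tokenize("C(EC)F")$token_count   # 6
#' @export
tokenize <- function(text, vocab = psmiles_vocab()) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  toks <- character(0)
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    matched <- FALSE
    for (d in vocab$double) {
      w <- nchar(d)
      if (i + w - 1L <= n && substr(text, i, i + w - 1L) == d) {
        toks <- c(toks, d); i <- i + w; matched <- TRUE; break
      }
    }
    if (!matched) {
      ch <- substr(text, i, i)
      if (!ch %in% vocab$single)
        stop("UnknownToken: character '", ch, "' at position ", i,
             " is outside the P-SMILES vocabulary", call. = FALSE)
      toks <- c(toks, ch); i <- i + 1L
    }
  }
  psmiles_state(toks, vocab)
}

#' Construct a P-SMILES state from a symbol sequence
#'
#' @param tokens Character vector of vocabulary symbols (possibly empty).
#' @param vocab A [psmiles_vocab()] object.
#' @return A \code{psmiles_state} object.
#' @export
psmiles_state <- function(tokens = character(0), vocab = psmiles_vocab()) {
  tokens <- as.character(tokens)
  bad <- setdiff(tokens, vocab$alphabet)
  if (length(bad))
    stop("UnknownToken: ", paste(unique(bad), collapse = ", "), call. = FALSE)
  structure(list(
    text = paste(tokens, collapse = ""),
    tokens = tokens,
    token_count = length(tokens)
  ), class = "psmiles_state")
}

#' @export
print.psmiles_state <- function(x, ...) {
  cat("<psmiles_state> \"", x$text, "\" (", x$token_count, " tokens)\n",
      sep = "")
  invisible(x)
}

#' Render a P-SMILES state back to text
#' @param state A \code{psmiles_state}.
#' @return Character scalar; \code{tokenize(render(s))} recovers \code{s}.
#' @export
render <- function(state) {
  stopifnot(inherits(state, "psmiles_state"))
  state$text
}

#' Size of a bounded token space
#'
#' Number of nonempty symbol sequences of length at most \code{max_tokens}
#' over an alphabet of \code{alphabet_size} symbols:
#' \eqn{\sum_{l=1}^{L} v^l}. This is the total-combination count of a bounded
#' chemical space before any validity filtering.
#'
#' @param alphabet_size Integer >= 1.
#' @param max_tokens Integer >= 0; 0 yields 0.
#' @return A double holding the exact integer count.
#' @examples
#' count_combinations(11, 6)   # 1948716
#' count_combinations(11, 7)   # 21435887
#' @export
count_combinations <- function(alphabet_size, max_tokens) {
  stopifnot(alphabet_size >= 1, max_tokens >= 0)
  if (max_tokens == 0) return(0)
  sum(as.numeric(alphabet_size)^(seq_len(max_tokens)))
}
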