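# The hierarchical generator: a master policy chooses among {add single
# token, add double (paired) token, stop}; position predictors choose
# insertion slots; token generators choose vocabulary entries; a value
# network scores states. All six models share the transformer architecture
# and see the current P-SMILES string as input (BOS-prefixed symbol ids).
# Generation is a masked-language-model-style modification policy: tokens
# can be inserted at any slot of the current string, so a carbon chain can
# be branched after its construction by a single paired insertion.

MASTER_ACTIONS <- c("single", "double", "stop")

#' Initialize the policy stack
#'
#' Six transformer models: master (3 actions), single/double position
#' predictors, single/double token generators, and the value network.
#' Parameters are Glorot-uniform initialized.
#'
#' @param hp A [psrl_config()].
#' @param vocab A [psmiles_vocab()].
#' @return A \code{policy_stack}.
#' @export
psrl_agent <- function(hp = psrl_config(), vocab = psmiles_vocab()) {
  V <- vocab$size + 1L              # + BOS
  maxlen <- hp$L + 2L
  nslots <- hp$L + 1L
  mk <- function(nout) nn_init(V, maxlen, d = hp$d_model, h = hp$n_heads,
                               nlayer = hp$n_layers, nout = nout)
  single_tokens <- setdiff(vocab$single, c("(", ")"))
  double_tokens <- c("a1", "()")
  structure(list(
    master = mk(3L),
    pos_s = mk(nslots),
    tok_s = mk(length(single_tokens)),
    pos_d = mk(2L * nslots),
    tok_d = mk(length(double_tokens)),
    value = mk(1L),
    single_tokens = single_tokens,
    double_tokens = double_tokens,
    vocab = vocab, nslots = nslots
  ), class = "policy_stack")
}

#' @export
print.policy_stack <- function(x, ...) {
  dm <- attr(x$master, "dims")
  cat("<policy_stack> 5 policies + value network; d =", dm$d,
      ", layers =", dm$nlayer, ", heads =", dm$h, "\n")
  invisible(x)
}

# BOS-prefixed symbol ids of a state (tokens = character vector of symbols)
state_ids <- function(tokens, vocab) {
  c(vocab$size + 1L, match(tokens, vocab$alphabet))
}

#' Per-policy action masks
#'
#' The master's add actions are masked at the token budget (a single needs
#' one free slot, a paired insertion two and at least one existing token to
#' enclose); stop is always available, so no mask is ever all-false.
#' Position masks restrict insertion slots to the current gaps; the double
#' position's second slot must lie strictly after the first.
#'
#' @param tokens Character vector of state symbols.
#' @param hp A [psrl_config()].
#' @param nslots Number of position outputs (L + 1).
#' @return List of logical vectors: \code{master}, \code{pos_s},
#'   \code{pos_d1}, and a function \code{pos_d2(i)} of the first slot.
#' @export
action_masks <- function(tokens, hp, nslots = hp$L + 1L) {
  tc <- length(tokens)
  master <- c(single = tc + 1L <= hp$L,
              double = tc + 2L <= hp$L && tc >= 1L,
              stop = TRUE)
  pos_s <- seq_len(nslots) <= tc + 1L          # slots 0..tc
  pos_d1 <- seq_len(nslots) <= tc              # first slot 0..tc-1
  pos_d2 <- function(i) {                      # second slot i+1..tc
    m <- seq_len(nslots) <= tc + 1L
    m[seq_len(min(i + 1L, nslots))] <- FALSE
    m
  }
  list(master = master, pos_s = pos_s, pos_d1 = pos_d1, pos_d2 = pos_d2)
}

# sample from masked logits; returns action index, its logprob, and the
# masked log-probability vector
sample_masked <- function(logits, mask) {
  lp <- masked_log_softmax(logits, mask)
  pr <- exp(lp); pr[!mask] <- 0
  a <- sample.int(length(pr), 1L, prob = pr)
  list(action = a, logp = lp[a], logps = lp)
}

#' Value estimate of a state
#' @param stack A [psrl_agent()] stack.
#' @param tokens State symbols (character vector) or a \code{psmiles_state}.
#' @return Finite scalar value estimate.
#' @export
evaluate_value <- function(stack, tokens) {
  if (inherits(tokens, "psmiles_state")) tokens <- tokens$tokens
  nn_forward(stack$value, state_ids(tokens, stack$vocab))$logits[1L]
}

# insert element(s) into a token vector at gap positions (0-based slots)
insert_at <- function(tokens, what, slot) {
  append(tokens, what, after = slot)
}

#' Generate one episode
#'
#' Runs the hierarchical generation loop from the empty state: the master
#' picks an action; singles sample an insertion slot and a one-character
#' token; doubles sample two slots (second strictly after the first) and a
#' paired token ("()" or "a1") whose two halves are placed at the two slots;
#' stop terminates. Each policy decision is recorded with its input, the
#' sampled action, its log-probability and the value estimate of the state,
#' grouped into transitions for one-step temporal-difference learning.
#'
#' @param stack A [psrl_agent()].
#' @param hp A [psrl_config()].
#' @return A \code{trajectory}: list with \code{records} (one per policy
#'   decision), \code{state} (final \code{psmiles_state}), \code{T}
#'   (number of master transitions before stop), and \code{empty}
#'   (terminated with zero tokens).
#' @export
generate_episode <- function(stack, hp = psrl_config()) {
  vocab <- stack$vocab
  tokens <- character(0)
  records <- list()
  transition <- 0L
  repeat {
    transition <- transition + 1L
    ids <- state_ids(tokens, vocab)
    v_here <- nn_forward(stack$value, ids)$logits[1L]
    masks <- action_masks(tokens, hp, stack$nslots)
    m <- nn_forward(stack$master, ids)
    sm <- sample_masked(m$logits, masks$master)
    rec0 <- list(model = "master", ids = ids, action = sm$action,
                 mask = masks$master, logp = sm$logp,
                 v = v_here, transition = transition)
    act <- MASTER_ACTIONS[sm$action]
    new_records <- list(rec0)
    if (act == "single") {
      ps <- sample_masked(nn_forward(stack$pos_s, ids)$logits, masks$pos_s)
      ts <- sample_masked(nn_forward(stack$tok_s, ids)$logits,
                          rep(TRUE, length(stack$single_tokens)))
      new_records <- c(new_records, list(
        list(model = "pos_s", ids = ids, action = ps$action,
             mask = masks$pos_s, logp = ps$logp, v = v_here,
             transition = transition),
        list(model = "tok_s", ids = ids, action = ts$action,
             mask = rep(TRUE, length(stack$single_tokens)), logp = ts$logp,
             v = v_here, transition = transition)))
      tokens <- insert_at(tokens, stack$single_tokens[ts$action],
                          ps$action - 1L)
    } else if (act == "double") {
      pd <- nn_forward(stack$pos_d, ids)
      l1 <- pd$logits[seq_len(stack$nslots)]
      l2 <- pd$logits[stack$nslots + seq_len(stack$nslots)]
      p1 <- sample_masked(l1, masks$pos_d1)
      m2 <- masks$pos_d2(p1$action - 1L)
      p2 <- sample_masked(l2, m2)
      td <- sample_masked(nn_forward(stack$tok_d, ids)$logits,
                          rep(TRUE, length(stack$double_tokens)))
      new_records <- c(new_records, list(
        list(model = "pos_d", ids = ids, action = p1$action,
             action2 = p2$action, mask = masks$pos_d1, mask2 = m2,
             logp = p1$logp + p2$logp, v = v_here, transition = transition),
        list(model = "tok_d", ids = ids, action = td$action,
             mask = rep(TRUE, length(stack$double_tokens)), logp = td$logp,
             v = v_here, transition = transition)))
      pair <- if (stack$double_tokens[td$action] == "()") c("(", ")")
              else c("a1", "a1")
      i <- p1$action - 1L; j <- p2$action - 1L
      tokens <- insert_at(tokens, pair[1L], i)
      tokens <- insert_at(tokens, pair[2L], j + 1L)   # shifted by the first
    }
    records <- c(records, new_records)
    if (act == "stop") break
  }
  # next-state value per transition (terminal successor value is 0)
  structure(list(records = records,
                 state = psmiles_state(tokens, vocab),
                 T = transition - 1L,
                 empty = length(tokens) == 0L),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$records), " decisions -> \"",
      x$state$text, "\" (T = ", x$T, ")\n", sep = "")
  invisible(x)
}

#' Save / load a policy stack
#'
#' Serializes the six networks (and their architecture attributes) as one
#' versioned archive.
#'
#' @param stack A [psrl_agent()] stack.
#' @param path File path.
#' @return \code{path} (write) or the restored \code{policy_stack} (read).
#' @export
save_agent <- function(stack, path) {
  stopifnot(inherits(stack, "policy_stack"))
  saveRDS(list(schema = 1L, stack = stack), path)
  invisible(path)
}

#' @rdname save_agent
#' @export
load_agent <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, 1L))
    stop("unsupported checkpoint schema: ", obj$schema, call. = FALSE)
  obj$stack
}
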