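# A small transformer encoder with explicit backpropagation, sized for
# P-SMILES sequences (a dozen tokens). Each policy and the value network is
# one such model: token + learned positional embeddings, post-norm
# multi-head self-attention blocks with a two-layer feed-forward, mean
# pooling and a linear head. Written in plain matrix algebra; gradients are
# checked against finite differences in the test suite.

glorot <- function(fan_in, fan_out, rng_n = fan_in * fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(rng_n, -lim, lim), fan_in, fan_out)
}

#' Initialize a transformer model
#'
#' Parameters are drawn from the Glorot uniform distribution (biases and
#' layer-norm offsets zero, layer-norm gains one).
#'
#' @param vocab_size Token embedding count (symbols + BOS).
#' @param maxlen Context length.
#' @param d Model width; \code{h} heads; \code{nlayer} blocks.
#' @param nout Output dimension of the linear head.
#' @param h,nlayer Heads and depth.
#' @return A list of parameter matrices (class \code{psrl_nn}).
#' @export
nn_init <- function(vocab_size, maxlen, d = 64L, h = 4L, nlayer = 2L, nout) {
  stopifnot(d %% h == 0)
  dff <- 2L * d
  p <- list(E = glorot(vocab_size, d), P = glorot(maxlen, d))
  for (l in seq_len(nlayer)) {
    p[[paste0("Wq", l)]] <- glorot(d, d)
    p[[paste0("Wk", l)]] <- glorot(d, d)
    p[[paste0("Wv", l)]] <- glorot(d, d)
    p[[paste0("Wo", l)]] <- glorot(d, d)
    p[[paste0("bo", l)]] <- matrix(0, 1, d)
    p[[paste0("g1", l)]] <- matrix(1, 1, d)
    p[[paste0("c1", l)]] <- matrix(0, 1, d)
    p[[paste0("W1", l)]] <- glorot(d, dff)
    p[[paste0("b1", l)]] <- matrix(0, 1, dff)
    p[[paste0("W2", l)]] <- glorot(dff, d)
    p[[paste0("b2", l)]] <- matrix(0, 1, d)
    p[[paste0("g2", l)]] <- matrix(1, 1, d)
    p[[paste0("c2", l)]] <- matrix(0, 1, d)
  }
  p$Wh <- glorot(d, nout)
  p$bh <- matrix(0, 1, nout)
  attr(p, "dims") <- list(d = d, h = h, nlayer = nlayer, nout = nout,
                          maxlen = maxlen, vocab = vocab_size)
  class(p) <- "psrl_nn"
  p
}

ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  sd <- sqrt(v + eps)
  xhat <- xc / sd
  list(Y = sweep(xhat, 2, as.numeric(g), "*") +
         matrix(as.numeric(b), nrow(X), ncol(X), byrow = TRUE),
       xhat = xhat, sd = sd)
}

ln_bwd <- function(dY, cache, g) {
  gv <- as.numeric(g)
  dxhat <- sweep(dY, 2, gv, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- (dxhat - m1 - cache$xhat * m2) / cache$sd
  dg <- matrix(colSums(dY * cache$xhat), 1)
  db <- matrix(colSums(dY), 1)
  list(dX = dX, dg = dg, db = db)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Forward pass of the transformer
#'
#' @param p A [nn_init()] parameter list.
#' @param ids Integer token ids (1-based), length >= 1.
#' @return List with \code{logits} (length nout) and \code{cache} for
#'   [nn_backward()].
#' @export
nn_forward <- function(p, ids) {
  dm <- attr(p, "dims")
  n <- length(ids)
  d <- dm$d; h <- dm$h; dk <- d %/% h
  X <- p$E[ids, , drop = FALSE] + p$P[seq_len(n), , drop = FALSE]
  cache <- list(ids = ids, X0 = X, layers = vector("list", dm$nlayer))
  for (l in seq_len(dm$nlayer)) {
    Q <- X %*% p[[paste0("Wq", l)]]
    K <- X %*% p[[paste0("Wk", l)]]
    V <- X %*% p[[paste0("Wv", l)]]
    O <- matrix(0, n, d)
    A <- vector("list", h)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1L) * dk + 1L):(hh * dk)
      S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk)
      A[[hh]] <- softmax_rows(S)
      O[, cols] <- A[[hh]] %*% V[, cols, drop = FALSE]
    }
    XO <- O %*% p[[paste0("Wo", l)]] +
      matrix(as.numeric(p[[paste0("bo", l)]]), n, d, byrow = TRUE)
    R1 <- X + XO
    l1 <- ln_fwd(R1, p[[paste0("g1", l)]], p[[paste0("c1", l)]])
    H1 <- l1$Y %*% p[[paste0("W1", l)]] +
      matrix(as.numeric(p[[paste0("b1", l)]]), n, 2L * d, byrow = TRUE)
    Hr <- pmax(H1, 0)
    FF <- Hr %*% p[[paste0("W2", l)]] +
      matrix(as.numeric(p[[paste0("b2", l)]]), n, d, byrow = TRUE)
    R2 <- l1$Y + FF
    l2 <- ln_fwd(R2, p[[paste0("g2", l)]], p[[paste0("c2", l)]])
    cache$layers[[l]] <- list(Xin = X, Q = Q, K = K, V = V, A = A, O = O,
                              l1 = l1, H1 = H1, Hr = Hr, l2 = l2)
    X <- l2$Y
  }
  pool <- colMeans(X)
  logits <- as.numeric(pool %*% p$Wh + as.numeric(p$bh))
  cache$Xout <- X; cache$pool <- pool
  list(logits = logits, cache = cache)
}

#' Backward pass of the transformer
#'
#' @param p Parameters; \code{cache} from [nn_forward()]; \code{dlogits}
#'   gradient at the head output.
#' @param cache Forward cache.
#' @param dlogits Numeric vector, d(loss)/d(logits).
#' @return Gradient list with the same shapes as \code{p}.
#' @export
nn_backward <- function(p, cache, dlogits) {
  dm <- attr(p, "dims")
  n <- length(cache$ids)
  d <- dm$d; h <- dm$h; dk <- d %/% h
  g <- rapply(p, function(m) m * 0, how = "replace")
  dl <- matrix(dlogits, ncol = 1)
  g$Wh <- cache$pool %o% dlogits
  g$bh <- matrix(dlogits, 1)
  dpool <- as.numeric(p$Wh %*% dl)
  dX <- matrix(dpool, n, d, byrow = TRUE) / n
  for (l in rev(seq_len(dm$nlayer))) {
    cl <- cache$layers[[l]]
    b2 <- ln_bwd(dX, cl$l2, p[[paste0("g2", l)]])
    g[[paste0("g2", l)]] <- b2$dg; g[[paste0("c2", l)]] <- b2$db
    dR2 <- b2$dX
    dFF <- dR2
    dHr <- dFF %*% t(p[[paste0("W2", l)]])
    g[[paste0("W2", l)]] <- t(cl$Hr) %*% dFF
    g[[paste0("b2", l)]] <- matrix(colSums(dFF), 1)
    dH1 <- dHr * (cl$H1 > 0)
    g[[paste0("W1", l)]] <- t(cl$l1$Y) %*% dH1
    g[[paste0("b1", l)]] <- matrix(colSums(dH1), 1)
    dL1 <- dR2 + dH1 %*% t(p[[paste0("W1", l)]])
    b1 <- ln_bwd(dL1, cl$l1, p[[paste0("g1", l)]])
    g[[paste0("g1", l)]] <- b1$dg; g[[paste0("c1", l)]] <- b1$db
    dR1 <- b1$dX
    dXO <- dR1
    g[[paste0("Wo", l)]] <- t(cl$O) %*% dXO
    g[[paste0("bo", l)]] <- matrix(colSums(dXO), 1)
    dO <- dXO %*% t(p[[paste0("Wo", l)]])
    dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1L) * dk + 1L):(hh * dk)
      A <- cl$A[[hh]]
      dOh <- dO[, cols, drop = FALSE]
      dA <- dOh %*% t(cl$V[, cols, drop = FALSE])
      dV[, cols] <- t(A) %*% dOh
      dS <- (dA - rowSums(dA * A)) * A
      dQ[, cols] <- dS %*% cl$K[, cols, drop = FALSE] / sqrt(dk)
      dK[, cols] <- t(dS) %*% cl$Q[, cols, drop = FALSE] / sqrt(dk)
    }
    dXin <- dR1 +
      dQ %*% t(p[[paste0("Wq", l)]]) +
      dK %*% t(p[[paste0("Wk", l)]]) +
      dV %*% t(p[[paste0("Wv", l)]])
    g[[paste0("Wq", l)]] <- t(cl$Xin) %*% dQ
    g[[paste0("Wk", l)]] <- t(cl$Xin) %*% dK
    g[[paste0("Wv", l)]] <- t(cl$Xin) %*% dV
    dX <- dXin
  }
  for (k in seq_len(n)) {
    g$E[cache$ids[k], ] <- g$E[cache$ids[k], ] + dX[k, ]
    g$P[k, ] <- g$P[k, ] + dX[k, ]
  }
  g
}

# element-wise Adam over a parameter list (state kept alongside)
adam_state <- function(p) {
  list(m = rapply(p, function(x) x * 0, how = "replace"),
       v = rapply(p, function(x) x * 0, how = "replace"),
       t = 0L)
}

adam_step <- function(p, g, st, lr = 3e-4, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (k in names(p)) {
    st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * g[[k]]
    st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * g[[k]]^2
    mhat <- st$m[[k]] / (1 - b1^st$t)
    vhat <- st$v[[k]] / (1 - b2^st$t)
    p[[k]] <- p[[k]] + lr * mhat / (sqrt(vhat) + eps)   # gradient ASCENT
  }
  list(p = p, st = st)
}

# masked log-softmax over logits; masked entries get -Inf logprob
masked_log_softmax <- function(logits, mask) {
  z <- logits
  z[!mask] <- -Inf
  m <- max(z)
  lse <- m + log(sum(exp(z - m)))
  z - lse
}
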