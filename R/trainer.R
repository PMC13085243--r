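# PPO optimization of the five policies and the value network: clipped
# surrogate, squared-error value loss against the one-step TD target,
# normalized entropy bonus, and prioritized replay that doubles the
# sampling probability of trajectories whose terminal state sits in the
# top-K memory.

#' One-step temporal-difference advantage
#'
#' \eqn{A_t = r_t + \gamma V(s_{t+1}) - V(s_t)}; the terminal successor
#' value is 0. The value target is \eqn{V^{target} = A_t + V(s_t)}.
#'
#' @param r_t Reward at the step.
#' @param v_next Value estimate of the successor state (0 at terminal).
#' @param v_curr Value estimate of the current state.
#' @param gamma Discount factor.
#' @return List with \code{A} and \code{v_target}.
#' @export
advantage <- function(r_t, v_next, v_curr, gamma) {
  A <- r_t + gamma * v_next - v_curr
  list(A = A, v_target = A + v_curr)
}

#' PPO clipped surrogate term
#'
#' \eqn{\min(\rho A, \mathrm{clip}(\rho, 1-\epsilon, 1+\epsilon) A)} with
#' \eqn{\rho = \exp(\log\pi_{new} - \log\pi_{old})}.
#'
#' @param logp_new,logp_old New and stored log-probabilities of the action.
#' @param A Advantage estimate.
#' @param epsilon Clip width.
#' @return Scalar objective term (a lower bound on \eqn{\rho A} for
#'   positive advantages).
#' @examples
#' clipped_surrogate(log(2), 0, 1, 0.2)   # 1.2
#' @export
clipped_surrogate <- function(logp_new, logp_old, A, epsilon) {
  rho <- exp(logp_new - logp_old)
  min(rho * A, min(max(rho, 1 - epsilon), 1 + epsilon) * A)
}

#' Normalized policy entropy
#'
#' Base-b Shannon entropy \eqn{-\sum_x p(x) \log_b p(x)} with b the number
#' of possible actions, so the uniform policy scores exactly 1 and a
#' deterministic policy 0. Under masking, b is the number of currently
#' legal actions; a single legal action contributes entropy 0.
#'
#' @param p Probability vector over the legal actions (sums to 1).
#' @return Entropy in [0, 1].
#' @examples
#' policy_entropy(rep(1/3, 3))   # 1
#' policy_entropy(c(1, 0, 0))    # 0
#' @export
policy_entropy <- function(p) {
  b <- length(p)
  if (b <= 1L) return(0)
  nz <- p > 0
  # algebraically equal to -sum(p log_b p); this form is exact at both
  # poles (uniform: log(p b) = log 1 = 0; deterministic: 1 - 1)
  1 - sum(p[nz] * log(p[nz] * b)) / log(b)
}

# entropy (unnormalized gradient helper): returns list(S, dS/dlogits)
entropy_and_grad <- function(lp, mask) {
  p <- exp(lp); p[!mask] <- 0
  b <- sum(mask)
  if (b <= 1L) return(list(S = 0, dlogits = rep(0, length(lp))))
  nz <- mask & p > 0
  S <- -sum(p[nz] * log(p[nz])) / log(b)
  # dS/dlogit_k = -p_k (log p_k - sum_j p_j log p_j) / log b
  slp <- sum(p[nz] * lp[nz])
  d <- rep(0, length(lp))
  d[mask] <- -(p[mask] * (ifelse(p[mask] > 0, lp[mask], 0) - slp)) / log(b)
  list(S = S, dlogits = d)
}

# gradient factor of the clipped surrogate w.r.t. logp_new
clip_grad_factor <- function(rho, A, epsilon) {
  if (A >= 0 && rho > 1 + epsilon) return(0)
  if (A < 0 && rho < 1 - epsilon) return(0)
  rho * A
}

#' Sample a prioritized training batch
#'
#' Samples trajectories with replacement, with probability proportional to
#' their priority weight: 2 when the trajectory's terminal state is
#' currently held in the top-K memory, 1 otherwise.
#'
#' @param buffer List of scored trajectories.
#' @param topk A [topk_memory()].
#' @param batch_size Number of trajectories to draw.
#' @return List of trajectories (class \code{training_batch}, with the
#'   drawn priority weights as attribute \code{weights}).
#' @export
sample_batch <- function(buffer, topk, batch_size) {
  stopifnot(length(buffer) >= 1)
  w <- vapply(buffer, function(tr)
    if (!is.null(tr$key) && topk_member(topk, tr$key)) 2 else 1, numeric(1))
  idx <- sample.int(length(buffer), batch_size, replace = TRUE, prob = w)
  structure(buffer[idx], class = "training_batch", weights = w[idx])
}

# ---------------------------------------------------------------------------

# Per-record advantages and value targets for a scored trajectory, using
# the CURRENT value network (Eq-5 advantages bootstrap from V_theta, so
# replayed trajectories get fresh values rather than generation-time
# snapshots; this is what lets value information propagate backwards along
# a trajectory over repeated updates). Returns records augmented with A and
# v_target plus the per-transition value forwards (reused for the value
# loss).
trajectory_advantages <- function(tr, stack, gamma, memo = NULL) {
  recs <- tr$records
  trans <- vapply(recs, `[[`, integer(1), "transition")
  ntrans <- max(trans)
  first_of <- match(seq_len(ntrans), trans)
  fwd <- function(ids) {
    if (is.null(memo)) return(nn_forward(stack$value, ids))
    key <- paste(ids, collapse = ",")
    f <- memo[[key]]
    if (is.null(f)) { f <- nn_forward(stack$value, ids); memo[[key]] <- f }
    f
  }
  vfwd <- lapply(first_of, function(k) fwd(recs[[k]]$ids))
  v <- vapply(vfwd, function(f) f$logits[1L], numeric(1))
  recs <- lapply(recs, function(rec) {
    tt <- rec$transition
    terminal <- tt == ntrans
    r <- if (terminal) tr$r_t else 0
    v_next <- if (terminal) 0 else v[tt + 1L]
    adv <- advantage(r, v_next, v[tt], gamma)
    c(rec, list(A = adv$A, v_target = adv$v_target))
  })
  list(records = recs, vfwd = vfwd, v = v, trans = trans, ntrans = ntrans,
       first_of = first_of)
}

#' PPO losses and gradients over a training batch
#'
#' Computes, per model, the mean PPO objective
#' \eqn{L = \hat E[L^{CLIP} - L^{VF} + c_e S]} over the steps where the
#' model acted (the value network over all steps) and its gradient, ready
#' for a gradient-ascent step. Non-finite losses abort the update.
#'
#' @param batch A [sample_batch()] result (or list of scored trajectories).
#' @param stack A [psrl_agent()].
#' @param hp A [psrl_config()].
#' @param ref_stack Stack whose value network supplies the advantages and
#'   TD targets (defaults to \code{stack}; the targets are constants of the
#'   value regression, so gradient checks perturb \code{stack} while holding
#'   \code{ref_stack} fixed).
#' @return List with \code{losses} (named scalars) and \code{grads}
#'   (named parameter-shaped lists), plus \code{n_records}.
#' @export
ppo_loss <- function(batch, stack, hp, ref_stack = stack) {
  models <- c("master", "pos_s", "tok_s", "pos_d", "tok_d")
  grads <- list(); counts <- list(); losses <- list()
  for (m in c(models, "value")) {
    grads[[m]] <- rapply(stack[[m]], function(x) x * 0, how = "replace")
    counts[[m]] <- 0L; losses[[m]] <- 0
  }
  # records sharing (model, input sequence) share one forward pass, and the
  # backward pass is linear in dlogits, so contributions are accumulated per
  # unique input and backpropagated once
  fw_cache <- lapply(c(models, "value"),
                     function(m) new.env(parent = emptyenv()))
  names(fw_cache) <- c(models, "value")
  dl_acc <- lapply(c(models, "value"),
                   function(m) new.env(parent = emptyenv()))
  names(dl_acc) <- c(models, "value")
  get_fw <- function(m, ids) {
    key <- paste(ids, collapse = ",")
    f <- fw_cache[[m]][[key]]
    if (is.null(f)) {
      f <- nn_forward(stack[[m]], ids)
      fw_cache[[m]][[key]] <- f
    }
    f
  }
  add_dl <- function(m, ids, dl) {
    key <- paste(ids, collapse = ",")
    cur <- dl_acc[[m]][[key]]
    dl_acc[[m]][[key]] <- if (is.null(cur)) dl else cur + dl
  }
  ref_memo <- if (identical(stack$value, ref_stack$value)) fw_cache[["value"]]
              else new.env(parent = emptyenv())
  for (tr in batch) {
    ta <- trajectory_advantages(tr, ref_stack, hp$gamma, memo = ref_memo)
    recs <- ta$records
    # value loss over all steps: records of one transition share the state
    # and the TD target, so weight contributions by the record count
    nrec_of <- tabulate(ta$trans, nbins = ta$ntrans)
    for (tt in seq_len(ta$ntrans)) {
      ids <- recs[[match(tt, ta$trans)]]$ids
      vfw <- get_fw("value", ids)
      verr <- vfw$logits[1L] - recs[[match(tt, ta$trans)]]$v_target
      losses$value <- losses$value - nrec_of[tt] * verr^2
      counts$value <- counts$value + nrec_of[tt]
      add_dl("value", ids, -2 * verr * nrec_of[tt])
    }
    for (rec in recs) {
      m <- rec$model
      fw <- get_fw(m, rec$ids)
      if (m == "pos_d") {
        ns <- stack$nslots
        lp1 <- masked_log_softmax(fw$logits[seq_len(ns)], rec$mask)
        lp2 <- masked_log_softmax(fw$logits[ns + seq_len(ns)], rec$mask2)
        lp_new <- lp1[rec$action] + lp2[rec$action2]
        e1 <- entropy_and_grad(lp1, rec$mask)
        e2 <- entropy_and_grad(lp2, rec$mask2)
        S <- (e1$S + e2$S) / 2
        rho <- exp(lp_new - rec$logp)
        f <- clip_grad_factor(rho, rec$A, hp$epsilon)
        p1 <- exp(lp1); p1[!rec$mask] <- 0
        p2 <- exp(lp2); p2[!rec$mask2] <- 0
        d1 <- -p1; d1[rec$action] <- d1[rec$action] + 1
        d2 <- -p2; d2[rec$action2] <- d2[rec$action2] + 1
        dlogits <- c(f * d1 + hp$c_e * e1$dlogits / 2,
                     f * d2 + hp$c_e * e2$dlogits / 2)
      } else {
        lp <- masked_log_softmax(fw$logits, rec$mask)
        lp_new <- lp[rec$action]
        ent <- entropy_and_grad(lp, rec$mask)
        S <- ent$S
        rho <- exp(lp_new - rec$logp)
        f <- clip_grad_factor(rho, rec$A, hp$epsilon)
        p <- exp(lp); p[!rec$mask] <- 0
        d <- -p; d[rec$action] <- d[rec$action] + 1
        dlogits <- f * d + hp$c_e * ent$dlogits
      }
      lclip <- clipped_surrogate(lp_new, rec$logp, rec$A, hp$epsilon)
      losses[[m]] <- losses[[m]] + lclip + hp$c_e * S
      counts[[m]] <- counts[[m]] + 1L
      add_dl(m, rec$ids, dlogits)
    }
  }
  for (m in c(models, "value")) {
    for (key in ls(dl_acc[[m]])) {
      g <- nn_backward(stack[[m]], fw_cache[[m]][[key]]$cache,
                       dl_acc[[m]][[key]])
      for (k in names(g)) grads[[m]][[k]] <- grads[[m]][[k]] + g[[k]]
    }
  }
  for (m in names(grads)) if (counts[[m]] > 0L) {
    for (k in names(grads[[m]])) grads[[m]][[k]] <- grads[[m]][[k]] / counts[[m]]
    losses[[m]] <- losses[[m]] / counts[[m]]
  }
  bad <- !vapply(losses, is.finite, logical(1))
  if (any(bad))
    stop("NaNGuard: non-finite PPO loss for ",
         paste(names(losses)[bad], collapse = ","), call. = FALSE)
  list(losses = losses, grads = grads, n_records = counts)
}

# ---------------------------------------------------------------------------

#' Train the molecular inverse-design agent
#'
#' The full data-free reinforcement-learning loop: generate episodes with
#' the hierarchical policy stack, score terminal states through the
#' chemical-reward cascade and the Tanimoto-complement diversity reward
#' (both normalized by discount-based scaling), update the top-K memory,
#' sample a prioritized batch and apply PPO updates to the five policies
#' and the value network. Fully reproducible for a fixed seed and fidelity.
#'
#' @param config A [psrl_config()].
#' @param engine An [energy_engine()] (defaults to the toy engine).
#' @param scaffold A [scaffold_styrene()].
#' @param fingerprinter Function decoded-state -> bit set (default
#'   [structural_keys()]).
#' @param target_key Optional canonical-pair key: when supplied, the run
#'   records after how many unique valid states this target was first
#'   generated (used by the search comparison harness).
#' @param verbose Print a progress line every 50 epochs.
#' @return A fitted object of class \code{psrl_fit}.
#' @seealso [simulate.psrl_fit()], [plot.psrl_fit()], [compare_search()]
#' @export
psrl_train <- function(config = psrl_config(), engine = toy_engine(),
                       scaffold = scaffold_styrene(),
                       fingerprinter = structural_keys,
                       target_key = NULL, verbose = FALSE) {
  set.seed(config$seed)
  stack <- psrl_agent(config)
  opt <- lapply(stack[c("master", "pos_s", "tok_s", "pos_d", "tok_d", "value")],
                adam_state)
  cache <- reward_cache()
  topk <- topk_memory(config$K)
  # unit floor on the scaling sigma: rewards are O(1) on their natural
  # scales (kcal/mol, [0,1]), so the normalizer only ever shrinks them and
  # the warm-up of the running statistics cannot inflate early rewards
  scaler_c <- reward_scaler(config$gamma, eps = 1)
  scaler_d <- reward_scaler(config$gamma, eps = 1)
  recent_fps <- list()
  buffer <- list()
  buffer_cap <- max(4L * config$batch_size, 64L)
  unique_valid <- character(0)
  target_hit <- NA_integer_
  logs <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ep_rc <- c(); ep_rd <- c(); ep_rt <- c(); ep_valid <- 0L; ep_n <- 0L
    for (e in seq_len(config$episodes_per_epoch)) {
      tr <- generate_episode(stack, config)
      ep_n <- ep_n + 1L
      rb <- chemical_reward(tr$state, scaffold, engine, cache, config)
      r_d <- NA_real_
      if (rb$valid) {
        fp <- fingerprinter(tr$state$text)
        r_d <- diversity_reward(fp, recent_fps, config$empty_fp_similarity)
        recent_fps <- c(recent_fps, list(fp))
        if (length(recent_fps) > config$n_div)
          recent_fps <- recent_fps[-1L]
      }
      T_eff <- if (tr$empty) 0L else max(1L, tr$T)
      r_t <- total_reward(T_eff, T_eff, config$L, rb$valid, rb$r_c, r_d,
                          config, scaler_c, scaler_d)
      tr$r_t <- r_t
      tr$key <- rb$key
      tr$valid <- rb$valid
      if (rb$valid) {
        # the memory of the best molecules ranks by the raw chemical reward
        # (kcal/mol): a stationary, physical ordering, unlike the normalized
        # r_t whose scale drifts with the running statistics
        topk_update(topk, tr$state$text, rb$r_c, rb$key)
        if (!rb$key %in% unique_valid) {
          unique_valid <- c(unique_valid, rb$key)
          if (!is.null(target_key) && is.na(target_hit) &&
              identical(rb$key, target_key))
            target_hit <- length(unique_valid)
        }
        ep_valid <- ep_valid + 1L
        ep_rc <- c(ep_rc, rb$r_c); ep_rd <- c(ep_rd, r_d)
      }
      ep_rt <- c(ep_rt, r_t)
      buffer <- c(buffer, list(tr))
      if (length(buffer) > buffer_cap) {
        # trim oldest, but pin trajectories whose terminal state is still in
        # the top-K memory so prioritized replay can keep exploiting them
        pinned <- vapply(buffer, function(b)
          !is.null(b$key) && !is.na(b$key) && b$valid &&
            topk_member(topk, b$key), logical(1))
        drop <- which(!pinned)[1L]
        if (is.na(drop)) drop <- 1L
        buffer <- buffer[-drop]
      }
    }
    batch <- sample_batch(buffer, topk, config$batch_size)
    for (pe in seq_len(config$ppo_epochs)) {
      upd <- ppo_loss(batch, stack, config)
      for (m in names(upd$grads)) {
        if (upd$n_records[[m]] == 0L) next
        res <- adam_step(stack[[m]], upd$grads[[m]], opt[[m]], lr = config$lr)
        stack[[m]] <- res$p; opt[[m]] <- res$st
      }
    }
    logs[[epoch]] <- data.frame(
      epoch = epoch,
      mean_rc = if (length(ep_rc)) mean(ep_rc) else NA_real_,
      mean_rd = if (length(ep_rd)) mean(ep_rd) else NA_real_,
      mean_rt = mean(ep_rt),
      valid_rate = ep_valid / ep_n,
      unique_valid = length(unique_valid))
    if (verbose && epoch %% 50L == 0L)
      cat(sprintf("epoch %d  mean r_c %.3f  valid %.2f  unique %d\n",
                  epoch, logs[[epoch]]$mean_rc, logs[[epoch]]$valid_rate,
                  length(unique_valid)))
    if (!is.null(target_key) && !is.na(target_hit)) break
  }
  structure(list(
    stack = stack, config = config,
    log = do.call(rbind, logs[!vapply(logs, is.null, logical(1))]),
    topk = topk, cache = cache,
    unique_valid = unique_valid, target_hit = target_hit,
    fidelity = engine$fidelity
  ), class = "psrl_fit")
}

#' @export
print.psrl_fit <- function(x, ...) {
  cat("Data-free RL molecular design fit (", x$fidelity, " fidelity)\n",
      sep = "")
  cat("  epochs run:", nrow(x$log), " unique valid molecules:",
      length(x$unique_valid), "\n")
  if (nrow(x$topk$env$df))
    cat("  best state: \"", x$topk$env$df$state[1L], "\" (r_t = ",
        format(x$topk$env$df$r_t[1L], digits = 4), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.psrl_fit <- function(object, ...) {
  lg <- object$log
  cat("Training summary\n")
  cat("  epochs:", nrow(lg), "  episodes/epoch:",
      object$config$episodes_per_epoch, "\n")
  cat("  final mean r_c:",
      format(utils::tail(stats::na.omit(lg$mean_rc), 1), digits = 4),
      " kcal/mol; valid rate:",
      format(utils::tail(lg$valid_rate, 1), digits = 3), "\n")
  cat("  engine calls:", object$cache$env$engine_calls,
      " cache hits:", object$cache$env$hits, "\n")
  cat("  top-K memory:\n")
  print(utils::head(object$topk$env$df, 5))
  invisible(object)
}

#' Reward curves of a fit
#'
#' Plots the per-epoch mean chemical reward and mean diversity reward with
#' running averages, the standard diagnostic of the exploration-to-
#' exploitation transition.
#'
#' @param x A \code{psrl_fit}.
#' @param window Running-average window (epochs).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.psrl_fit <- function(x, window = 10L, ...) {
  lg <- x$log
  runmean <- function(v) stats::filter(v, rep(1 / window, window),
                                       sides = 1)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(lg$epoch, lg$mean_rc, pch = 16, cex = 0.4, col = "steelblue",
                 xlab = "epoch", ylab = "mean r_c (kcal/mol)", ...)
  graphics::lines(lg$epoch, runmean(lg$mean_rc), col = "red", lwd = 2)
  graphics::plot(lg$epoch, lg$mean_rd, pch = 16, cex = 0.4, col = "steelblue",
                 xlab = "epoch", ylab = "mean r_d", ...)
  graphics::lines(lg$epoch, runmean(lg$mean_rd), col = "red", lwd = 2)
  invisible(x)
}

#' Generate molecules from a trained agent
#'
#' Samples episodes from the trained policy stack without further training
#' and scores them through the reward cascade.
#'
#' @param object A \code{psrl_fit}.
#' @param nsim Number of episodes.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A data.frame: state, validity, r_c, and the decoded isomer pair.
#' @export
simulate.psrl_fit <- function(object, nsim = 10L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  engine <- if (object$fidelity == "toy") toy_engine() else forcefield_engine()
  cache <- reward_cache()
  rows <- lapply(seq_len(nsim), function(k) {
    tr <- generate_episode(object$stack, object$config)
    rb <- chemical_reward(tr$state, engine = engine, cache = cache,
                          hp = object$config)
    data.frame(state = tr$state$text, valid = rb$valid,
               r_c = rb$r_c, failure_stage = rb$failure_stage,
               e_smiles = rb$e_smiles, z_smiles = rb$z_smiles,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
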