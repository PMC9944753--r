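# Compact transformer over coded EHR sequences, trained jointly on a
# masked-sequence objective, a propensity head and two arm-specific outcome
# heads. Implemented directly on R matrices with analytic gradients and Adam;
# the backward pass is validated against finite differences in the test
# suite. Sequences are flattened column-major: flat row r corresponds to
# patient b = ((r - 1) %% B) + 1 at position l = ((r - 1) %/% B) + 1.

#' Model configuration for the EHR transformer
#'
#' @param layers Number of encoder blocks.
#' @param heads Attention heads; `hidden_size` must be divisible by it.
#' @param hidden_size Embedding/encoder width.
#' @param intermediate_size Feed-forward inner width.
#' @param max_len Maximum tokens per sequence (oldest events truncated).
#' @param mask_rate Masked-sequence corruption probability, in (0, 1).
#' @param lambda_mem,lambda_prop,lambda_out Loss weights of the
#'   masked-sequence, propensity and outcome terms.
#' @param epochs Training epochs (joint phase).
#' @param pretrain_epochs Optional masked-sequence-only epochs run first.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param seed Seed governing initialization, masking, shuffling and splits.
#' @param propensity_clip Truncation bound `delta`; propensities are clipped
#'   to `[delta, 1 - delta]` for positivity protection.
#' @param val_fraction Inner validation fraction used for early stopping on
#'   the propensity + outcome loss; 0 disables early stopping.
#' @param patience Epochs without validation improvement before stopping.
#' @return A list of class `model_config`.
#' @export
model_config <- function(layers = 2L, heads = 4L, hidden_size = 96L,
                         intermediate_size = 4L * hidden_size,
                         max_len = 256L, mask_rate = 0.15,
                         lambda_mem = 1, lambda_prop = 1, lambda_out = 1,
                         epochs = 10L, pretrain_epochs = 0L,
                         batch_size = 64L, lr = 1e-3, seed = 1L,
                         propensity_clip = 0.01, val_fraction = 0.1,
                         patience = 2L) {
  if (hidden_size %% heads != 0) {
    abort("`hidden_size` must be divisible by `heads`.",
          class = "ehrtmle_config_error")
  }
  if (mask_rate <= 0 || mask_rate >= 1) {
    abort("`mask_rate` must be in (0, 1).", class = "ehrtmle_config_error")
  }
  if (propensity_clip <= 0 || propensity_clip >= 0.5) {
    abort("`propensity_clip` must be in (0, 0.5).", class = "ehrtmle_config_error")
  }
  structure(list(layers = as.integer(layers), heads = as.integer(heads),
                 hidden_size = as.integer(hidden_size),
                 intermediate_size = as.integer(intermediate_size),
                 max_len = as.integer(max_len), mask_rate = mask_rate,
                 lambda_mem = lambda_mem, lambda_prop = lambda_prop,
                 lambda_out = lambda_out, epochs = as.integer(epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed), propensity_clip = propensity_clip,
                 val_fraction = val_fraction, patience = as.integer(patience)),
            class = "model_config")
}

N_AGES <- 111L  # integer years 0..110

#' Initialize transformer parameters
#'
#' @param vocab An `ehr_vocabulary`.
#' @param config A [model_config()].
#' @return Named list of parameter matrices/vectors.
#' @export
init_model <- function(vocab, config) {
  d <- config$hidden_size; f <- config$intermediate_size
  V <- vocab$size; P <- config$max_len + 1L
  rn <- function(nr, nc) matrix(rnorm(nr * nc, 0, 0.02), nr, nc)
  with_seed(derive_seed(config$seed, 11L), {
    p <- list(E_tok = rn(V, d), E_age = rn(N_AGES, d), E_seg = rn(2L, d),
              E_pos = rn(P, d), ln_e_g = rep(1, d), ln_e_b = rep(0, d),
              Wm = rn(d, V), bm = rep(0, V),
              wp = rn(d, 1L), bp = 0,
              w1 = rn(d, 1L), b1h = 0,
              w0 = rn(d, 1L), b0h = 0)
    for (l in seq_len(config$layers)) {
      pre <- sprintf("L%d_", l)
      p[[paste0(pre, "Wq")]] <- rn(d, d); p[[paste0(pre, "bq")]] <- rep(0, d)
      p[[paste0(pre, "Wk")]] <- rn(d, d); p[[paste0(pre, "bk")]] <- rep(0, d)
      p[[paste0(pre, "Wv")]] <- rn(d, d); p[[paste0(pre, "bv")]] <- rep(0, d)
      p[[paste0(pre, "Wo")]] <- rn(d, d); p[[paste0(pre, "bo")]] <- rep(0, d)
      p[[paste0(pre, "ln1_g")]] <- rep(1, d); p[[paste0(pre, "ln1_b")]] <- rep(0, d)
      p[[paste0(pre, "W1")]] <- rn(d, f); p[[paste0(pre, "b1")]] <- rep(0, f)
      p[[paste0(pre, "W2")]] <- rn(f, d); p[[paste0(pre, "b2")]] <- rep(0, d)
      p[[paste0(pre, "ln2_g")]] <- rep(1, d); p[[paste0(pre, "ln2_b")]] <- rep(0, d)
    }
    p
  })
}

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

ln_forward <- function(X, g, b, eps = 1e-5) {
  m <- rowMeans(X)
  xc <- X - m
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(Y = sweep(xhat, 2, g, `*`) + matrix(b, nrow(X), length(b), byrow = TRUE),
       xhat = xhat, inv = inv)
}

ln_backward <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2, g, `*`)
  mh <- rowMeans(dxhat)
  mxh <- rowMeans(dxhat * cache$xhat)
  list(dX = cache$inv * (dxhat - mh - cache$xhat * mxh),
       dg = colSums(dY * cache$xhat), db = colSums(dY))
}

# Pad a list of token sequences into aligned index matrices (B x L).
make_batch <- function(seqs, vocab) {
  B <- length(seqs)
  L <- max(vapply(seqs, function(s) length(s$tokens), integer(1)))
  padm <- function(get, fill) {
    m <- matrix(fill, B, L)
    for (b in seq_len(B)) {
      v <- get(seqs[[b]])
      if (length(v)) m[b, seq_along(v)] <- v
    }
    m
  }
  list(tok = padm(function(s) s$tokens, vocab$pad_id),
       age = padm(function(s) s$ages, 0L),
       seg = padm(function(s) s$segments, 1L),
       pos = padm(function(s) s$positions, 0L),
       mem = padm(function(s) s$mem_labels, NA_integer_),
       pad = padm(function(s) rep(TRUE, length(s$tokens)), FALSE),
       B = B, L = L)
}

row_softmax <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

# Encoder forward pass over one padded batch. Returns the final hidden
# states (flat N x d) and, when `keep_cache`, every intermediate needed for
# the analytic backward pass.
tf_encode <- function(params, batch, config, keep_cache = FALSE) {
  B <- batch$B; L <- batch$L; d <- config$hidden_size
  H <- config$heads; dh <- d %/% H
  tokv <- as.vector(batch$tok); agev <- as.vector(batch$age)
  segv <- as.vector(batch$seg); posv <- as.vector(batch$pos)
  X <- params$E_tok[tokv, , drop = FALSE] +
    params$E_age[pmin(agev, N_AGES - 1L) + 1L, , drop = FALSE] +
    params$E_seg[segv, , drop = FALSE] +
    params$E_pos[posv + 1L, , drop = FALSE]
  lne <- ln_forward(X, params$ln_e_g, params$ln_e_b)
  Hcur <- lne$Y
  cache <- if (keep_cache) list(tokv = tokv, agev = agev, segv = segv,
                                posv = posv, lne = lne, layers = list()) else NULL
  hcols <- lapply(seq_len(H), function(h) ((h - 1L) * dh + 1L):(h * dh))
  rows_of <- lapply(seq_len(B), function(b) b + B * (seq_len(L) - 1L))
  real <- lapply(seq_len(B), function(b) which(batch$pad[b, ]))

  for (l in seq_len(config$layers)) {
    pre <- sprintf("L%d_", l)
    Hin <- Hcur
    Qm <- Hin %*% params[[paste0(pre, "Wq")]] +
      matrix(params[[paste0(pre, "bq")]], nrow(Hin), d, byrow = TRUE)
    Km <- Hin %*% params[[paste0(pre, "Wk")]] +
      matrix(params[[paste0(pre, "bk")]], nrow(Hin), d, byrow = TRUE)
    Vm <- Hin %*% params[[paste0(pre, "Wv")]] +
      matrix(params[[paste0(pre, "bv")]], nrow(Hin), d, byrow = TRUE)
    O <- matrix(0, nrow(Hin), d)
    Alist <- if (keep_cache) vector("list", B) else NULL
    for (b in seq_len(B)) {
      idx <- rows_of[[b]]
      rl <- real[[b]]
      Ab <- if (keep_cache) vector("list", H) else NULL
      for (h in seq_len(H)) {
        cs <- hcols[[h]]
        Q <- Qm[idx, cs, drop = FALSE]; K <- Km[idx, cs, drop = FALSE]
        S <- tcrossprod(Q, K) / sqrt(dh)
        if (length(rl) < L) S[, -rl] <- -1e30
        A <- row_softmax(S)
        O[idx, cs] <- A %*% Vm[idx, cs, drop = FALSE]
        if (keep_cache) Ab[[h]] <- A
      }
      if (keep_cache) Alist[[b]] <- Ab
    }
    AO <- O %*% params[[paste0(pre, "Wo")]] +
      matrix(params[[paste0(pre, "bo")]], nrow(Hin), d, byrow = TRUE)
    ln1 <- ln_forward(Hin + AO, params[[paste0(pre, "ln1_g")]],
                      params[[paste0(pre, "ln1_b")]])
    H1 <- ln1$Y
    Hpre <- H1 %*% params[[paste0(pre, "W1")]] +
      matrix(params[[paste0(pre, "b1")]], nrow(H1), config$intermediate_size,
             byrow = TRUE)
    Hact <- gelu(Hpre)
    Ff <- Hact %*% params[[paste0(pre, "W2")]] +
      matrix(params[[paste0(pre, "b2")]], nrow(H1), d, byrow = TRUE)
    ln2 <- ln_forward(H1 + Ff, params[[paste0(pre, "ln2_g")]],
                      params[[paste0(pre, "ln2_b")]])
    if (keep_cache) {
      cache$layers[[l]] <- list(Hin = Hin, Qm = Qm, Km = Km, Vm = Vm,
                                Alist = Alist, O = O, ln1 = ln1, H1 = H1,
                                Hpre = Hpre, Hact = Hact, ln2 = ln2)
    }
    Hcur <- ln2$Y
  }
  list(Hfinal = Hcur, cache = cache, rows_of = rows_of, real = real,
       hcols = hcols)
}

#' Forward pass of the EHR transformer
#'
#' Encodes a batch of token sequences and returns the masked-slot logits and
#' the propensity and arm-specific outcome probabilities (logistic link, so
#' all outputs lie in (0, 1)). Patients are independent: outputs do not
#' depend on batch composition or order.
#'
#' @param params Parameters from [init_model()] or [train_model()].
#' @param seqs List of `token_sequence` objects.
#' @param vocab The `ehr_vocabulary`.
#' @param config A [model_config()].
#' @return List with `g`, `q1`, `q0` (length-B vectors) and `mem_logits`
#'   (matrix, one row per masked slot in batch order).
#' @export
model_forward <- function(params, seqs, vocab, config) {
  if (max(vapply(seqs, function(s) length(s$tokens), integer(1))) > config$max_len) {
    abort("A sequence exceeds `max_len`.", class = "ehrtmle_contract_error")
  }
  batch <- make_batch(seqs, vocab)
  enc <- tf_encode(params, batch, config, keep_cache = FALSE)
  hcls <- enc$Hfinal[seq_len(batch$B), , drop = FALSE]
  midx <- which(!is.na(as.vector(batch$mem)))
  # flat indices are column-major (position-major); reorder so logit rows
  # follow patients in batch order, then position within patient
  midx <- midx[order((midx - 1L) %% batch$B, (midx - 1L) %/% batch$B)]
  mem_logits <- if (length(midx)) {
    sweep(enc$Hfinal[midx, , drop = FALSE] %*% params$Wm, 2, params$bm, `+`)
  } else matrix(numeric(0), 0, vocab$size)
  list(g = as.vector(expit(hcls %*% params$wp + params$bp)),
       q1 = as.vector(expit(hcls %*% params$w1 + params$b1h)),
       q0 = as.vector(expit(hcls %*% params$w0 + params$b0h)),
       mem_logits = mem_logits)
}

# Joint loss and analytic gradients for one batch. `arm`/`y` may be NULL
# during masked-sequence-only pretraining.
tf_loss_grads <- function(params, batch, config, arm = NULL, y = NULL) {
  B <- batch$B; d <- config$hidden_size
  H <- config$heads; dh <- d %/% H
  enc <- tf_encode(params, batch, config, keep_cache = TRUE)
  Hf <- enc$Hfinal; cache <- enc$cache
  grads <- lapply(params, function(p) if (is.matrix(p)) p * 0 else p * 0)
  dH <- Hf * 0
  loss_mem <- loss_prop <- loss_out <- 0

  hcls <- Hf[seq_len(B), , drop = FALSE]
  if (!is.null(arm) && config$lambda_prop > 0) {
    g <- as.vector(expit(hcls %*% params$wp + params$bp))
    loss_prop <- -mean(arm * log(pmax(g, 1e-12)) +
                         (1 - arm) * log(pmax(1 - g, 1e-12)))
    dz <- config$lambda_prop * (g - arm) / B
    grads$wp <- grads$wp + crossprod(hcls, dz)
    grads$bp <- grads$bp + sum(dz)
    dH[seq_len(B), ] <- dH[seq_len(B), ] + matrix(dz, ncol = 1) %*% t(params$wp)
  }
  if (!is.null(y) && config$lambda_out > 0) {
    q1 <- as.vector(expit(hcls %*% params$w1 + params$b1h))
    q0 <- as.vector(expit(hcls %*% params$w0 + params$b0h))
    qobs <- ifelse(arm == 1, q1, q0)
    loss_out <- -mean(y * log(pmax(qobs, 1e-12)) +
                        (1 - y) * log(pmax(1 - qobs, 1e-12)))
    dz1 <- config$lambda_out * ifelse(arm == 1, q1 - y, 0) / B
    dz0 <- config$lambda_out * ifelse(arm == 0, q0 - y, 0) / B
    grads$w1 <- grads$w1 + crossprod(hcls, dz1)
    grads$b1h <- grads$b1h + sum(dz1)
    grads$w0 <- grads$w0 + crossprod(hcls, dz0)
    grads$b0h <- grads$b0h + sum(dz0)
    dH[seq_len(B), ] <- dH[seq_len(B), ] +
      matrix(dz1, ncol = 1) %*% t(params$w1) +
      matrix(dz0, ncol = 1) %*% t(params$w0)
  }
  memv <- as.vector(batch$mem)
  midx <- which(!is.na(memv))
  if (length(midx) && config$lambda_mem > 0) {
    Xm <- Hf[midx, , drop = FALSE]
    logits <- sweep(Xm %*% params$Wm, 2, params$bm, `+`)
    P <- row_softmax(logits)
    lab <- memv[midx]
    m <- length(midx)
    loss_mem <- -mean(log(pmax(P[cbind(seq_len(m), lab)], 1e-12)))
    dlog <- P
    dlog[cbind(seq_len(m), lab)] <- dlog[cbind(seq_len(m), lab)] - 1
    dlog <- config$lambda_mem * dlog / m
    grads$Wm <- grads$Wm + crossprod(Xm, dlog)
    grads$bm <- grads$bm + colSums(dlog)
    dH[midx, ] <- dH[midx, ] + dlog %*% t(params$Wm)
  }

  for (l in rev(seq_len(config$layers))) {
    pre <- sprintf("L%d_", l)
    cl <- cache$layers[[l]]
    ln2b <- ln_backward(dH, cl$ln2, params[[paste0(pre, "ln2_g")]])
    grads[[paste0(pre, "ln2_g")]] <- grads[[paste0(pre, "ln2_g")]] + ln2b$dg
    grads[[paste0(pre, "ln2_b")]] <- grads[[paste0(pre, "ln2_b")]] + ln2b$db
    dH1 <- ln2b$dX
    dF <- ln2b$dX
    dHact <- dF %*% t(params[[paste0(pre, "W2")]])
    grads[[paste0(pre, "W2")]] <- grads[[paste0(pre, "W2")]] + crossprod(cl$Hact, dF)
    grads[[paste0(pre, "b2")]] <- grads[[paste0(pre, "b2")]] + colSums(dF)
    dHpre <- dHact * gelu_grad(cl$Hpre)
    grads[[paste0(pre, "W1")]] <- grads[[paste0(pre, "W1")]] + crossprod(cl$H1, dHpre)
    grads[[paste0(pre, "b1")]] <- grads[[paste0(pre, "b1")]] + colSums(dHpre)
    dH1 <- dH1 + dHpre %*% t(params[[paste0(pre, "W1")]])
    ln1b <- ln_backward(dH1, cl$ln1, params[[paste0(pre, "ln1_g")]])
    grads[[paste0(pre, "ln1_g")]] <- grads[[paste0(pre, "ln1_g")]] + ln1b$dg
    grads[[paste0(pre, "ln1_b")]] <- grads[[paste0(pre, "ln1_b")]] + ln1b$db
    dHin <- ln1b$dX
    dAO <- ln1b$dX
    dO <- dAO %*% t(params[[paste0(pre, "Wo")]])
    grads[[paste0(pre, "Wo")]] <- grads[[paste0(pre, "Wo")]] + crossprod(cl$O, dAO)
    grads[[paste0(pre, "bo")]] <- grads[[paste0(pre, "bo")]] + colSums(dAO)
    dQ <- dH * 0; dK <- dH * 0; dV <- dH * 0
    for (b in seq_len(B)) {
      idx <- enc$rows_of[[b]]
      for (h in seq_len(H)) {
        cs <- enc$hcols[[h]]
        A <- cl$Alist[[b]][[h]]
        dOb <- dO[idx, cs, drop = FALSE]
        Vb <- cl$Vm[idx, cs, drop = FALSE]
        dA <- tcrossprod(dOb, Vb)
        dV[idx, cs] <- dV[idx, cs] + crossprod(A, dOb)
        dS <- A * (dA - rowSums(dA * A))
        dQ[idx, cs] <- dQ[idx, cs] + dS %*% cl$Km[idx, cs, drop = FALSE] / sqrt(dh)
        dK[idx, cs] <- dK[idx, cs] + crossprod(dS, cl$Qm[idx, cs, drop = FALSE]) / sqrt(dh)
      }
    }
    grads[[paste0(pre, "Wq")]] <- grads[[paste0(pre, "Wq")]] + crossprod(cl$Hin, dQ)
    grads[[paste0(pre, "bq")]] <- grads[[paste0(pre, "bq")]] + colSums(dQ)
    grads[[paste0(pre, "Wk")]] <- grads[[paste0(pre, "Wk")]] + crossprod(cl$Hin, dK)
    grads[[paste0(pre, "bk")]] <- grads[[paste0(pre, "bk")]] + colSums(dK)
    grads[[paste0(pre, "Wv")]] <- grads[[paste0(pre, "Wv")]] + crossprod(cl$Hin, dV)
    grads[[paste0(pre, "bv")]] <- grads[[paste0(pre, "bv")]] + colSums(dV)
    dH <- dHin + dQ %*% t(params[[paste0(pre, "Wq")]]) +
      dK %*% t(params[[paste0(pre, "Wk")]]) +
      dV %*% t(params[[paste0(pre, "Wv")]])
  }

  lnb <- ln_backward(dH, cache$lne, params$ln_e_g)
  grads$ln_e_g <- grads$ln_e_g + lnb$dg
  grads$ln_e_b <- grads$ln_e_b + lnb$db
  dX <- lnb$dX
  scatter <- function(gmat, idx) {
    rs <- rowsum(dX, idx)
    ids <- as.integer(rownames(rs))
    gmat[ids, ] <- gmat[ids, ] + rs
    gmat
  }
  grads$E_tok <- scatter(grads$E_tok, cache$tokv)
  grads$E_age <- scatter(grads$E_age, pmin(cache$agev, N_AGES - 1L) + 1L)
  grads$E_seg <- scatter(grads$E_seg, cache$segv)
  grads$E_pos <- scatter(grads$E_pos, cache$posv + 1L)

  list(loss = config$lambda_mem * loss_mem + config$lambda_prop * loss_prop +
         config$lambda_out * loss_out,
       loss_mem = loss_mem, loss_prop = loss_prop, loss_out = loss_out,
       grads = grads)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

mask_all <- function(seqs, vocab, rate) {
  lapply(seqs, function(s) {
    cand <- which(s$tokens %in% vocab$code_ids)
    sel <- cand[runif(length(cand)) < rate]
    s$mem_labels <- rep(NA_integer_, length(s$tokens))
    if (length(sel)) {
      s$mem_labels[sel] <- s$tokens[sel]
      r <- runif(length(sel))
      s$tokens[sel[r < 0.8]] <- vocab$mask_id
      repl <- sel[r >= 0.8 & r < 0.9]
      if (length(repl)) s$tokens[repl] <- sample(vocab$code_ids, length(repl),
                                                 replace = TRUE)
    }
    s
  })
}

eval_supervised_loss <- function(params, seqs, arm, y, vocab, config) {
  out <- model_predict(params, seqs, vocab, config, clip_g = FALSE)
  g <- pmin(pmax(out$g, 1e-12), 1 - 1e-12)
  qobs <- ifelse(arm == 1, out$q1, out$q0)
  qobs <- pmin(pmax(qobs, 1e-12), 1 - 1e-12)
  lp <- if (config$lambda_prop > 0)
    -mean(arm * log(g) + (1 - arm) * log(1 - g)) else 0
  lo <- if (config$lambda_out > 0)
    -mean(y * log(qobs) + (1 - y) * log(1 - qobs)) else 0
  config$lambda_prop * lp + config$lambda_out * lo
}

#' Train the EHR transformer
#'
#' Co-trains the masked-sequence, propensity and outcome objectives with
#' Adam, with an optional masked-sequence-only pretraining phase and early
#' stopping on an inner validation split scored by the propensity + outcome
#' loss. Deterministic given `config$seed`.
#'
#' @param seqs List of `token_sequence` (uncorrupted; masking is applied
#'   internally per epoch).
#' @param arm Binary exposure-arm indicator per sequence.
#' @param y Binary outcome per sequence.
#' @param vocab The `ehr_vocabulary`.
#' @param config A [model_config()].
#' @return List with `params`, and a `history` tibble of per-epoch losses.
#' @export
train_model <- function(seqs, arm, y, vocab, config) {
  n <- length(seqs)
  params <- init_model(vocab, config)
  state <- adam_init(params)
  use_val <- config$val_fraction > 0 && n >= 20
  val_idx <- if (use_val) {
    with_seed(derive_seed(config$seed, 21L),
              sort(sample(n, max(2L, round(config$val_fraction * n)))))
  } else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  best <- list(loss = Inf, params = params)
  bad_epochs <- 0L
  hist <- list()
  total_epochs <- config$pretrain_epochs + config$epochs

  for (ep in seq_len(total_epochs)) {
    pretrain <- ep <= config$pretrain_epochs
    cfg_ep <- config
    if (pretrain) { cfg_ep$lambda_prop <- 0; cfg_ep$lambda_out <- 0 }
    ep_losses <- c()
    with_seed(derive_seed(config$seed, 100L + ep), {
      masked <- mask_all(seqs[tr_idx], vocab, config$mask_rate)
      ord <- sample(length(tr_idx))
      starts <- seq(1, length(ord), by = config$batch_size)
      for (s in starts) {
        take <- ord[s:min(s + config$batch_size - 1L, length(ord))]
        batch <- make_batch(masked[take], vocab)
        res <- tf_loss_grads(params, batch, cfg_ep,
                             arm = if (pretrain) NULL else arm[tr_idx][take],
                             y = if (pretrain) NULL else y[tr_idx][take])
        st <- adam_step(params, res$grads, state, config$lr)
        params <- st$params; state <- st$state
        ep_losses <- c(ep_losses, res$loss)
      }
    })
    vloss <- NA_real_
    if (use_val && !pretrain) {
      vloss <- eval_supervised_loss(params, seqs[val_idx], arm[val_idx],
                                    y[val_idx], vocab, config)
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, params = params)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
      }
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, pretrain = pretrain,
                                 train_loss = mean(ep_losses), val_loss = vloss)
    if (use_val && !pretrain && bad_epochs >= config$patience) break
  }
  final <- if (use_val && is.finite(best$loss)) best$params else params
  list(params = final, history = dplyr::bind_rows(hist))
}

#' Predict held-out nuisances with a trained transformer
#'
#' @inheritParams train_model
#' @param params Trained parameters.
#' @param clip_g Clip propensities to `[delta, 1 - delta]`.
#' @return Tibble with `g`, `q1`, `q0` per sequence.
#' @export
model_predict <- function(params, seqs, vocab, config, clip_g = TRUE) {
  n <- length(seqs)
  g <- q1 <- q0 <- numeric(n)
  starts <- seq(1, n, by = config$batch_size)
  for (s in starts) {
    take <- s:min(s + config$batch_size - 1L, n)
    out <- model_forward(params, seqs[take], vocab, config)
    g[take] <- out$g; q1[take] <- out$q1; q0[take] <- out$q0
  }
  if (clip_g) g <- clip(g, config$propensity_clip, 1 - config$propensity_clip)
  tibble::tibble(g = g, q1 = q1, q0 = q0)
}
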