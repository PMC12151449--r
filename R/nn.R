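# Minimal dense/convolutional network primitives with explicit backprop.
# All layers operate on one sequence of frames at a time; shapes are
#   stream input:  (C channels, L samples, T frames)
#   frame latent:  (T frames, D dims)
# Convolutions over the sample axis use im2col + GEMM. The channel-major
# layout makes the im2col patch matrix a plain reshape of one subscript
# extraction (no permutations in the training hot path); weight-matrix
# rows are ordered channel-fastest within kernel tap.

# --- 1-D convolution over the sample axis (shared across frames) -------

conv1d_fw <- function(A, W, b, stride, k) {
  d <- dim(A)  # (C, L, T)
  C <- d[1L]; L <- d[2L]; T <- d[3L]
  L1 <- (L - k) %/% stride + 1L
  idx <- as.vector(outer(seq_len(k), (seq_len(L1) - 1L) * stride, `+`))
  P <- A[, idx, , drop = FALSE]       # (C, k*L1, T), c fastest
  dim(P) <- c(C * k, L1 * T)
  Z <- crossprod(W, P) + b            # (F, L1*T); b recycles per column
  dim(Z) <- c(ncol(W), L1, T)
  list(out = Z, P = P, L = L, L1 = L1, C = C, T = T)
}

conv1d_bw <- function(dY, cache, W, stride, k, want_dA = TRUE) {
  L1 <- cache$L1; T <- cache$T; C <- cache$C; L <- cache$L
  F_ <- dim(dY)[1L]
  dim(dY) <- c(F_, L1 * T)
  dW <- tcrossprod(cache$P, dY)       # (C*k, F)
  db <- rowSums(dY)
  if (!want_dA) return(list(dA = NULL, dW = dW, db = db))
  dP <- W %*% dY                      # (C*k, L1*T)
  dim(dP) <- c(C, k, L1, T)
  dA <- array(0, c(C, L, T))
  for (kk in seq_len(k)) {
    pos <- (seq_len(L1) - 1L) * stride + kk
    dA[, pos, ] <- dA[, pos, , drop = FALSE] +
      array(dP[, kk, , ], c(C, L1, T))
  }
  list(dA = dA, dW = dW, db = db)
}

# --- temporal dilated convolution over the frame axis ------------------

dilconv_fw <- function(H, W, b, d) {
  T <- nrow(H); D <- ncol(H)
  Hp <- rbind(matrix(0, d, D), H, matrix(0, d, D))
  X3 <- cbind(Hp[seq_len(T), , drop = FALSE],
              Hp[d + seq_len(T), , drop = FALSE],
              Hp[2L * d + seq_len(T), , drop = FALSE])
  Z <- X3 %*% W
  Z <- Z + matrix(b, T, length(b), byrow = TRUE)
  list(out = Z, X3 = X3)
}

dilconv_bw <- function(dY, cache, W, d) {
  T <- nrow(dY); D <- ncol(W) ; Din <- nrow(W) / 3L
  dX3 <- dY %*% t(W)
  dW <- crossprod(cache$X3, dY)
  db <- colSums(dY)
  dHp <- matrix(0, T + 2L * d, Din)
  dHp[seq_len(T), ] <- dHp[seq_len(T), ] + dX3[, seq_len(Din)]
  dHp[d + seq_len(T), ] <- dHp[d + seq_len(T), ] +
    dX3[, Din + seq_len(Din)]
  dHp[2L * d + seq_len(T), ] <- dHp[2L * d + seq_len(T), ] +
    dX3[, 2L * Din + seq_len(Din)]
  list(dH = dHp[d + seq_len(T), , drop = FALSE], dW = dW, db = db)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Weighted cross-entropy over valid frames; returns loss and dlogits.
weighted_ce <- function(logits, y, valid, class_weights) {
  p <- softmax_rows(logits)
  T <- nrow(logits)
  sel <- which(valid & !is.na(y))
  w <- numeric(T)
  w[sel] <- class_weights[y[sel]]
  tot <- sum(w)
  if (tot <= 0) {
    return(list(loss = NA_real_, dlogits = matrix(0, T, ncol(logits))))
  }
  eps <- 1e-12
  loss <- -sum(w[sel] * log(p[cbind(sel, y[sel])] + eps)) / tot
  dl <- p * (w / tot)
  dl[cbind(sel, y[sel])] <- dl[cbind(sel, y[sel])] - w[sel] / tot
  list(loss = loss, dlogits = dl)
}

# --- ADAM ---------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
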