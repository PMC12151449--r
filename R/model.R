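#' Classifier architecture specification
#'
#' The end-to-end classifier has one input head per modality stream (a
#' stack of strided 1-D convolutions over the 120-sample axis followed by
#' global average pooling), a merge stage (concatenation of head
#' embeddings, two dense layers) producing a per-frame latent vector, a
#' temporal module of residual blocks doing symmetric dilated
#' convolutions over the frame axis (kernel 3, dilations 1, 2, 4, 8 -
#' receptive field 31 frames, about 34.6 s), and a softmax output per
#' track. At reference scale the latent dimension is 160 and each head
#' embeds to 64; `scale = "small"` is a desk-scale profile that trains on
#' a CPU in minutes.
#'
#' @param scale `"small"` or `"reference"`, or override the widths
#'   directly.
#' @param head_filters Per-head embedding width.
#' @param latent Frame latent dimension.
#' @param dilations Temporal dilation factors.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(scale = c("small", "reference"),
                       head_filters = NULL, latent = NULL,
                       dilations = c(1L, 2L, 4L, 8L)) {
  scale <- match.arg(scale)
  defaults <- switch(scale,
                     small = list(head_filters = 8L, latent = 24L),
                     reference = list(head_filters = 64L, latent = 160L))
  structure(list(scale = scale,
                 head_filters = head_filters %||% defaults$head_filters,
                 latent = latent %||% defaults$latent,
                 head_kernel = 5L, head_stride = 2L,
                 temporal_kernel = 3L,
                 dilations = as.integer(dilations)),
            class = "model_spec")
}

#' Build a classifier for a stream layout
#'
#' @param spec A `model_spec`.
#' @param stream_channels Named integer vector: channels per stream (from
#'   the configuration: 3 channels per sensor per stream).
#' @param n_classes Number of output categories (7 posture, 9 movement).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `imu_classifier`.
#' @export
build_model <- function(spec, stream_channels, n_classes, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), length(stream_channels) >= 1L,
            n_classes >= 2L)
  set.seed(seed)
  k <- spec$head_kernel
  f <- spec$head_filters
  D <- spec$latent
  init <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  }
  params <- list()
  for (s in names(stream_channels)) {
    C <- stream_channels[[s]]
    params[[paste0("Wh1_", s)]] <- init(k * C, f)
    params[[paste0("bh1_", s)]] <- numeric(f)
    params[[paste0("Wh2_", s)]] <- init(k * f, f)
    params[[paste0("bh2_", s)]] <- numeric(f)
  }
  S <- length(stream_channels)
  params$Wm1 <- init(S * f, D); params$bm1 <- numeric(D)
  params$Wm2 <- init(D, D); params$bm2 <- numeric(D)
  for (j in seq_along(spec$dilations)) {
    params[[paste0("Wt_", j)]] <- init(3L * D, D)
    params[[paste0("bt_", j)]] <- numeric(D)
    params[[paste0("Wp_", j)]] <- init(D, D) * 0.5
    params[[paste0("bp_", j)]] <- numeric(D)
  }
  params$Wout <- init(D, n_classes); params$bout <- numeric(n_classes)
  structure(list(spec = spec, stream_channels = stream_channels,
                 n_classes = n_classes, params = params),
            class = "imu_classifier")
}

#' @export
print.imu_classifier <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<imu_classifier> %d streams (%s), latent %d, %d classes, %d params\n",
              length(x$stream_channels),
              paste(names(x$stream_channels), collapse = ","),
              x$spec$latent, x$n_classes, np))
  invisible(x)
}

# Full forward pass; returns logits and (optionally) all caches.
nn_forward <- function(model, xlist, keep_cache = FALSE) {
  spec <- model$spec
  p <- model$params
  k <- spec$head_kernel; st <- spec$head_stride
  heads <- list(); caches <- list()
  T <- dim(xlist[[1L]])[3L]
  for (s in names(xlist)) {
    c1 <- conv1d_fw(xlist[[s]], p[[paste0("Wh1_", s)]],
                    p[[paste0("bh1_", s)]], st, k)
    a1 <- relu(c1$out)
    c2 <- conv1d_fw(a1, p[[paste0("Wh2_", s)]],
                    p[[paste0("bh2_", s)]], st, k)
    a2 <- relu(c2$out)             # (f, L2, T)
    L2 <- dim(a2)[2L]
    pool <- colMeans(aperm(a2, c(2L, 1L, 3L)))  # (f, T)
    heads[[s]] <- t(pool)          # (T, f)
    if (keep_cache) {
      caches[[s]] <- list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, L2 = L2)
    }
  }
  Hcat <- do.call(cbind, heads)    # (T, S*f)
  Z1 <- Hcat %*% p$Wm1 + matrix(p$bm1, T, length(p$bm1), byrow = TRUE)
  A1 <- relu(Z1)
  Z2 <- A1 %*% p$Wm2 + matrix(p$bm2, T, length(p$bm2), byrow = TRUE)
  H <- relu(Z2)
  blocks <- list()
  for (j in seq_along(spec$dilations)) {
    d <- spec$dilations[j]
    dc <- dilconv_fw(H, p[[paste0("Wt_", j)]], p[[paste0("bt_", j)]], d)
    A <- relu(dc$out)
    Z <- A %*% p[[paste0("Wp_", j)]] +
      matrix(p[[paste0("bp_", j)]], T, spec$latent, byrow = TRUE)
    Hnew <- H + Z
    if (keep_cache) {
      blocks[[j]] <- list(dc = dc, A = A, Hin = H)
    }
    H <- Hnew
  }
  logits <- H %*% p$Wout + matrix(p$bout, T, model$n_classes,
                                  byrow = TRUE)
  out <- list(logits = logits)
  if (keep_cache) {
    out$cache <- list(heads = caches, Hcat = Hcat, Z1 = Z1, A1 = A1,
                      Z2 = Z2, blocks = blocks, Hfinal = H, T = T)
  }
  out
}

# Backward pass given dlogits; returns gradient list aligned with params.
nn_backward <- function(model, xlist, fw, dlogits) {
  spec <- model$spec
  p <- model$params
  cache <- fw$cache
  k <- spec$head_kernel; st <- spec$head_stride
  g <- list()
  T <- cache$T
  g$Wout <- crossprod(cache$Hfinal, dlogits)
  g$bout <- colSums(dlogits)
  dH <- dlogits %*% t(p$Wout)
  for (j in rev(seq_along(spec$dilations))) {
    blk <- cache$blocks[[j]]
    d <- spec$dilations[j]
    dZ <- dH                                   # residual: out = Hin + Z
    g[[paste0("Wp_", j)]] <- crossprod(blk$A, dZ)
    g[[paste0("bp_", j)]] <- colSums(dZ)
    dA <- dZ %*% t(p[[paste0("Wp_", j)]])
    dA[blk$dc$out < 0] <- 0
    bw <- dilconv_bw(dA, blk$dc, p[[paste0("Wt_", j)]], d)
    g[[paste0("Wt_", j)]] <- bw$dW
    g[[paste0("bt_", j)]] <- bw$db
    dH <- dH + bw$dH
  }
  dZ2 <- dH
  dZ2[cache$Z2 < 0] <- 0
  g$Wm2 <- crossprod(cache$A1, dZ2)
  g$bm2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(p$Wm2)
  dA1[cache$Z1 < 0] <- 0
  g$Wm1 <- crossprod(cache$Hcat, dA1)
  g$bm1 <- colSums(dA1)
  dHcat <- dA1 %*% t(p$Wm1)
  f <- spec$head_filters
  off <- 0L
  for (s in names(xlist)) {
    hc <- cache$heads[[s]]
    dPool <- t(dHcat[, off + seq_len(f), drop = FALSE])  # (f, T)
    off <- off + f
    L2 <- hc$L2
    # mean pool backward: spread evenly over the L2 axis
    dA2 <- aperm(array(dPool / L2, c(f, T, L2)), c(1L, 3L, 2L))
    dA2[hc$c2$out < 0] <- 0
    bw2 <- conv1d_bw(dA2, hc$c2, p[[paste0("Wh2_", s)]], st, k)
    g[[paste0("Wh2_", s)]] <- bw2$dW
    g[[paste0("bh2_", s)]] <- bw2$db
    dA1h <- bw2$dA
    dA1h[hc$c1$out < 0] <- 0
    # input gradient of the first layer is never consumed (input = data)
    bw1 <- conv1d_bw(dA1h, hc$c1, p[[paste0("Wh1_", s)]], st, k,
                     want_dA = FALSE)
    g[[paste0("Wh1_", s)]] <- bw1$dW
    g[[paste0("bh1_", s)]] <- bw1$db
  }
  g
}

#' Predict one-hot frame categories for a frame tensor
#'
#' Deterministic argmax predictions of a trained classifier.
#'
#' @param model An `imu_classifier`.
#' @param frames A `frame_tensor` from [make_frames()], built for the same
#'   configuration the model was trained on.
#' @param valid_mask Optional logical mask; masked rows are zeroed.
#' @return A `frame_predictions` object.
#' @export
predict_frames <- function(model, frames, valid_mask = NULL) {
  xl <- frames$frames
  got <- unname(vapply(xl, function(a) dim(a)[1L], 0L))
  want <- unname(as.integer(model$stream_channels))
  if (length(got) != length(want) || !all(got == want)) {
    stop("predict_frames: stream layout does not match the model")
  }
  logits <- nn_forward(model, xl)$logits
  idx <- max.col(logits, ties.method = "first")
  onehot <- matrix(0L, nrow(logits), model$n_classes)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, nrow(logits))
  sel <- which(valid_mask)
  onehot[cbind(sel, idx[sel])] <- 1L
  frame_predictions(frames$frame_times, onehot, valid_mask)
}
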