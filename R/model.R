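#' Transformer model configuration
#'
#' Architecture hyperparameters of the Patterson-to-density network: a 3D
#' CNN stem expands the input to `c` channels, the grid is partitioned
#' into patches of `patch_dims`, each patch is flattened and projected to
#' token width `d_t` and given a learned positional embedding; `L` layers
#' of one-way attention (Patterson tokens attend Patterson and
#' partial-structure tokens; partial tokens are never updated) are
#' followed by an un-patching MLP decoder, a two-layer 3D CNN and a tanh
#' output.
#'
#' @param grid_dims Integer length-3 map dimensions (N1, N2, N3).
#' @param patch_dims Integer length-3 patch dimensions; must divide
#'   `grid_dims`.
#' @param in_channels Input channels of the Patterson stem (1, or 2 when a
#'   previous prediction is recycled as a second channel).
#' @param c Stem output channels.
#' @param d_t Token width; must equal `heads * d_h`.
#' @param heads Number of attention heads.
#' @param d_h Per-head width.
#' @param layers Number of attention layers.
#' @param ff_width Feed-forward hidden width.
#' @return A list of class `model_config`; `S` is the token count.
#' @export
model_config <- function(grid_dims = c(16L, 16L, 16L),
                         patch_dims = c(4L, 4L, 4L),
                         in_channels = 1L, c = 8L, d_t = 64L, heads = 4L,
                         d_h = 16L, layers = 2L, ff_width = 128L) {
  grid_dims <- as.integer(rep_len(grid_dims, 3L))
  patch_dims <- as.integer(rep_len(patch_dims, 3L))
  if (any(grid_dims %% patch_dims != 0L)) {
    stop("config error: grid dims must be divisible by patch dims",
         call. = FALSE)
  }
  if (d_t != heads * d_h) {
    stop("config error: d_t must equal heads * d_h", call. = FALSE)
  }
  S <- prod(grid_dims %/% patch_dims)
  structure(list(grid_dims = grid_dims, patch_dims = patch_dims,
                 in_channels = as.integer(in_channels), c = as.integer(c),
                 d_t = as.integer(d_t), heads = as.integer(heads),
                 d_h = as.integer(d_h), layers = as.integer(layers),
                 ff_width = as.integer(ff_width), S = as.integer(S),
                 patch_vox = as.integer(prod(patch_dims))),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "model config: grid %s, patch %s -> S=%d tokens, d_t=%d (%d heads x %d), L=%d, c=%d, ff=%d, in_ch=%d\n",
    paste(x$grid_dims, collapse = "x"), paste(x$patch_dims, collapse = "x"),
    x$S, x$d_t, x$heads, x$d_h, x$layers, x$c, x$ff_width,
    x$in_channels))
  invisible(x)
}

# --- precomputed index maps ------------------------------------------------

# im2col neighbor indices for a 3x3x3 stencil with zero padding: an
# Ntot x 27 integer matrix; out-of-bounds neighbors point at the padding
# slot Ntot + 1.
make_conv_index <- function(dims) {
  N1 <- dims[1L]; N2 <- dims[2L]; N3 <- dims[3L]
  Ntot <- N1 * N2 * N3
  ii <- rep.int(seq_len(N1), N2 * N3)
  jj <- rep.int(rep(seq_len(N2), each = N1), N3)
  kk <- rep(seq_len(N3), each = N1 * N2)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  idx <- matrix(Ntot + 1L, Ntot, 27L)
  for (t in seq_len(27L)) {
    i2 <- ii + off[t, 1L]; j2 <- jj + off[t, 2L]; k2 <- kk + off[t, 3L]
    ok <- i2 >= 1L & i2 <= N1 & j2 >= 1L & j2 <= N2 & k2 >= 1L & k2 <= N3
    idx[ok, t] <- i2[ok] + (j2[ok] - 1L) * N1 + (k2[ok] - 1L) * N1 * N2
  }
  idx
}

# Patch gather map: S x (patch_vox * c) indices into as.vector of an
# Ntot x c matrix. Patch order and in-patch voxel order are both raster
# with the first axis fastest; features are voxel-major within channel.
make_patch_index <- function(grid_dims, patch_dims, c) {
  P <- grid_dims %/% patch_dims
  S <- prod(P)
  dvox <- prod(patch_dims)
  Ntot <- prod(grid_dims)
  pg <- as.matrix(expand.grid(p1 = 0:(P[1L] - 1L), p2 = 0:(P[2L] - 1L),
                              p3 = 0:(P[3L] - 1L)))
  vg <- as.matrix(expand.grid(v1 = 0:(patch_dims[1L] - 1L),
                              v2 = 0:(patch_dims[2L] - 1L),
                              v3 = 0:(patch_dims[3L] - 1L)))
  vox <- matrix(0L, S, dvox)
  for (s in seq_len(S)) {
    i <- pg[s, 1L] * patch_dims[1L] + vg[, 1L]
    j <- pg[s, 2L] * patch_dims[2L] + vg[, 2L]
    k <- pg[s, 3L] * patch_dims[3L] + vg[, 3L]
    vox[s, ] <- 1L + i + j * grid_dims[1L] + k * grid_dims[1L] * grid_dims[2L]
  }
  out <- matrix(0L, S, dvox * c)
  for (ch in seq_len(c)) {
    out[, ((ch - 1L) * dvox + 1L):(ch * dvox)] <- vox + (ch - 1L) * Ntot
  }
  out
}

model_indices <- function(config) {
  list(conv = make_conv_index(config$grid_dims),
       patch = make_patch_index(config$grid_dims, config$patch_dims,
                                config$c))
}

# --- parameters ------------------------------------------------------------

#' Initialize trainable parameters
#'
#' Truncated-normal initialization for projections and convolution stems
#' (He scaling for the convolutions), zeros for biases and the decoder
#' convolution bias, unit gain for the layer norms. Deterministic in the
#' seed.
#'
#' @param config A [model_config].
#' @param seed Integer seed.
#' @return A flat named list of arrays (class `model_parameters`).
#' @export
init_parameters <- function(config, seed = 1L) {
  set.seed(seed)
  tn <- function(n, sd) {
    x <- stats::rnorm(n, 0, sd)
    pmin(pmax(x, -2 * sd), 2 * sd)
  }
  lin <- function(nin, nout) matrix(tn(nin * nout, sqrt(1 / nin)), nin, nout)
  conv <- function(nin, nout) matrix(tn(nin * nout, sqrt(2 / nin)), nin, nout)
  cfg <- config
  tokw <- cfg$patch_vox * cfg$c
  p <- list()
  p[["stem_p.W1"]] <- conv(27L * cfg$in_channels, cfg$c)
  p[["stem_p.b1"]] <- numeric(cfg$c)
  p[["stem_p.W2"]] <- conv(27L * cfg$c, cfg$c)
  p[["stem_p.b2"]] <- numeric(cfg$c)
  p[["stem_u.W1"]] <- conv(27L, cfg$c)
  p[["stem_u.b1"]] <- numeric(cfg$c)
  p[["stem_u.W2"]] <- conv(27L * cfg$c, cfg$c)
  p[["stem_u.b2"]] <- numeric(cfg$c)
  p[["tok_p.W1"]] <- lin(tokw, cfg$d_t)
  p[["tok_p.b1"]] <- numeric(cfg$d_t)
  p[["tok_p.W2"]] <- lin(cfg$d_t, cfg$d_t)
  p[["tok_p.b2"]] <- numeric(cfg$d_t)
  p[["tok_u.W1"]] <- lin(tokw, cfg$d_t)
  p[["tok_u.b1"]] <- numeric(cfg$d_t)
  p[["tok_u.W2"]] <- lin(cfg$d_t, cfg$d_t)
  p[["tok_u.b2"]] <- numeric(cfg$d_t)
  p[["pos_p"]] <- matrix(tn(cfg$S * cfg$d_t, 0.02), cfg$S, cfg$d_t)
  p[["pos_u"]] <- matrix(tn(cfg$S * cfg$d_t, 0.02), cfg$S, cfg$d_t)
  for (l in seq_len(cfg$layers)) {
    pre <- sprintf("l%d.", l)
    p[[paste0(pre, "ln1_g")]] <- rep(1, cfg$d_t)
    p[[paste0(pre, "ln1_b")]] <- numeric(cfg$d_t)
    p[[paste0(pre, "lnu_g")]] <- rep(1, cfg$d_t)
    p[[paste0(pre, "lnu_b")]] <- numeric(cfg$d_t)
    p[[paste0(pre, "Wq")]] <- lin(cfg$d_t, cfg$d_t)
    p[[paste0(pre, "Wk")]] <- lin(cfg$d_t, cfg$d_t)
    p[[paste0(pre, "Wv")]] <- lin(cfg$d_t, cfg$d_t)
    p[[paste0(pre, "Wkp")]] <- lin(cfg$d_t, cfg$d_t)
    p[[paste0(pre, "Wvp")]] <- lin(cfg$d_t, cfg$d_t)
    p[[paste0(pre, "Wo")]] <- lin(cfg$d_t, cfg$d_t)
    p[[paste0(pre, "bo")]] <- numeric(cfg$d_t)
    p[[paste0(pre, "ln2_g")]] <- rep(1, cfg$d_t)
    p[[paste0(pre, "ln2_b")]] <- numeric(cfg$d_t)
    p[[paste0(pre, "Wf1")]] <- lin(cfg$d_t, cfg$ff_width)
    p[[paste0(pre, "bf1")]] <- numeric(cfg$ff_width)
    p[[paste0(pre, "Wf2")]] <- lin(cfg$ff_width, cfg$d_t)
    p[[paste0(pre, "bf2")]] <- numeric(cfg$d_t)
  }
  p[["fin.ln_g"]] <- rep(1, cfg$d_t)
  p[["fin.ln_b"]] <- numeric(cfg$d_t)
  p[["fin.Wd1"]] <- lin(cfg$d_t, cfg$d_t)
  p[["fin.bd1"]] <- numeric(cfg$d_t)
  p[["fin.Wd2"]] <- lin(cfg$d_t, tokw)
  p[["fin.bd2"]] <- numeric(tokw)
  p[["fin.convW1"]] <- conv(27L * cfg$c, cfg$c)
  p[["fin.convb1"]] <- numeric(cfg$c)
  p[["fin.convW2"]] <- conv(27L * cfg$c, 1L)
  p[["fin.convb2"]] <- 0
  class(p) <- "model_parameters"
  p
}

zero_like <- function(params) {
  g <- lapply(unclass(params), function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  })
  g
}

# --- primitive layers ------------------------------------------------------

# Leaky-ReLU slope for the convolutional stems and patch MLPs. A small
# negative-side slope keeps units trainable after large early updates;
# the transformer feed-forward blocks use plain ReLU.
leaky_slope <- 0.01

conv3d_fwd <- function(X, W, b, conv_idx) {
  in_ch <- ncol(X)
  Ntot <- nrow(X)
  Xa <- rbind(X, 0)
  P <- Xa[as.vector(conv_idx), , drop = FALSE]
  dim(P) <- c(Ntot, 27L * in_ch)
  Y <- P %*% W
  Y <- Y + rep(b, each = Ntot)
  list(Y = Y, P = P)
}

conv3d_bwd <- function(dY, P, W, conv_idx, in_ch) {
  Ntot <- nrow(dY)
  dW <- crossprod(P, dY)
  db <- colSums(dY)
  dP <- dY %*% t(W)
  dim(dP) <- c(Ntot * 27L, in_ch)
  dXa <- matrix(0, Ntot + 1L, in_ch)
  for (t in seq_len(27L)) {
    rows <- ((t - 1L) * Ntot + 1L):(t * Ntot)
    tgt <- conv_idx[, t]
    dXa[tgt, ] <- dXa[tgt, ] + dP[rows, , drop = FALSE]
  }
  list(dW = dW, db = db, dX = dXa[seq_len(Ntot), , drop = FALSE])
}

ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  invstd <- 1 / sqrt(v + 1e-6)
  xhat <- xc * invstd
  Y <- xhat * rep(g, each = nrow(X)) + rep(b, each = nrow(X))
  list(Y = Y, xhat = xhat, invstd = invstd)
}

ln_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  n <- nrow(dY)
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- dY * rep(g, each = n)
  dX <- cache$invstd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# --- forward ---------------------------------------------------------------

# Embedding pipeline shared by Patterson and partial branches.
embed_fwd <- function(Xmat, params, prefix, tok_prefix, pos, config, idx) {
  c1 <- conv3d_fwd(Xmat, params[[paste0(prefix, ".W1")]],
                   params[[paste0(prefix, ".b1")]], idx$conv)
  R1 <- pmax(c1$Y, 0) + leaky_slope * pmin(c1$Y, 0)
  c2 <- conv3d_fwd(R1, params[[paste0(prefix, ".W2")]],
                   params[[paste0(prefix, ".b2")]], idx$conv)
  Tok0 <- matrix(as.vector(c2$Y)[idx$patch], config$S,
                 config$patch_vox * config$c)
  M1 <- Tok0 %*% params[[paste0(tok_prefix, ".W1")]]
  M1 <- M1 + rep(params[[paste0(tok_prefix, ".b1")]], each = config$S)
  Mr <- pmax(M1, 0) + leaky_slope * pmin(M1, 0)
  T <- Mr %*% params[[paste0(tok_prefix, ".W2")]]
  T <- T + rep(params[[paste0(tok_prefix, ".b2")]], each = config$S) + pos
  list(T = T, P1 = c1$P, mask1 = (c1$Y > 0) + leaky_slope * (c1$Y <= 0), P2 = c2$P, Tok0 = Tok0,
       mlp_mask = (M1 > 0) + leaky_slope * (M1 <= 0), Mr = Mr)
}

embed_bwd <- function(dT, cache, params, prefix, tok_prefix, config, idx,
                      grads) {
  S <- config$S
  grads[[paste0(tok_prefix, ".W2")]] <- grads[[paste0(tok_prefix, ".W2")]] +
    crossprod(cache$Mr, dT)
  grads[[paste0(tok_prefix, ".b2")]] <- grads[[paste0(tok_prefix, ".b2")]] +
    colSums(dT)
  dMr <- dT %*% t(params[[paste0(tok_prefix, ".W2")]])
  dM1 <- dMr * cache$mlp_mask
  grads[[paste0(tok_prefix, ".W1")]] <- grads[[paste0(tok_prefix, ".W1")]] +
    crossprod(cache$Tok0, dM1)
  grads[[paste0(tok_prefix, ".b1")]] <- grads[[paste0(tok_prefix, ".b1")]] +
    colSums(dM1)
  dTok0 <- dM1 %*% t(params[[paste0(tok_prefix, ".W1")]])
  Ntot <- prod(config$grid_dims)
  dA2vec <- numeric(Ntot * config$c)
  dA2vec[as.vector(idx$patch)] <- as.vector(dTok0)
  dA2 <- matrix(dA2vec, Ntot, config$c)
  b2 <- conv3d_bwd(dA2, cache$P2, params[[paste0(prefix, ".W2")]],
                   idx$conv, config$c)
  grads[[paste0(prefix, ".W2")]] <- grads[[paste0(prefix, ".W2")]] + b2$dW
  grads[[paste0(prefix, ".b2")]] <- grads[[paste0(prefix, ".b2")]] + b2$db
  dA1 <- b2$dX * cache$mask1
  in_ch <- nrow(params[[paste0(prefix, ".W1")]]) %/% 27L
  b1 <- conv3d_bwd(dA1, cache$P1, params[[paste0(prefix, ".W1")]],
                   idx$conv, in_ch)
  grads[[paste0(prefix, ".W1")]] <- grads[[paste0(prefix, ".W1")]] + b1$dW
  grads[[paste0(prefix, ".b1")]] <- grads[[paste0(prefix, ".b1")]] + b1$db
  grads
}

#' One one-way attention layer
#'
#' Patterson tokens form the queries; keys and values are the
#' concatenation of projected Patterson tokens and projected
#' partial-structure tokens, so information flows one way from the
#' partials into the Patterson stream. Pre-norm residual wiring; `U` is
#' not updated. Exposed for direct testing; [forward_model()] applies it
#' `L` times.
#'
#' @param X S x d_t token matrix.
#' @param U (S*J) x d_t partial token matrix (0 rows allowed).
#' @param params `model_parameters`.
#' @param layer Layer number (1-based).
#' @param config A [model_config].
#' @param want_cache Keep intermediates for backprop.
#' @return A list with `X` (updated tokens) and optionally `cache`.
#' @export
attention_layer <- function(X, U, params, layer, config,
                            want_cache = FALSE) {
  pre <- sprintf("l%d.", layer)
  S <- nrow(X)
  dh <- config$d_h
  H <- config$heads
  ln1 <- ln_fwd(X, params[[paste0(pre, "ln1_g")]],
                params[[paste0(pre, "ln1_b")]])
  hasU <- nrow(U) > 0L
  lnu <- if (hasU) {
    ln_fwd(U, params[[paste0(pre, "lnu_g")]], params[[paste0(pre, "lnu_b")]])
  } else {
    list(Y = U)
  }
  Q <- ln1$Y %*% params[[paste0(pre, "Wq")]]
  K <- rbind(ln1$Y %*% params[[paste0(pre, "Wk")]],
             if (hasU) lnu$Y %*% params[[paste0(pre, "Wkp")]])
  V <- rbind(ln1$Y %*% params[[paste0(pre, "Wv")]],
             if (hasU) lnu$Y %*% params[[paste0(pre, "Wvp")]])
  Hcat <- matrix(0, S, config$d_t)
  Alist <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    A <- softmax_rows(tcrossprod(Q[, cols, drop = FALSE],
                                 K[, cols, drop = FALSE]) / sqrt(dh))
    Alist[[h]] <- A
    Hcat[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  O <- Hcat %*% params[[paste0(pre, "Wo")]]
  O <- O + rep(params[[paste0(pre, "bo")]], each = S)
  X1 <- X + O
  ln2 <- ln_fwd(X1, params[[paste0(pre, "ln2_g")]],
                params[[paste0(pre, "ln2_b")]])
  F1 <- ln2$Y %*% params[[paste0(pre, "Wf1")]]
  F1 <- F1 + rep(params[[paste0(pre, "bf1")]], each = S)
  Fr <- pmax(F1, 0)
  F2 <- Fr %*% params[[paste0(pre, "Wf2")]]
  F2 <- F2 + rep(params[[paste0(pre, "bf2")]], each = S)
  X2 <- X1 + F2
  out <- list(X = X2)
  if (want_cache) {
    out$cache <- list(ln1 = ln1, lnu = lnu, Q = Q, K = K, V = V,
                      Alist = Alist, Hcat = Hcat, X1 = X1, ln2 = ln2,
                      mask_ff = F1 > 0, Fr = Fr, hasU = hasU)
  }
  out
}

attention_layer_bwd <- function(dX2, cache, params, layer, config, grads) {
  pre <- sprintf("l%d.", layer)
  S <- nrow(dX2)
  dh <- config$d_h
  H <- config$heads
  # feed-forward block
  dF2 <- dX2
  grads[[paste0(pre, "Wf2")]] <- grads[[paste0(pre, "Wf2")]] +
    crossprod(cache$Fr, dF2)
  grads[[paste0(pre, "bf2")]] <- grads[[paste0(pre, "bf2")]] + colSums(dF2)
  dFr <- dF2 %*% t(params[[paste0(pre, "Wf2")]])
  dF1 <- dFr * cache$mask_ff
  grads[[paste0(pre, "Wf1")]] <- grads[[paste0(pre, "Wf1")]] +
    crossprod(cache$ln2$Y, dF1)
  grads[[paste0(pre, "bf1")]] <- grads[[paste0(pre, "bf1")]] + colSums(dF1)
  dXn2 <- dF1 %*% t(params[[paste0(pre, "Wf1")]])
  lb2 <- ln_bwd(dXn2, cache$ln2, params[[paste0(pre, "ln2_g")]])
  grads[[paste0(pre, "ln2_g")]] <- grads[[paste0(pre, "ln2_g")]] + lb2$dg
  grads[[paste0(pre, "ln2_b")]] <- grads[[paste0(pre, "ln2_b")]] + lb2$db
  dX1 <- dX2 + lb2$dX
  # attention block
  dO <- dX1
  grads[[paste0(pre, "Wo")]] <- grads[[paste0(pre, "Wo")]] +
    crossprod(cache$Hcat, dO)
  grads[[paste0(pre, "bo")]] <- grads[[paste0(pre, "bo")]] + colSums(dO)
  dHcat <- dO %*% t(params[[paste0(pre, "Wo")]])
  dQ <- matrix(0, S, config$d_t)
  dK <- matrix(0, nrow(cache$K), config$d_t)
  dV <- matrix(0, nrow(cache$V), config$d_t)
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    A <- cache$Alist[[h]]
    dHh <- dHcat[, cols, drop = FALSE]
    dA <- tcrossprod(dHh, cache$V[, cols, drop = FALSE])
    dV[, cols] <- crossprod(A, dHh)
    dSc <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- dSc %*% cache$K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- crossprod(dSc, cache$Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  dXn <- dQ %*% t(params[[paste0(pre, "Wq")]])
  dXn <- dXn + dK[seq_len(S), , drop = FALSE] %*%
    t(params[[paste0(pre, "Wk")]])
  dXn <- dXn + dV[seq_len(S), , drop = FALSE] %*%
    t(params[[paste0(pre, "Wv")]])
  grads[[paste0(pre, "Wq")]] <- grads[[paste0(pre, "Wq")]] +
    crossprod(cache$ln1$Y, dQ)
  grads[[paste0(pre, "Wk")]] <- grads[[paste0(pre, "Wk")]] +
    crossprod(cache$ln1$Y, dK[seq_len(S), , drop = FALSE])
  grads[[paste0(pre, "Wv")]] <- grads[[paste0(pre, "Wv")]] +
    crossprod(cache$ln1$Y, dV[seq_len(S), , drop = FALSE])
  lb1 <- ln_bwd(dXn, cache$ln1, params[[paste0(pre, "ln1_g")]])
  grads[[paste0(pre, "ln1_g")]] <- grads[[paste0(pre, "ln1_g")]] + lb1$dg
  grads[[paste0(pre, "ln1_b")]] <- grads[[paste0(pre, "ln1_b")]] + lb1$db
  dX <- dX1 + lb1$dX
  dU <- NULL
  if (cache$hasU) {
    rows_u <- (S + 1L):nrow(cache$K)
    dKu <- dK[rows_u, , drop = FALSE]
    dVu <- dV[rows_u, , drop = FALSE]
    grads[[paste0(pre, "Wkp")]] <- grads[[paste0(pre, "Wkp")]] +
      crossprod(cache$lnu$Y, dKu)
    grads[[paste0(pre, "Wvp")]] <- grads[[paste0(pre, "Wvp")]] +
      crossprod(cache$lnu$Y, dVu)
    dUn <- dKu %*% t(params[[paste0(pre, "Wkp")]]) +
      dVu %*% t(params[[paste0(pre, "Wvp")]])
    lbu <- ln_bwd(dUn, cache$lnu, params[[paste0(pre, "lnu_g")]])
    grads[[paste0(pre, "lnu_g")]] <- grads[[paste0(pre, "lnu_g")]] + lbu$dg
    grads[[paste0(pre, "lnu_b")]] <- grads[[paste0(pre, "lnu_b")]] + lbu$db
    dU <- lbu$dX
  }
  list(dX = dX, dU = dU, grads = grads)
}

# Assemble the Ntot x in_channels Patterson input matrix of an example.
model_input_matrix <- function(example, config, recycled = NULL) {
  p <- as.vector(example$patterson$values)
  if (config$in_channels == 1L) {
    matrix(p, ncol = 1L)
  } else {
    if (is.null(recycled)) {
      stop("pairing error: recycling model needs a previous prediction",
           call. = FALSE)
    }
    r <- if (inherits(recycled, "volume_grid")) {
      as.vector(recycled$values)
    } else {
      as.vector(recycled)
    }
    cbind(p, r, deparse.level = 0)
  }
}

#' Full forward pass of the network
#'
#' @param Xmat Ntot x in_channels input matrix (Patterson values, plus a
#'   recycled prediction channel if configured).
#' @param partial_mats List of J Ntot x 1 matrices of partial-structure
#'   values (possibly empty).
#' @param params `model_parameters`.
#' @param config A [model_config].
#' @param idx Precomputed [model_indices()] (rebuilt if NULL).
#' @param want_cache Keep all intermediates for backprop.
#' @return A list with `out` (Ntot vector in (-1, 1)) and optionally
#'   `cache`.
#' @export
forward_model <- function(Xmat, partial_mats, params, config, idx = NULL,
                          want_cache = FALSE) {
  if (is.null(idx)) idx <- model_indices(config)
  embp <- embed_fwd(Xmat, params, "stem_p", "tok_p", params[["pos_p"]],
                    config, idx)
  X <- embp$T
  J <- length(partial_mats)
  embu <- lapply(partial_mats, function(u) {
    embed_fwd(u, params, "stem_u", "tok_u", params[["pos_u"]], config, idx)
  })
  U <- if (J > 0L) do.call(rbind, lapply(embu, `[[`, "T")) else
    matrix(0, 0L, config$d_t)
  layer_caches <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    res <- attention_layer(X, U, params, l, config, want_cache = want_cache)
    X <- res$X
    if (want_cache) layer_caches[[l]] <- res$cache
  }
  lnf <- ln_fwd(X, params[["fin.ln_g"]], params[["fin.ln_b"]])
  D1 <- lnf$Y %*% params[["fin.Wd1"]]
  D1 <- D1 + rep(params[["fin.bd1"]], each = config$S)
  Dr <- pmax(D1, 0) + leaky_slope * pmin(D1, 0)
  D <- Dr %*% params[["fin.Wd2"]]
  D <- D + rep(params[["fin.bd2"]], each = config$S)
  Ntot <- prod(config$grid_dims)
  dec_vec <- numeric(Ntot * config$c)
  dec_vec[as.vector(idx$patch)] <- as.vector(D)
  Xdec <- matrix(dec_vec, Ntot, config$c)
  cd1 <- conv3d_fwd(Xdec, params[["fin.convW1"]], params[["fin.convb1"]],
                    idx$conv)
  R1 <- pmax(cd1$Y, 0) + leaky_slope * pmin(cd1$Y, 0)
  cd2 <- conv3d_fwd(R1, params[["fin.convW2"]], params[["fin.convb2"]],
                    idx$conv)
  out <- tanh(cd2$Y[, 1L])
  res <- list(out = out)
  if (want_cache) {
    res$cache <- list(embp = embp, embu = embu, layers = layer_caches,
                      lnf = lnf, dec_mask = (D1 > 0) + leaky_slope * (D1 <= 0), Dr = Dr,
                      Pd1 = cd1$P, conv_mask = (cd1$Y > 0) + leaky_slope * (cd1$Y <= 0), Pd2 = cd2$P,
                      out = out, J = J)
  }
  res
}

# Backward pass: dout is the gradient of a scalar loss w.r.t. the output
# vector. Returns the parameter gradient list.
backward_model <- function(dout, cache, params, config, idx, grads = NULL) {
  if (is.null(grads)) grads <- zero_like(params)
  Ntot <- prod(config$grid_dims)
  dAd <- matrix(dout * (1 - cache$out^2), ncol = 1L)
  cb2 <- conv3d_bwd(dAd, cache$Pd2, params[["fin.convW2"]], idx$conv,
                    config$c)
  grads[["fin.convW2"]] <- grads[["fin.convW2"]] + cb2$dW
  grads[["fin.convb2"]] <- grads[["fin.convb2"]] + cb2$db
  dR1 <- cb2$dX * cache$conv_mask
  cb1 <- conv3d_bwd(dR1, cache$Pd1, params[["fin.convW1"]], idx$conv,
                    config$c)
  grads[["fin.convW1"]] <- grads[["fin.convW1"]] + cb1$dW
  grads[["fin.convb1"]] <- grads[["fin.convb1"]] + cb1$db
  dD <- matrix(as.vector(cb1$dX)[as.vector(idx$patch)], config$S,
               config$patch_vox * config$c)
  grads[["fin.Wd2"]] <- grads[["fin.Wd2"]] + crossprod(cache$Dr, dD)
  grads[["fin.bd2"]] <- grads[["fin.bd2"]] + colSums(dD)
  dDr <- dD %*% t(params[["fin.Wd2"]])
  dD1 <- dDr * cache$dec_mask
  grads[["fin.Wd1"]] <- grads[["fin.Wd1"]] + crossprod(cache$lnf$Y, dD1)
  grads[["fin.bd1"]] <- grads[["fin.bd1"]] + colSums(dD1)
  dXnf <- dD1 %*% t(params[["fin.Wd1"]])
  lbf <- ln_bwd(dXnf, cache$lnf, params[["fin.ln_g"]])
  grads[["fin.ln_g"]] <- grads[["fin.ln_g"]] + lbf$dg
  grads[["fin.ln_b"]] <- grads[["fin.ln_b"]] + lbf$db
  dX <- lbf$dX
  J <- cache$J
  dU <- if (J > 0L) matrix(0, J * config$S, config$d_t) else NULL
  for (l in rev(seq_len(config$layers))) {
    ab <- attention_layer_bwd(dX, cache$layers[[l]], params, l, config,
                              grads)
    grads <- ab$grads
    dX <- ab$dX
    if (J > 0L && !is.null(ab$dU)) dU <- dU + ab$dU
  }
  grads <- embed_bwd(dX, cache$embp, params, "stem_p", "tok_p", config,
                     idx, grads)
  grads[["pos_p"]] <- grads[["pos_p"]] + dX
  if (J > 0L) {
    for (j in seq_len(J)) {
      rows <- ((j - 1L) * config$S + 1L):(j * config$S)
      dTj <- dU[rows, , drop = FALSE]
      grads <- embed_bwd(dTj, cache$embu[[j]], params, "stem_u", "tok_u",
                         config, idx, grads)
      grads[["pos_u"]] <- grads[["pos_u"]] + dTj
    }
  }
  grads
}

#' Predict a density map from one example
#'
#' @param example An `example_record` (its `patterson` and `partials` are
#'   the inputs; `density` is not used).
#' @param params,config,idx Model state.
#' @param recycled Optional previous-prediction [volume_grid] for
#'   two-channel (recycling) models.
#' @return A [volume_grid] of kind "prediction" with values in (-1, 1).
#' @export
predict_example <- function(example, params, config, idx = NULL,
                            recycled = NULL) {
  if (is.null(idx)) idx <- model_indices(config)
  stopifnot(all(example$patterson$dims == config$grid_dims))
  Xmat <- model_input_matrix(example, config, recycled)
  partial_mats <- lapply(example$partials$grids,
                         function(g) matrix(as.vector(g$values), ncol = 1L))
  fwd <- forward_model(Xmat, partial_mats, params, config, idx)
  # tanh bounds values inside (-1, 1) but the peak is not rescaled to 1,
  # so the map is not flagged as normalized
  volume_grid(array(fwd$out, config$grid_dims), example$patterson$cell,
              kind = "prediction", spacing = example$patterson$spacing)
}
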