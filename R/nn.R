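# Minimal CNN engine: zero-padded 3x3 convolutions via im2col + GEMM,
# 2x2 max pooling, dense layers, sigmoid + binary cross-entropy, Adam.
# Activations live in matrices of shape (N * H * W) x channels with
# spatial index p = (w - 1) * H + h flattened column-major and images
# stacked along rows, so convolution is one BLAS matrix product per
# layer and training is deterministic under set.seed().

# nine (dh, dw) offsets of a 3x3 kernel, fixed order
.kernel_offsets <- function(radius = 1L) {
  g <- expand.grid(dh = -radius:radius, dw = -radius:radius)
  lapply(seq_len(nrow(g)), function(i) c(g$dh[i], g$dw[i]))
}

# for each offset: map output spatial index -> input spatial index (NA = pad)
.shift_index <- function(H, W, offsets) {
  h <- rep(seq_len(H), times = W)
  w <- rep(seq_len(W), each = H)
  lapply(offsets, function(o) {
    hs <- h + o[1]
    ws <- w + o[2]
    ok <- hs >= 1 & hs <= H & ws >= 1 & ws <= W
    idx <- rep(NA_integer_, H * W)
    idx[ok] <- (ws[ok] - 1L) * H + hs[ok]
    idx
  })
}

# expand a spatial index map (into an HW-sized input) to batch row
# indices; NA -> zero pad row (N*HW + 1)
.batch_gather <- function(idx, N, HW) {
  g <- rep(idx, times = N) + rep((seq_len(N) - 1L) * HW, each = length(idx))
  g[is.na(g)] <- N * HW + 1L
  g
}

# 2x2/stride-2 pooling: HWo x 4 matrix of child spatial indices
.pool_index <- function(H, W) {
  Ho <- H %/% 2L
  Wo <- W %/% 2L
  ho <- rep(seq_len(Ho), times = Wo)
  wo <- rep(seq_len(Wo), each = Ho)
  cbind((2L * wo - 2L) * H + 2L * ho - 1L,
        (2L * wo - 2L) * H + 2L * ho,
        (2L * wo - 1L) * H + 2L * ho - 1L,
        (2L * wo - 1L) * H + 2L * ho)
}

# im2col: (N*HW) x (9*Cin) patch matrix; columns blocked by offset k
.im2col <- function(X, gidx) {
  Xe <- rbind(X, 0)
  do.call(cbind, lapply(gidx, function(g) Xe[g, , drop = FALSE]))
}

# W: (9*Cin) x Cout, b: length Cout
.conv_forward <- function(X, W, b, gidx) {
  Xcols <- .im2col(X, gidx)
  Y <- Xcols %*% W
  Y <- Y + matrix(b, nrow(Y), length(b), byrow = TRUE)
  list(Y = Y, Xcols = Xcols)
}

# col2im accumulation: each offset maps output rows to distinct input
# rows (the pad row absorbs out-of-range writes and is dropped)
.conv_backward <- function(dY, Xcols, W, cin, gidx) {
  dW <- crossprod(Xcols, dY)
  db <- colSums(dY)
  dXcols <- dY %*% t(W)
  NHW <- nrow(dY)
  dXe <- matrix(0, NHW + 1L, cin)
  for (k in seq_along(gidx)) {
    block <- dXcols[, ((k - 1L) * cin + 1L):(k * cin), drop = FALSE]
    g <- gidx[[k]]
    dXe[g, ] <- dXe[g, , drop = FALSE] + block
  }
  list(dX = dXe[-(NHW + 1L), , drop = FALSE], dW = dW, db = db)
}

.pool_forward <- function(X, pidx, N, HW) {
  C <- ncol(X)
  HWo <- nrow(pidx)
  g <- lapply(1:4, function(k) .batch_gather(pidx[, k], N, HW))
  Y <- X[g[[1]], , drop = FALSE]
  A <- matrix(1L, N * HWo, C)
  for (k in 2:4) {
    Gk <- X[g[[k]], , drop = FALSE]
    m <- Gk > Y
    Y[m] <- Gk[m]
    A[m] <- k
  }
  list(Y = Y, argmax = A, gather = g)
}

.pool_backward <- function(dY, cache, NHW) {
  # pooling windows are disjoint (stride = window), so each input row
  # receives from exactly one (window, slot) and plain assignment works
  dX <- matrix(0, NHW, ncol(dY))
  for (k in 1:4)
    dX[cache$gather[[k]], ] <- dY * (cache$argmax == k)
  dX
}

.he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

# build parameter set for a model plan
.init_params <- function(plan, seed) {
  set.seed(seed)
  conv <- lapply(plan$conv, function(ly)
    list(W = .he_init(9L * ly$cin, ly$cout, 9 * ly$cin), b = rep(0, ly$cout)))
  dense <- lapply(plan$dense, function(ly)
    list(W = .he_init(ly$nin, ly$nout, ly$nin), b = rep(0, ly$nout)))
  out <- list(W = .he_init(plan$out$nin, 1L, plan$out$nin), b = 0)
  list(conv = conv, dense = dense, out = out)
}

# layer plan: spatial sizes and channel counts per stage, validated
.model_plan <- function(input_shape, conv_filters, pool_after, dense_widths) {
  H <- as.integer(input_shape[1])
  W <- as.integer(input_shape[2])
  if (length(conv_filters) != 6) stop("exactly 6 convolutional layers are required")
  if (length(pool_after) != 3) stop("exactly 3 pooling positions are required")
  if (length(dense_widths) != 2) stop("exactly 2 hidden dense layers are required")
  conv <- vector("list", 6)
  cin <- 1L
  for (i in 1:6) {
    conv[[i]] <- list(cin = cin, cout = as.integer(conv_filters[i]),
                      H = H, W = W, pool = i %in% pool_after)
    cin <- as.integer(conv_filters[i])
    if (i %in% pool_after) {
      if (H < 2 || W < 2)
        stop(sprintf("pooling after conv %d would reduce a %dx%d map below 1", i, H, W))
      if (H %% 2 != 0 || W %% 2 != 0)
        stop(sprintf("pooling after conv %d needs even spatial dims, got %dx%d", i, H, W))
      H <- H %/% 2L
      W <- W %/% 2L
    }
  }
  flat <- H * W * cin
  dense <- list(list(nin = flat, nout = as.integer(dense_widths[1])),
                list(nin = as.integer(dense_widths[1]), nout = as.integer(dense_widths[2])))
  list(conv = conv, dense = dense, out = list(nin = as.integer(dense_widths[2])),
       out_shape = c(H, W), flat = flat)
}

# precompute gather geometry for a batch size
.make_geom <- function(plan, N) {
  offsets <- .kernel_offsets()
  lapply(plan$conv, function(ly) {
    sidx <- .shift_index(ly$H, ly$W, offsets)
    HW <- ly$H * ly$W
    list(gidx = lapply(sidx, .batch_gather, N = N, HW = HW),
         pidx = if (ly$pool) .pool_index(ly$H, ly$W) else NULL)
  })
}

# forward pass; with_cache = TRUE keeps intermediates for backprop
.forward <- function(params, plan, geom, X, N, with_cache = FALSE) {
  caches <- if (with_cache) vector("list", 6) else NULL
  A <- X
  for (i in seq_along(plan$conv)) {
    ly <- plan$conv[[i]]
    cf <- .conv_forward(A, params$conv[[i]]$W, params$conv[[i]]$b, geom[[i]]$gidx)
    R <- cf$Y * (cf$Y > 0)
    if (with_cache) caches[[i]] <- list(Xcols = cf$Xcols, relu_mask = cf$Y > 0)
    A <- R
    if (ly$pool) {
      pf <- .pool_forward(A, geom[[i]]$pidx, N, ly$H * ly$W)
      if (with_cache) caches[[i]]$pool <- pf
      A <- pf$Y
    }
  }
  # flatten (HW x N x C -> N x HW*C)
  HWf <- prod(plan$out_shape)
  Cf <- plan$flat / HWf
  arr <- A
  dim(arr) <- c(HWf, N, Cf)
  Fm <- matrix(aperm(arr, c(2, 1, 3)), N, plan$flat)
  d_caches <- vector("list", 2)
  A2 <- Fm
  for (j in 1:2) {
    Z <- sweep(A2 %*% params$dense[[j]]$W, 2, params$dense[[j]]$b, "+")
    if (with_cache) d_caches[[j]] <- list(X_in = A2, relu_mask = Z > 0)
    A2 <- Z * (Z > 0)
  }
  z <- drop(A2 %*% params$out$W) + params$out$b
  p <- 1 / (1 + exp(-z))
  list(p = p, conv_caches = caches, dense_caches = d_caches, dense_out = A2)
}

.backward <- function(params, plan, geom, fw, y, N) {
  grads <- list(conv = vector("list", 6), dense = vector("list", 2), out = NULL)
  dz <- (fw$p - y) / N # d(mean BCE)/dz through the sigmoid output
  grads$out <- list(W = crossprod(fw$dense_out, matrix(dz, ncol = 1)),
                    b = sum(dz))
  dA <- matrix(dz, ncol = 1) %*% t(params$out$W)
  for (j in 2:1) {
    dZ <- dA * fw$dense_caches[[j]]$relu_mask
    grads$dense[[j]] <- list(W = crossprod(fw$dense_caches[[j]]$X_in, dZ),
                             b = colSums(dZ))
    dA <- dZ %*% t(params$dense[[j]]$W)
  }
  # unflatten
  HWf <- prod(plan$out_shape)
  Cf <- plan$flat / HWf
  arr <- array(dA, c(N, HWf, Cf))
  dA <- matrix(aperm(arr, c(2, 1, 3)), N * HWf, Cf)
  for (i in 6:1) {
    ly <- plan$conv[[i]]
    cache <- fw$conv_caches[[i]]
    if (ly$pool)
      dA <- .pool_backward(dA, cache$pool, N * ly$H * ly$W)
    dZ <- dA * cache$relu_mask
    cb <- .conv_backward(dZ, cache$Xcols, params$conv[[i]]$W, ly$cin,
                         geom[[i]]$gidx)
    grads$conv[[i]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dX
  }
  grads
}

# flat list of (path) references into the nested parameter list,
# shared by the Adam state and the update loop
.param_refs <- function(params) {
  refs <- list()
  for (i in seq_along(params$conv)) {
    refs[[length(refs) + 1]] <- list("conv", i, "W")
    refs[[length(refs) + 1]] <- list("conv", i, "b")
  }
  for (j in seq_along(params$dense)) {
    refs[[length(refs) + 1]] <- list("dense", j, "W")
    refs[[length(refs) + 1]] <- list("dense", j, "b")
  }
  refs[[length(refs) + 1]] <- list("out", "W")
  refs[[length(refs) + 1]] <- list("out", "b")
  refs
}

.get_ref <- function(lst, ref) {
  for (r in ref) lst <- lst[[r]]
  lst
}

.set_ref <- function(lst, ref, value) {
  if (length(ref) == 1) {
    lst[[ref[[1]]]] <- value
    return(lst)
  }
  lst[[ref[[1]]]] <- .set_ref(lst[[ref[[1]]]], ref[-1], value)
  lst
}

.adam_init <- function(params, refs) {
  zeros <- lapply(refs, function(r) .get_ref(params, r) * 0)
  list(t = 0, m = zeros, v = zeros)
}

.adam_step <- function(params, grads, state, refs, lr, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(refs)) {
    g <- .get_ref(grads, refs[[i]])
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    upd <- lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
    params <- .set_ref(params, refs[[i]], .get_ref(params, refs[[i]]) - upd)
  }
  list(params = params, state = state)
}
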