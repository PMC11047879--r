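# Neural-network building blocks on top of the autodiff tape.
#
# Tensor convention: a batch of 1-D feature maps with C channels of length L
# is a (batch x L*C) matrix whose column (c-1)*L + l holds channel c,
# position l. Convolutions are expressed as one multiplication with a
# precomputed constant sparse im2col selector followed by a dense matmul,
# so the whole stack is differentiable to second order.

glorot <- function(fan_in, fan_out, dim) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(prod(dim), -lim, lim), dim[1L], dim[2L])
}

zeros <- function(r, c) matrix(0, r, c)
ones_row <- function(c) matrix(1, 1L, c)

## ---- dense -----------------------------------------------------------------

dense_init <- function(d_in, d_out) {
  list(W = glorot(d_in, d_out, c(d_in, d_out)), b = zeros(1L, d_out))
}

dense_fwd <- function(p, x) {
  t_add(t_mm(x, p$W), t_brow(p$b, nrow(tval(x))))
}

## ---- activations -----------------------------------------------------------

leaky_relu <- function(x, slope) {
  m <- (tval(x) > 0) * 1
  t_mul(x, m + slope * (1 - m))
}

elu <- function(x, alpha = 1) {
  m <- (tval(x) > 0) * 1
  neg <- t_mul(t_sub(t_exp(t_mul(x, 1 - m)), 1), (1 - m) * alpha)
  t_add(t_mul(x, m), neg)
}

# Inverted dropout; `mask` is pre-drawn so a step is reproducible.
dropout_mask <- function(dim, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(prod(dim)) >= rate) / (1 - rate), dim[1L], dim[2L])
}

apply_dropout <- function(x, mask) {
  if (is.null(mask)) x else t_mul(x, mask)
}

## ---- batch normalization ---------------------------------------------------

bn_init <- function(k) {
  list(gamma = ones_row(k), beta = zeros(1L, k))
}

bn_state_init <- function(k) {
  list(mean = zeros(1L, k), var = ones_row(k))
}

# Returns list(out, state). With batch statistics the (biased) moments of
# the current batch are used; `update` folds them into the running state
# with the given momentum (training only — sampling leaves state alone).
bn_fwd <- function(p, state, x, training, eps = 1e-5, momentum = 0.9,
                   update = training) {
  n <- nrow(tval(x))
  if (training && n > 1L) {
    mu <- t_mul(t_csum(x), 1 / n)
    xc <- t_sub(x, t_brow(mu, n))
    va <- t_mul(t_csum(t_mul(xc, xc)), 1 / n)
    xhat <- t_mul(xc, t_brow(t_pow(t_add(va, eps), -0.5), n))
    if (update) {
      state$mean <- momentum * state$mean + (1 - momentum) * tval(mu)
      state$var <- momentum * state$var + (1 - momentum) * tval(va)
    }
  } else {
    xc <- t_sub(x, t_brow(state$mean, n))
    xhat <- t_mul(xc, t_brow(1 / sqrt(state$var + eps), n))
  }
  out <- t_add(t_mul(xhat, t_brow(p$gamma, n)), t_brow(p$beta, n))
  list(out = out, state = state)
}

# Channel-wise BN for conv maps: reshape (batch x L*C) -> (batch*L x C),
# normalize per channel, reshape back.
bn_fwd_channels <- function(p, state, x, L, C, training, eps = 1e-5,
                            momentum = 0.9) {
  n <- nrow(tval(x))
  xr <- t_reshape(x, c(n * L, C))
  r <- bn_fwd(p, state, xr, training, eps, momentum)
  list(out = t_reshape(r$out, c(n, L * C)), state = r$state)
}

## ---- 1-D convolution -------------------------------------------------------

conv1d_out_len <- function(L, kernel, stride, pad, dilation) {
  span <- (kernel - 1L) * dilation + 1L
  as.integer(floor((L + 2L * pad - span) / stride) + 1L)
}

# im2col selector: maps (batch x L_in*C_in) to the column-expanded
# (batch x L_out*kernel*C_in) matrix; out-of-range taps are zero columns.
# Stored as a gather index plus the sparse adjoint for the backward
# scatter-add (each expanded column has at most one source).
conv1d_selector <- function(L_in, C_in, kernel, stride, pad, dilation) {
  L_out <- conv1d_out_len(L_in, kernel, stride, pad, dilation)
  n_out <- L_out * kernel * C_in
  src <- integer(n_out)
  for (ci in seq_len(C_in)) {
    for (ki in seq_len(kernel)) {
      tap <- (ci - 1L) * kernel + ki
      l_src <- (seq_len(L_out) - 1L) * stride + 1L + (ki - 1L) * dilation - pad
      keep <- l_src >= 1L & l_src <= L_in
      src[(tap - 1L) * L_out + which(keep)] <- (ci - 1L) * L_in + l_src[keep]
    }
  }
  keep <- src > 0L
  tP <- Matrix::sparseMatrix(i = which(keep), j = src[keep],
                             dims = c(n_out, L_in * C_in), x = 1)
  list(src = src, zero_cols = which(!keep), tP = tP, L_out = L_out)
}

conv1d_init <- function(C_in, C_out, kernel) {
  fan_in <- C_in * kernel
  list(W = glorot(fan_in, C_out, c(fan_in, C_out)), b = zeros(1L, C_out))
}

# p: conv params; sel: precomputed selector; returns (batch x L_out*C_out).
conv1d_fwd <- function(p, x, sel, L_out, kernel, C_in) {
  n <- nrow(tval(x))
  C_out <- ncol(tval(p$W))
  xc <- t_gather_cols(x, sel)
  x2 <- t_reshape(xc, c(n * L_out, kernel * C_in))
  y2 <- t_add(t_mm(x2, p$W), t_brow(p$b, n * L_out))
  t_reshape(y2, c(n, L_out * C_out))
}

## ---- LSTM ------------------------------------------------------------------

# Peephole LSTM (gates receive the previous cell state through diagonal
# peephole weights; the candidate does not):
#   i_t = sigma(W_ix x_t + W_ih h_{t-1} + w_ic . c_{t-1} + b_i)
#   f_t = sigma(W_fx x_t + W_fh h_{t-1} + w_fc . c_{t-1} + b_f)
#   o_t = sigma(W_ox x_t + W_oh h_{t-1} + w_oc . c_{t-1} + b_o)
#   c_t = f_t . c_{t-1} + i_t . tanh(W_cx x_t + W_ch h_{t-1} + b_c)
#   h_t = o_t . tanh(c_t)
lstm_init <- function(d_in, H) {
  p <- list(
    Wx = glorot(d_in + H, 4L * H, c(d_in, 4L * H)),
    Wh = glorot(d_in + H, 4L * H, c(H, 4L * H)),
    b  = zeros(1L, 4L * H),
    pi = zeros(1L, H), pf = zeros(1L, H), po = zeros(1L, H)
  )
  # forget-gate bias 1: standard initialization for stable early training
  p$b[1L, (H + 1L):(2L * H)] <- 1
  p
}

# One step, fused into a single tape node carrying cbind(h_t, c_t) with a
# hand-derived backward rule (first-order only; the recurrent path never
# sits under the double-backprop gradient penalty). x: (batch x d_in);
# h, c: (batch x H). Returns list(h, c) as column slices of the node.
lstm_step <- function(p, x, h, c, H) {
  xv <- tval(x); hv <- tval(h); cv <- tval(c)
  Wx <- tval(p$Wx); Wh <- tval(p$Wh); bv <- tval(p$b)
  piv <- tval(p$pi); pfv <- tval(p$pf); pov <- tval(p$po)
  n <- nrow(xv)
  z <- xv %*% Wx + hv %*% Wh + bv[rep.int(1L, n), , drop = FALSE]
  i_idx <- 1:H; f_idx <- (H + 1L):(2L * H)
  o_idx <- (2L * H + 1L):(3L * H); g_idx <- (3L * H + 1L):(4L * H)
  sig <- function(a) 1 / (1 + exp(-a))
  ig <- sig(z[, i_idx, drop = FALSE] +
              cv * piv[rep.int(1L, n), , drop = FALSE])
  fg <- sig(z[, f_idx, drop = FALSE] +
              cv * pfv[rep.int(1L, n), , drop = FALSE])
  og <- sig(z[, o_idx, drop = FALSE] +
              cv * pov[rep.int(1L, n), , drop = FALSE])
  gg <- tanh(z[, g_idx, drop = FALSE])
  c_new <- fg * cv + ig * gg
  tc <- tanh(c_new)
  h_new <- og * tc
  node <- mknode(cbind(h_new, c_new),
                 list(x, h, c, p$Wx, p$Wh, p$b, p$pi, p$pf, p$po),
                 function(g) {
                   gv <- tval(g)
                   dh <- gv[, i_idx, drop = FALSE]
                   dc <- gv[, f_idx, drop = FALSE] + dh * og * (1 - tc^2)
                   do_ <- dh * tc
                   df <- dc * cv
                   di <- dc * gg
                   dg <- dc * ig
                   dzi <- di * ig * (1 - ig)
                   dzf <- df * fg * (1 - fg)
                   dzo <- do_ * og * (1 - og)
                   dzg <- dg * (1 - gg^2)
                   dc_prev <- dc * fg +
                     dzi * piv[rep.int(1L, n), , drop = FALSE] +
                     dzf * pfv[rep.int(1L, n), , drop = FALSE] +
                     dzo * pov[rep.int(1L, n), , drop = FALSE]
                   dz <- cbind(dzi, dzf, dzo, dzg)
                   list(dz %*% t(Wx),                  # x
                        dz %*% t(Wh),                  # h
                        dc_prev,                       # c
                        t(xv) %*% dz,                  # Wx
                        t(hv) %*% dz,                  # Wh
                        matrix(colSums(dz), 1L),       # b
                        matrix(colSums(dzi * cv), 1L), # pi
                        matrix(colSums(dzf * cv), 1L), # pf
                        matrix(colSums(dzo * cv), 1L)) # po
                 })
  list(h = t_cols(node, i_idx), c = t_cols(node, f_idx))
}

# Run a layer over a list of per-step inputs; returns list of h_t.
lstm_layer_fwd <- function(p, xs, H) {
  n <- nrow(tval(xs[[1L]]))
  h <- zeros(n, H)
  c <- zeros(n, H)
  out <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    st <- lstm_step(p, xs[[t]], h, c, H)
    h <- st$h
    c <- st$c
    out[[t]] <- h
  }
  out
}

## ---- parameter utilities and Adam ------------------------------------------

# Parameters live in nested named lists of matrices. Flatten for the
# optimizer and for leaf creation.
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p[[nm]])) {
      out <- c(out, flatten_params(p[[nm]], key))
    } else {
      out[[key]] <- p[[nm]]
    }
  }
  out
}

unflatten_assign <- function(p, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1L]]
    p[[path]] <- flat[[key]]
  }
  p
}

n_params <- function(p) sum(vapply(flatten_params(p), length, 1L))

# Wrap every parameter matrix as a differentiable leaf (tape must be open).
leaf_params <- function(flat) lapply(flat, tleaf)

adam_init <- function(flat) {
  list(m = lapply(flat, function(w) w * 0),
       v = lapply(flat, function(w) w * 0),
       t = 0L)
}

adam_step <- function(flat, grads, opt, lr, beta1 = 0.5, beta2 = 0.9,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (key in names(flat)) {
    g <- grads[[key]]
    opt$m[[key]] <- beta1 * opt$m[[key]] + (1 - beta1) * g
    opt$v[[key]] <- beta2 * opt$v[[key]] + (1 - beta2) * g * g
    mhat <- opt$m[[key]] / bc1
    vhat <- opt$v[[key]] / bc2
    flat[[key]] <- flat[[key]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = flat, opt = opt)
}
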