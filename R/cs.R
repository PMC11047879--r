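#' Sparse binary measurement matrix
#'
#' Builds an M x N sensing matrix with exactly `ones_per_column` ones per
#' column, dealt in balanced rounds (each round distributes row indices
#' as evenly as possible), so row weights stay near-uniform and the
#' degenerate case M = N with one 1 per column yields a permutation
#' matrix. The Moore-Penrose pseudoinverse is precomputed for the lift.
#'
#' @param M number of measurements (1 <= M <= N).
#' @param N signal length (default 500).
#' @param ones_per_column ones per column (default 4; must be <= M).
#' @param seed integer seed.
#' @return object of class `measurement_matrix` with fields `phi`,
#'   `pinv`, `M`, `N`, `cr` (compression ratio M/N), `ones_per_column`,
#'   `seed`.
#' @export
measurement_matrix <- function(M, N = 500L, ones_per_column = 4L, seed = 1L) {
  M <- as.integer(M); N <- as.integer(N)
  ones_per_column <- as.integer(ones_per_column)
  if (M < 1L || M > N) stop("need 1 <= M <= N")
  if (ones_per_column < 1L || ones_per_column > M) {
    stop("infeasible ones_per_column")
  }
  rows <- with_seed(seed, {
    rmat <- matrix(NA_integer_, ones_per_column, N)
    for (r in seq_len(ones_per_column)) {
      deal <- sample(rep_len(seq_len(M), N))
      if (r > 1L) {
        for (j in seq_len(N)) {
          if (!(deal[j] %in% rmat[seq_len(r - 1L), j])) next
          # swap with another column to keep all columns duplicate-free
          for (j2 in c(seq_len(N)[-j])) {
            if (!(deal[j2] %in% rmat[seq_len(r - 1L), j]) &&
                !(deal[j] %in% rmat[seq_len(r - 1L), j2]) &&
                deal[j2] != deal[j]) {
              tmp <- deal[j]; deal[j] <- deal[j2]; deal[j2] <- tmp
              break
            }
          }
          if (deal[j] %in% rmat[seq_len(r - 1L), j]) {
            # no swap partner: redraw from rows unused in this column
            free <- setdiff(seq_len(M), rmat[seq_len(r - 1L), j])
            deal[j] <- free[sample.int(length(free), 1L)]
          }
        }
      }
      rmat[r, ] <- deal
    }
    rmat
  })
  phi <- matrix(0, M, N)
  for (j in seq_len(N)) phi[rows[, j], j] <- 1
  structure(list(phi = phi, pinv = MASS::ginv(phi), M = M, N = N,
                 cr = M / N, ones_per_column = ones_per_column,
                 seed = as.integer(seed)),
            class = "measurement_matrix")
}

#' @exportS3Method base::print
print.measurement_matrix <- function(x, ...) {
  cat(sprintf("<measurement_matrix> %d x %d, %d ones/column, CR = %.0f%%\n",
              x$M, x$N, x$ones_per_column, 100 * x$cr))
  invisible(x)
}

#' Project frames to the measurement space: y = phi x
#' @param x numeric vector of length N, or matrix / [frame_set()] with
#'   frames in rows.
#' @param mm a [measurement_matrix()].
#' @return measurement vector (or matrix, measurements in rows).
#' @export
cs_compress <- function(x, mm) {
  stopifnot(inherits(mm, "measurement_matrix"))
  if (inherits(x, "frame_set")) x <- x$frames
  if (is.matrix(x)) {
    if (ncol(x) != mm$N) stop("length mismatch")
    x %*% t(mm$phi)
  } else {
    if (length(x) != mm$N) stop("length mismatch")
    as.numeric(mm$phi %*% x)
  }
}

#' Pseudoinverse lift back to signal space: x0 = phi^+ y
#' @param y measurement vector of length M (or matrix, rows).
#' @param mm a [measurement_matrix()].
#' @return length-N initial reconstruction (or matrix, rows).
#' @export
cs_lift <- function(y, mm) {
  stopifnot(inherits(mm, "measurement_matrix"))
  if (is.matrix(y)) {
    if (ncol(y) != mm$M) stop("length mismatch")
    y %*% t(mm$pinv)
  } else {
    if (length(y) != mm$M) stop("length mismatch")
    as.numeric(mm$pinv %*% y)
  }
}

#' Percentage root-mean-square distortion
#'
#' `PRD = 100 * ||x_hat - x||_2 / ||x||_2`; lower is better (0 for a
#' perfect reconstruction).
#'
#' @param x reference frame (non-zero norm).
#' @param x_hat reconstruction of equal length.
#' @return PRD in percent.
#' @export
prd <- function(x, x_hat) {
  if (length(x) != length(x_hat)) stop("length mismatch")
  nx <- sqrt(sum(x^2))
  if (nx == 0) stop("zero reference norm")
  100 * sqrt(sum((x_hat - x)^2)) / nx
}

#' Residual reconstructor architecture
#'
#' A 16-channel convolutional stem, `blocks` residual blocks of six
#' dilated convolutions each (identity skip; block input and output are
#' both 16-channel maps of the full signal length), a one-channel
#' convolutional head and a fully connected output layer.
#'
#' @param input_len signal length (default 500).
#' @param stem_filters stem channels (default 16).
#' @param stem_kernel stem kernel size (default 3).
#' @param blocks number of residual blocks (default 2).
#' @param block_filters filters of the six in-block convolutions
#'   (default 32, 64, 128, 64, 32, 16; the last must equal
#'   `stem_filters` so the skip addition is well-formed).
#' @param block_kernels kernel sizes of the in-block convolutions
#'   (default 7, 7, 5, 5, 3, 3).
#' @param dilation dilation of the in-block convolutions (default 2).
#' @param head_kernel head kernel size (default 3).
#' @return object of class `cs_resnet_spec`.
#' @export
cs_resnet_spec <- function(input_len = 500L, stem_filters = 16L,
                           stem_kernel = 3L, blocks = 2L,
                           block_filters = c(32L, 64L, 128L, 64L, 32L, 16L),
                           block_kernels = c(7L, 7L, 5L, 5L, 3L, 3L),
                           dilation = 2L, head_kernel = 3L) {
  if (length(block_filters) != length(block_kernels)) {
    stop("block_filters and block_kernels must have equal length")
  }
  if (block_filters[length(block_filters)] != stem_filters) {
    stop("last block filter count must equal stem_filters for the identity skip")
  }
  if (any(block_kernels %% 2L == 0L) || stem_kernel %% 2L == 0L) {
    stop("kernels must be odd so padding can keep the length unchanged")
  }
  structure(list(input_len = as.integer(input_len),
                 stem_filters = as.integer(stem_filters),
                 stem_kernel = as.integer(stem_kernel),
                 blocks = as.integer(blocks),
                 block_filters = as.integer(block_filters),
                 block_kernels = as.integer(block_kernels),
                 dilation = as.integer(dilation),
                 head_kernel = as.integer(head_kernel)),
            class = "cs_resnet_spec")
}

#' Build the residual reconstructor
#' @param spec a [cs_resnet_spec()].
#' @param seed integer seed for initialization.
#' @return object of class `cs_resnet`.
#' @export
build_cs_resnet <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cs_resnet_spec"))
  L <- spec$input_len
  nb <- length(spec$block_filters)
  sel_stem <- conv1d_selector(L, 1L, spec$stem_kernel, 1L,
                              (spec$stem_kernel - 1L) %/% 2L, 1L)
  sels_block <- vector("list", nb)
  Cin <- c(spec$stem_filters, spec$block_filters[-nb])
  for (i in seq_len(nb)) {
    k <- spec$block_kernels[i]
    pad <- spec$dilation * (k - 1L) %/% 2L
    sels_block[[i]] <- conv1d_selector(L, Cin[i], k, 1L, pad, spec$dilation)
  }
  sel_head <- conv1d_selector(L, spec$stem_filters, spec$head_kernel, 1L,
                              (spec$head_kernel - 1L) %/% 2L, 1L)
  params <- with_seed(seed, {
    p <- list(stem = conv1d_init(1L, spec$stem_filters, spec$stem_kernel))
    for (b in seq_len(spec$blocks)) {
      for (i in seq_len(nb)) {
        p[[sprintf("b%d_conv%d", b, i)]] <-
          conv1d_init(Cin[i], spec$block_filters[i], spec$block_kernels[i])
      }
    }
    p$head_conv <- conv1d_init(spec$stem_filters, 1L, spec$head_kernel)
    p$head_fc <- dense_init(L, L)
    p
  })
  structure(list(spec = spec, params = params, sel_stem = sel_stem,
                 sels_block = sels_block, sel_head = sel_head,
                 Cin = Cin, seed = as.integer(seed)),
            class = "cs_resnet")
}

# Forward: (batch x L) lifted input -> (batch x L) reconstruction.
cs_resnet_fwd <- function(net, params, x) {
  spec <- net$spec
  L <- spec$input_len
  nb <- length(spec$block_filters)
  a <- conv1d_fwd(params$stem, x, net$sel_stem, L, spec$stem_kernel, 1L)
  a <- elu(a)
  for (b in seq_len(spec$blocks)) {
    inp <- a
    for (i in seq_len(nb)) {
      a <- conv1d_fwd(params[[sprintf("b%d_conv%d", b, i)]], a,
                      net$sels_block[[i]], L, spec$block_kernels[i],
                      net$Cin[i])
      a <- elu(a)
    }
    a <- t_add(a, inp)
  }
  h <- conv1d_fwd(params$head_conv, a, net$sel_head, L, spec$head_kernel,
                  spec$stem_filters)
  dense_fwd(params$head_fc, h)
}

#' Reconstruct frames from measurements
#' @param net a trained `cs_resnet`.
#' @param y measurement matrix (rows) or vector.
#' @param mm the [measurement_matrix()] used for sensing.
#' @return reconstructed frames (rows) or vector.
#' @export
cs_reconstruct <- function(net, y, mm) {
  x0 <- cs_lift(y, mm)
  vec <- !is.matrix(x0)
  if (vec) x0 <- matrix(x0, 1L)
  out <- tval(cs_resnet_fwd(net, net$params, x0))
  if (vec) as.numeric(out) else out
}

#' Train the reconstructor by mean squared error
#'
#' Frames are sensed with `mm`, lifted with the pseudoinverse and the
#' network is fit to map the lift back to the original frame (Adam,
#' MSE).
#'
#' @param net a `cs_resnet`.
#' @param frames training [frame_set()] or matrix (frames in rows).
#' @param mm a [measurement_matrix()].
#' @param epochs training epochs (default 30).
#' @param batch_size minibatch size (default 32).
#' @param lr Adam learning rate (default 0.001).
#' @param seed integer seed.
#' @return list with the trained `net` and `history` (epoch, mse).
#' @export
train_reconstructor <- function(net, frames, mm, epochs = 30L,
                                batch_size = 32L, lr = 0.001, seed = 1L) {
  stopifnot(inherits(net, "cs_resnet"))
  X <- if (inherits(frames, "frame_set")) frames$frames else as.matrix(frames)
  if (nrow(X) == 0L) stop("empty training set")
  X0 <- cs_lift(cs_compress(X, mm), mm)
  n <- nrow(X)
  bsz <- min(batch_size, n)
  params <- net$params
  opt <- adam_init(flatten_params(params))
  hist <- numeric(epochs)
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      idx <- sample.int(n)
      nb <- max(1L, floor(n / bsz))
      losses <- numeric(nb)
      for (bi in seq_len(nb)) {
        take <- idx[((bi - 1L) * bsz + 1L):min(bi * bsz, n)]
        tape_start()
        lf <- leafify(params)
        out <- cs_resnet_fwd(net, lf$nested, X0[take, , drop = FALSE])
        err <- t_sub(out, X[take, , drop = FALSE])
        loss <- t_mean(t_mul(err, err))
        losses[bi] <- as.numeric(tval(loss))
        gs <- grad_values(tape_grad(loss, lf$leaves))
        tape_stop()
        st <- adam_step(flatten_params(params), gs, opt, lr, 0.9, 0.999)
        params <- unflatten_assign(params, st$params)
        opt <- st$opt
      }
      hist[e] <- mean(losses)
    }
  })
  net$params <- params
  list(net = net, history = data.frame(epoch = seq_len(epochs), mse = hist))
}

trunc2 <- function(x) trunc(x * 100) / 100

#' Augmentation-benefit benchmark
#'
#' For every compression ratio and augmentation fraction, trains the
#' reconstructor on the real training frames plus that fraction of the
#' generated frames and reports the mean PRD on the held-out test
#' frames, together with the improvement deltas
#' `PRD(none) - PRD(fraction)` truncated to 2 decimals.
#'
#' @param real_train,generated,test [frame_set()]s (or matrices) of
#'   equal frame length.
#' @param fractions percentages of the generated set to add
#'   (default 0, 25, 50, 75, 100).
#' @param cr_grid compression ratios in percent (default 10-90 by 10 is
#'   the full grid; pass a subset for desk-scale runs).
#' @param spec reconstructor spec; defaults to [cs_resnet_spec()] at the
#'   frame length.
#' @param ones_per_column sensing-matrix density (default 4).
#' @param epochs,batch_size,lr reconstructor training settings.
#' @param seed integer master seed (sub-seeds are derived per cell).
#' @return object of class `prd_table`: list with `prd` (CR x fraction
#'   matrix, percent), `deltas`, and `meta`.
#' @export
augmentation_benchmark <- function(real_train, generated, test,
                                   fractions = c(0, 25, 50, 75, 100),
                                   cr_grid = c(30),
                                   spec = NULL, ones_per_column = 4L,
                                   epochs = 30L, batch_size = 32L,
                                   lr = 0.001, seed = 1L) {
  R <- if (inherits(real_train, "frame_set")) real_train$frames
       else as.matrix(real_train)
  G <- if (inherits(generated, "frame_set")) generated$frames
       else as.matrix(generated)
  Te <- if (inherits(test, "frame_set")) test$frames else as.matrix(test)
  if (nrow(Te) == 0L) stop("empty test set")
  N <- ncol(R)
  stopifnot(ncol(G) == N, ncol(Te) == N)
  if (is.null(spec)) spec <- cs_resnet_spec(input_len = N)
  fractions <- sort(unique(fractions))
  P <- matrix(NA_real_, length(cr_grid), length(fractions),
              dimnames = list(paste0(cr_grid, "%"),
                              ifelse(fractions == 0, "none",
                                     paste0("add", fractions))))
  for (ci in seq_along(cr_grid)) {
    M <- max(1L, round(cr_grid[ci] / 100 * N))
    mm <- measurement_matrix(M, N, ones_per_column,
                             seed = sub_seed(seed, ci))
    for (fi in seq_along(fractions)) {
      k <- round(fractions[fi] / 100 * nrow(G))
      Xtr <- rbind(R, G[seq_len(k), , drop = FALSE])
      net <- build_cs_resnet(spec, seed = sub_seed(seed, 100L + ci))
      tr <- train_reconstructor(net, Xtr, mm, epochs = epochs,
                                batch_size = batch_size, lr = lr,
                                seed = sub_seed(seed, 200L + 10L * ci + fi))
      rec <- cs_reconstruct(tr$net, cs_compress(Te, mm), mm)
      P[ci, fi] <- mean(vapply(seq_len(nrow(Te)),
                               function(i) prd(Te[i, ], rec[i, ]),
                               numeric(1L)))
    }
  }
  structure(list(prd = P, deltas = prd_delta_matrix(P),
                 meta = list(ones_per_column = ones_per_column,
                             epochs = epochs, batch_size = batch_size,
                             lr = lr, seed = seed,
                             n_real = nrow(R), n_generated = nrow(G),
                             n_test = nrow(Te))),
            class = "prd_table")
}

# none-minus-fraction deltas, truncated to 2 decimals
prd_delta_matrix <- function(P) {
  if (!("none" %in% colnames(P))) return(NULL)
  base <- P[, "none"]
  D <- P[, setdiff(colnames(P), "none"), drop = FALSE]
  trunc2(base - D)
}

#' @exportS3Method base::print
print.prd_table <- function(x, ...) {
  cat("<prd_table> mean test PRD (%) by compression ratio and augmentation:\n")
  print(round(x$prd, 4))
  if (!is.null(x$deltas)) {
    cat("improvement over no augmentation (truncated to 2 dp):\n")
    print(x$deltas)
  }
  invisible(x)
}
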