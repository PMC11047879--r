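# Reverse-mode automatic differentiation on a Wengert tape.
#
# Values are numeric matrices (scalars are 1x1). Recorded nodes are small
# environments holding the value, the parent nodes and a vector-Jacobian
# product rule expressed in terms of the same primitives, so that running
# the backward pass with recording switched on yields a differentiable
# graph of the gradient itself (second-order gradients, as required by the
# gradient penalty of the Wasserstein critic).

.tape <- new.env(parent = emptyenv())
.tape$active <- FALSE
.tape$nodes <- list()
.tape$n <- 0L

#' @keywords internal
tape_start <- function() {
  .tape$active <- TRUE
  .tape$nodes <- vector("list", 4096L)
  .tape$n <- 0L
  invisible(NULL)
}

#' @keywords internal
tape_stop <- function() {
  .tape$active <- FALSE
  .tape$nodes <- list()
  .tape$n <- 0L
  invisible(NULL)
}

#' Evaluate an expression with gradient recording enabled
#' @param expr expression to evaluate under an open tape
#' @keywords internal
with_tape <- function(expr) {
  tape_start()
  on.exit(tape_stop())
  expr
}

is_tn <- function(x) inherits(x, "tn")

#' Underlying numeric value of a tape node (identity on plain numerics)
#' @param x tape node or numeric
#' @keywords internal
tval <- function(x) if (is_tn(x)) x$v else x

t_req <- function(x) is_tn(x) && isTRUE(x$req)

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

# Create a leaf node (parameter or input we differentiate with respect to).
tleaf <- function(v, req = TRUE) {
  nd <- new.env(parent = emptyenv())
  nd$v <- as_mat(v)
  nd$req <- req
  nd$parents <- NULL
  nd$vjp <- NULL
  if (.tape$active) {
    .tape$n <- .tape$n + 1L
    if (.tape$n > length(.tape$nodes)) {
      length(.tape$nodes) <- 2L * length(.tape$nodes)
    }
    nd$id <- .tape$n
    .tape$nodes[[.tape$n]] <- nd
  } else {
    nd$id <- 0L
  }
  class(nd) <- "tn"
  nd
}

# Record an interior node; returns the raw value when nothing requires grad.
mknode <- function(v, parents, vjp = NULL) {
  track <- FALSE
  if (.tape$active) {
    for (p in parents) if (t_req(p)) { track <- TRUE; break }
  }
  if (!track) return(v)
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$req <- TRUE
  nd$parents <- parents
  nd$vjp <- vjp
  .tape$n <- .tape$n + 1L
  if (.tape$n > length(.tape$nodes)) {
    length(.tape$nodes) <- 2L * length(.tape$nodes)
  }
  nd$id <- .tape$n
  .tape$nodes[[.tape$n]] <- nd
  class(nd) <- "tn"
  nd
}

# Reduce a gradient to the shape of the target (scalar broadcasting only).
unbcast <- function(g, target_v) {
  if (length(target_v) == 1L && length(tval(g)) > 1L) t_sum(g) else g
}

## ---- primitives ------------------------------------------------------------

t_add <- function(a, b) {
  v <- tval(a) + tval(b)
  mknode(v, list(a, b), function(g) list(unbcast(g, tval(a)), unbcast(g, tval(b))))
}

t_sub <- function(a, b) {
  v <- tval(a) - tval(b)
  mknode(v, list(a, b), function(g) list(unbcast(g, tval(a)),
                                         unbcast(t_neg(g), tval(b))))
}

t_neg <- function(a) {
  mknode(-tval(a), list(a), function(g) list(t_neg(g)))
}

t_mul <- function(a, b) {
  v <- tval(a) * tval(b)
  mknode(v, list(a, b), function(g) list(unbcast(t_mul(g, b), tval(a)),
                                         unbcast(t_mul(g, a), tval(b))))
}

t_div <- function(a, b) {
  v <- tval(a) / tval(b)
  mknode(v, list(a, b), function(g) {
    ga <- t_div(g, b)
    gb <- t_neg(t_div(t_mul(g, a), t_mul(b, b)))
    list(unbcast(ga, tval(a)), unbcast(gb, tval(b)))
  })
}

t_mm <- function(a, b) {
  v <- tval(a) %*% tval(b)
  mknode(v, list(a, b), function(g) list(t_mm(g, t_tr(b)), t_mm(t_tr(a), g)))
}

# Multiply by a constant sparse matrix (im2col selection for convolutions).
t_smm <- function(a, P) {
  v <- as.matrix(tval(a) %*% P)
  tP <- Matrix::t(P)
  mknode(v, list(a), function(g) list(t_smm(g, tP)))
}

# im2col column gather: each output column is one input column or zero.
# `sel` carries `src` (0 = all-zero column) and the precomputed sparse
# transpose `tP` used by the adjoint scatter-add.
t_gather_cols <- function(a, sel) {
  av <- tval(a)
  v <- av[, pmax(sel$src, 1L), drop = FALSE]
  if (length(sel$zero_cols)) v[, sel$zero_cols] <- 0
  mknode(v, list(a), function(g) list(t_scatter_cols(g, sel)))
}

t_scatter_cols <- function(a, sel) {
  v <- as.matrix(tval(a) %*% sel$tP)
  mknode(v, list(a), function(g) list(t_gather_cols(g, sel)))
}

t_tr <- function(a) {
  mknode(t(tval(a)), list(a), function(g) list(t_tr(g)))
}

t_sum <- function(a) {
  v <- matrix(sum(tval(a)), 1L, 1L)
  d <- dim(as_mat(tval(a)))
  mknode(v, list(a), function(g) list(t_bcast(g, d)))
}

t_bcast <- function(s, d) {
  v <- matrix(tval(s)[1L], d[1L], d[2L])
  mknode(v, list(s), function(g) list(t_sum(g)))
}

t_csum <- function(a) {
  av <- tval(a)
  v <- matrix(colSums(av), 1L, ncol(av))
  n <- nrow(av)
  mknode(v, list(a), function(g) list(t_brow(g, n)))
}

t_brow <- function(b, n) {
  bv <- tval(b)
  v <- bv[rep.int(1L, n), , drop = FALSE]
  mknode(v, list(b), function(g) list(t_csum(g)))
}

t_reshape <- function(a, d) {
  v <- tval(a)
  d0 <- dim(as_mat(v))
  dim(v) <- d
  mknode(v, list(a), function(g) list(t_reshape(g, d0)))
}

t_cols <- function(a, idx) {
  av <- tval(a)
  v <- av[, idx, drop = FALSE]
  tot <- ncol(av)
  mknode(v, list(a), function(g) list(t_colscatter(g, idx, tot)))
}

t_colscatter <- function(a, idx, total) {
  av <- tval(a)
  v <- matrix(0, nrow(av), total)
  v[, idx] <- av
  mknode(v, list(a), function(g) list(t_cols(g, idx)))
}

t_cbind <- function(lst) {
  vs <- lapply(lst, tval)
  widths <- vapply(vs, ncol, 1L)
  v <- do.call(cbind, vs)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  mknode(v, lst, function(g) {
    lapply(seq_along(lst), function(k) t_cols(g, starts[k]:ends[k]))
  })
}

t_pow <- function(a, p) {
  v <- tval(a)^p
  mknode(v, list(a), function(g) list(t_mul(g, t_mul(t_pow(a, p - 1), p))))
}

t_exp <- function(a) {
  out <- mknode(exp(tval(a)), list(a), NULL)
  if (is_tn(out)) out$vjp <- function(g) list(t_mul(g, out))
  out
}

t_log <- function(a) {
  mknode(log(tval(a)), list(a), function(g) list(t_div(g, a)))
}

t_tanh <- function(a) {
  out <- mknode(tanh(tval(a)), list(a), NULL)
  if (is_tn(out)) out$vjp <- function(g) list(t_mul(g, t_sub(1, t_mul(out, out))))
  out
}

t_sigmoid <- function(a) {
  out <- mknode(1 / (1 + exp(-tval(a))), list(a), NULL)
  if (is_tn(out)) {
    out$vjp <- function(g) list(t_mul(g, t_mul(out, t_sub(1, out))))
  }
  out
}

t_sqrt <- function(a) t_pow(a, 0.5)

t_mean <- function(a) t_mul(t_sum(a), 1 / length(tval(a)))

## ---- backward --------------------------------------------------------------

#' Gradients of a scalar node with respect to leaves
#'
#' @param root scalar (1x1) tape node.
#' @param wrt list of leaf nodes.
#' @param create_graph record the backward computation so the returned
#'   gradients are themselves differentiable nodes.
#' @return list of gradients aligned with `wrt`; raw matrices unless
#'   `create_graph = TRUE`.
#' @keywords internal
tape_grad <- function(root, wrt, create_graph = FALSE) {
  stopifnot(is_tn(root), length(tval(root)) == 1L)
  top <- root$id
  grads <- vector("list", top)
  grads[[top]] <- matrix(1, 1L, 1L)
  prev <- .tape$active
  .tape$active <- isTRUE(create_graph)
  on.exit(.tape$active <- prev)
  nodes <- .tape$nodes
  for (i in top:1L) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- nodes[[i]]
    if (is.null(nd$parents)) next
    pg <- nd$vjp(g)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (!t_req(p)) next
      cur <- grads[[p$id]]
      grads[[p$id]] <- if (is.null(cur)) pg[[k]] else t_add(cur, pg[[k]])
    }
    grads[i] <- list(NULL)
  }
  lapply(wrt, function(w) {
    g <- grads[[w$id]]
    if (is.null(g)) matrix(0, nrow(w$v), ncol(w$v)) else g
  })
}
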