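# Minimal reverse-mode tape for the segmentation network.
#
# Values are numeric arrays (H, W, C). A tape records nodes in creation
# order; each op node stores its parents and a backward closure mapping
# the node's output gradient to a list of parent gradients. Parameters
# enter the tape as leaves; their gradients are read off the leaves
# after the backward sweep. The network is small and static, so a full
# framework is unnecessary — this keeps every gradient explicit and
# unit-checkable against numerical differentiation.

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

tape_node <- function(tape, value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$grad <- NULL
  tape$n <- tape$n + 1L
  node$id <- tape$n
  tape$nodes[[tape$n]] <- node
  node
}

tape_leaf <- function(tape, value) tape_node(tape, value)

# reverse sweep from `root`, whose gradient must be pre-seeded
tape_backward <- function(tape, root) {
  if (is.null(root$grad)) abort("seed root$grad before calling tape_backward()")
  for (i in rev(seq_len(tape$n))) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad) || is.null(node$backward)) next
    grads <- node$backward(node$grad, node)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      g <- grads[[j]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

as_hwc <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

# ---- ops ------------------------------------------------------------------

# 2-D convolution; w dims (kh, kw, Cin, Cout), b length Cout
op_conv <- function(tape, x, w, b, stride = 1L, pad = 1L) {
  dm <- dim(x$value)
  kd <- dim(w$value)
  cols <- im2col_cpp(x$value, dm[1], dm[2], dm[3], kd[1], kd[2], stride, pad)
  Ho <- (dm[1] + 2L * pad - kd[1]) %/% stride + 1L
  Wo <- (dm[2] + 2L * pad - kd[2]) %/% stride + 1L
  Wm <- matrix(w$value, nrow = kd[1] * kd[2] * kd[3])
  ymat <- crossprod(cols, Wm)                       # (Ho*Wo) x Cout
  ymat <- sweep(ymat, 2L, b$value, "+")
  node <- tape_node(tape, array(ymat, dim = c(Ho, Wo, kd[4])),
                    parents = list(x, w, b))
  node$backward <- function(grad, node) {
    dymat <- matrix(grad, Ho * Wo, kd[4])
    dW <- array(cols %*% dymat, dim = kd)
    db <- colSums(dymat)
    dcols <- Wm %*% t(dymat)
    dx <- col2im_cpp(dcols, dm[1], dm[2], dm[3], kd[1], kd[2], stride, pad)
    list(dx, dW, db)
  }
  node
}

# transposed convolution, kernel 2, stride 2 (2x upsampling);
# w dims (2, 2, Cout, Cin), b length Cout
op_convT2 <- function(tape, x, w, b) {
  dm <- dim(x$value)
  kd <- dim(w$value)
  Cout <- kd[3]; Cin <- kd[4]
  Wm <- matrix(w$value, nrow = 4L * Cout)           # (2*2*Cout) x Cin
  xmat <- matrix(x$value, dm[1] * dm[2], Cin)
  colsY <- Wm %*% t(xmat)                           # (2*2*Cout) x (H*W)
  Ho <- 2L * dm[1]; Wo <- 2L * dm[2]
  y <- col2im_cpp(colsY, Ho, Wo, Cout, 2L, 2L, 2L, 0L)
  y <- y + rep(b$value, each = Ho * Wo)
  node <- tape_node(tape, array(y, dim = c(Ho, Wo, Cout)), parents = list(x, w, b))
  node$backward <- function(grad, node) {
    dcolsY <- im2col_cpp(grad, Ho, Wo, Cout, 2L, 2L, 2L, 0L)
    dx <- array(t(dcolsY) %*% Wm, dim = dm)
    dW <- array(dcolsY %*% xmat, dim = kd)
    db <- colSums(matrix(grad, Ho * Wo, Cout))
    list(dx, dW, db)
  }
  node
}

op_maxpool2 <- function(tape, x) {
  dm <- dim(x$value)
  fw <- maxpool2_fwd_cpp(x$value, dm[1], dm[2], dm[3])
  node <- tape_node(tape, fw$y, parents = list(x))
  idx <- fw$idx
  node$backward <- function(grad, node) {
    list(maxpool2_bwd_cpp(grad, idx, dm[1], dm[2], dm[3]))
  }
  node
}

op_relu <- function(tape, x) {
  y <- pmax(x$value, 0)
  node <- tape_node(tape, y, parents = list(x))
  pos <- x$value > 0
  node$backward <- function(grad, node) list(grad * pos)
  node
}

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$value))
  node <- tape_node(tape, y, parents = list(x))
  node$backward <- function(grad, node) list(grad * node$value * (1 - node$value))
  node
}

op_add <- function(tape, a, b) {
  node <- tape_node(tape, a$value + b$value, parents = list(a, b))
  node$backward <- function(grad, node) list(grad, grad)
  node
}

# channel concatenation
op_concat <- function(tape, a, b) {
  da <- dim(a$value); db_ <- dim(b$value)
  y <- array(c(a$value, b$value), dim = c(da[1], da[2], da[3] + db_[3]))
  node <- tape_node(tape, y, parents = list(a, b))
  node$backward <- function(grad, node) {
    list(array(grad[, , seq_len(da[3]), drop = FALSE], dim = da),
         array(grad[, , da[3] + seq_len(db_[3]), drop = FALSE], dim = db_))
  }
  node
}

# multiply every channel of x by a single-channel gate psi (H, W, 1)
op_gate <- function(tape, x, psi) {
  dm <- dim(x$value)
  p <- psi$value[, , 1L]
  y <- x$value * as.vector(p)
  node <- tape_node(tape, y, parents = list(x, psi))
  node$backward <- function(grad, node) {
    dx <- grad * as.vector(p)
    dpsi <- array(rowSums(matrix(grad * x$value, dm[1] * dm[2], dm[3])),
                  dim = c(dm[1], dm[2], 1L))
    list(dx, dpsi)
  }
  node
}
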