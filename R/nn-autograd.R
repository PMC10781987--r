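## Minimal reverse-mode automatic differentiation over dense arrays.
##
## Feature maps are 4-D arrays dim c(H, W, C, N) (N = batch); compiled
## im2col/col2im kernels (src/ops.cpp) do the convolution heavy lifting and
## the tape is a DAG of environments.  Inference can run without taping via
## agNoGrad().

.agState <- new.env(parent = emptyenv())
.agState$id <- 0L
.agState$nograd <- FALSE

#' Run an expression without recording the autodiff tape
#'
#' Disables gradient taping (and the activation caching that supports it)
#' while `expr` is evaluated, which keeps memory flat during inference over
#' large rasters.
#'
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
agNoGrad <- function(expr) {
  old <- .agState$nograd
  .agState$nograd <- TRUE
  on.exit(.agState$nograd <- old)
  expr
}

#' Create an autodiff tensor
#'
#' @param v numeric array/matrix/vector holding the value.
#' @param req logical; does this leaf require a gradient (i.e. is it a
#'   trainable parameter)?
#' @return An object of class `agTensor`.
#' @export
agTensor <- function(v, req = FALSE) {
  e <- new.env(parent = emptyenv())
  .agState$id <- .agState$id + 1L
  e$id <- .agState$id
  e$v <- v
  e$grad <- NULL
  e$parents <- list()
  e$bw <- NULL
  e$req <- req
  e$needs <- req
  class(e) <- "agTensor"
  e
}

agNode <- function(v, parents, bw) {
  if (.agState$nograd) return(agTensor(v))
  t <- agTensor(v)
  needs <- FALSE
  for (p in parents) if (p$needs) { needs <- TRUE; break }
  if (needs) {
    t$parents <- parents
    t$bw <- bw
    t$needs <- TRUE
  }
  t
}

#' @export
print.agTensor <- function(x, ...) {
  cat("<agTensor", paste(dim(x$v) %||% length(x$v), collapse = "x"),
      if (x$req) "(param)" else "", ">\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- elementwise ----------------------------------------------------------

agAdd <- function(a, b) agNode(a$v + b$v, list(a, b),
                               function(g) list(g, g))

agSub <- function(a, b) agNode(a$v - b$v, list(a, b),
                               function(g) list(g, -g))

agMul <- function(a, b) agNode(a$v * b$v, list(a, b), local({
  av <- a$v; bv <- b$v
  function(g) list(g * bv, g * av)
}))

## multiply by a plain numeric array/scalar (no gradient for it)
agMulC <- function(a, m) agNode(a$v * m, list(a), function(g) list(g * m))

agAddC <- function(a, m) agNode(a$v + m, list(a), function(g) list(g))

## c - x for numeric constant c
agRsubC <- function(cst, a) agNode(cst - a$v, list(a), function(g) list(-g))

## scale by a 1-element tensor (learned scalar, e.g. attention gain)
agScaleT <- function(a, s) agNode(a$v * as.numeric(s$v), list(a, s), local({
  av <- a$v; sv <- as.numeric(s$v)
  function(g) list(g * sv, sum(g * av))
}))

agSqr <- function(a) agNode(a$v^2, list(a), local({
  av <- a$v
  function(g) list(2 * g * av)
}))

agAbs <- function(a) agNode(abs(a$v), list(a), local({
  sg <- sign(a$v)
  function(g) list(g * sg)
}))

agSigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$v))
  agNode(s, list(a), function(g) list(g * s * (1 - s)))
}

agTanh <- function(a) {
  t <- tanh(a$v)
  agNode(t, list(a), function(g) list(g * (1 - t^2)))
}

agLeakyReLU <- function(a, slope = 0.2) {
  m <- slope + (1 - slope) * (a$v > 0)
  agNode(a$v * m, list(a), function(g) list(g * m))
}

agSoftplus <- function(a) {
  v <- pmax(a$v, 0) + log1p(exp(-abs(a$v)))
  s <- 1 / (1 + exp(-a$v))
  agNode(v, list(a), function(g) list(g * s))
}

agClamp <- function(a, lo, hi) {
  m <- (a$v >= lo) & (a$v <= hi)
  agNode(pmin(pmax(a$v, lo), hi), list(a), function(g) list(g * m))
}

## ---- reductions -----------------------------------------------------------

agMeanAll <- function(a) {
  n <- length(a$v)
  agNode(mean(a$v), list(a), function(g) {
    gv <- as.numeric(g)
    list(array(gv / n, dim = dim(a$v) %||% n))
  })
}

agSumAll <- function(a) {
  agNode(sum(a$v), list(a), function(g) {
    gv <- as.numeric(g)
    list(array(gv, dim = dim(a$v) %||% length(a$v)))
  })
}

## ---- shape ----------------------------------------------------------------

agConcatC <- function(a, b) {
  da <- dim(a$v); db <- dim(b$v)
  stopifnot(length(da) == 4, all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  v <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  v[, , seq_len(da[3]), ] <- a$v
  v[, , da[3] + seq_len(db[3]), ] <- b$v
  agNode(v, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

agSliceC <- function(a, from, to) {
  d <- dim(a$v)
  v <- a$v[, , from:to, , drop = FALSE]
  agNode(v, list(a), function(g) {
    full <- array(0, dim = d)
    full[, , from:to, ] <- g
    list(full)
  })
}

## (H,W,C,1) -> (H*W) x C matrix, column-major over the map
agToMat <- function(a) {
  d <- dim(a$v)
  stopifnot(d[4] == 1)
  v <- matrix(a$v, nrow = d[1] * d[2], ncol = d[3])
  agNode(v, list(a), function(g) list(array(g, dim = d)))
}

agFromMat <- function(a, H, W, C) {
  v <- array(a$v, dim = c(H, W, C, 1))
  agNode(v, list(a), function(g) list(matrix(g, nrow = H * W, ncol = C)))
}

agSelectSample <- function(a, n) {
  d <- dim(a$v)
  v <- a$v[, , , n, drop = FALSE]
  agNode(v, list(a), function(g) {
    full <- array(0, dim = d)
    full[, , , n] <- g
    list(full)
  })
}

agStackSamples <- function(lst) {
  d <- dim(lst[[1]]$v)
  N <- length(lst)
  v <- array(0, dim = c(d[1], d[2], d[3], N))
  for (i in seq_len(N)) v[, , , i] <- lst[[i]]$v
  agNode(v, lst, function(g) {
    lapply(seq_len(N), function(i) g[, , , i, drop = FALSE])
  })
}

## ---- linear algebra -------------------------------------------------------

agMatmul <- function(a, b) agNode(a$v %*% b$v, list(a, b), local({
  av <- a$v; bv <- b$v
  function(g) list(g %*% t(bv), t(av) %*% g)
}))

agMatmulTB <- function(a, b) agNode(a$v %*% t(b$v), list(a, b), local({
  av <- a$v; bv <- b$v
  function(g) list(g %*% bv, t(g) %*% av)
}))

agMatmulTA <- function(a, b) agNode(t(a$v) %*% b$v, list(a, b), local({
  av <- a$v; bv <- b$v
  function(g) list(bv %*% t(g), av %*% g)
}))

## scalar / scalar division
agDivSc <- function(a, b) agNode(as.numeric(a$v) / as.numeric(b$v),
                                 list(a, b), local({
  av <- as.numeric(a$v); bv <- as.numeric(b$v)
  function(g) list(g / bv, -g * av / bv^2)
}))

agSoftmaxRows <- function(a) {
  m <- a$v - apply(a$v, 1, max)
  e <- exp(m)
  s <- e / rowSums(e)
  agNode(s, list(a), function(g) {
    dot <- rowSums(g * s)
    list((g - dot) * s)
  })
}

## ---- convolution ----------------------------------------------------------

## x: (H,W,C,N); w: (Cout x k*k*Cin) matrix with attr "k"; b: length Cout
agConv <- function(x, w, b, stride = 1L, pad = 0L, dil = 1L) {
  k <- attr(w$v, "k")
  out <- cpp_conv_fwd(x$v, w$v, b$v, k, stride, pad, dil)
  agNode(out, list(x, w, b), local({
    xv <- x$v; wv <- w$v
    function(g) {
      r <- cpp_conv_bwd(xv, wv, g, k, stride, pad, dil)
      attr(r$dw, "k") <- k
      list(r$dx, r$dw, as.numeric(r$db))
    }
  }))
}

## transposed convolution: x (H,W,Cin,N) -> ((H-1)s + k - 2p, ., Cout, N)
## w: (Cin x k*k*Cout) matrix with attr "k" and attr "cout"
agConvT <- function(x, w, b, stride = 2L, pad = 1L) {
  k <- attr(w$v, "k")
  Cout <- attr(w$v, "cout")
  out <- cpp_convt_fwd(x$v, w$v, b$v, k, stride, pad, Cout)
  agNode(out, list(x, w, b), local({
    xv <- x$v; wv <- w$v
    function(g) {
      r <- cpp_convt_bwd(xv, wv, g, k, stride, pad, Cout)
      attr(r$dw, "k") <- k
      attr(r$dw, "cout") <- Cout
      list(r$dx, r$dw, as.numeric(r$db))
    }
  }))
}

## batch normalization over (H,W,N) per channel; stats env carries running
## moments for inference mode
agBatchNorm <- function(x, gamma, beta, stats, training = TRUE,
                        momentum = 0.1, eps = 1e-5) {
  d <- dim(x$v)
  C <- d[3]
  m <- d[1] * d[2] * d[4]
  perm <- aperm(x$v, c(1, 2, 4, 3))
  xm <- matrix(perm, nrow = m, ncol = C)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2, mu)^2)
    stats$mean <- (1 - momentum) * stats$mean + momentum * mu
    stats$var <- (1 - momentum) * stats$var + momentum * va
  } else {
    mu <- stats$mean
    va <- stats$var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, "*")
  y <- sweep(sweep(xhat, 2, gamma$v, "*"), 2, beta$v, "+")
  out <- aperm(array(y, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  agNode(out, list(x, gamma, beta), function(g) {
    gperm <- aperm(g, c(1, 2, 4, 3))
    gm <- matrix(gperm, nrow = m, ncol = C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    if (training) {
      gx <- sweep(gm, 2, gamma$v, "*")
      t1 <- gx
      t2 <- matrix(colMeans(gx), nrow = m, ncol = C, byrow = TRUE)
      t3 <- xhat * matrix(colMeans(gx * xhat), nrow = m, ncol = C, byrow = TRUE)
      dxm <- sweep(t1 - t2 - t3, 2, istd, "*")
    } else {
      dxm <- sweep(sweep(gm, 2, gamma$v, "*"), 2, istd, "*")
    }
    dx <- aperm(array(dxm, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
    list(dx, dgamma, dbeta)
  })
}

## ---- backward pass --------------------------------------------------------

#' Backpropagate from a scalar loss tensor
#'
#' Accumulates gradients into every parameter leaf (created with
#' `agTensor(v, req = TRUE)`) reachable from `loss`.
#'
#' @param loss an `agTensor` holding a scalar.
#' @export
agBackward <- function(loss) {
  stopifnot(length(loss$v) == 1)
  ## iterative topological sort
  topo <- vector("list", 256)
  ntopo <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, i = 0L))
  while (length(stack) > 0) {
    fr <- stack[[length(stack)]]
    node <- fr$node
    key <- as.character(node$id)
    if (fr$i == 0L && !is.null(seen[[key]])) {
      stack[[length(stack)]] <- NULL
      next
    }
    kids <- node$parents
    if (fr$i < length(kids)) {
      stack[[length(stack)]]$i <- fr$i + 1L
      child <- kids[[fr$i + 1L]]
      if (child$needs && is.null(seen[[as.character(child$id)]]))
        stack[[length(stack) + 1L]] <- list(node = child, i = 0L)
    } else {
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        ntopo <- ntopo + 1L
        if (ntopo > length(topo)) topo <- c(topo, vector("list", length(topo)))
        topo[[ntopo]] <- node
      }
      stack[[length(stack)]] <- NULL
    }
  }
  loss$grad <- 1
  for (i in seq(ntopo, 1L)) {
    node <- topo[[i]]
    if (is.null(node$bw) || is.null(node$grad)) next
    gs <- node$bw(node$grad)
    ps <- node$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!p$needs) next
      g <- gs[[j]]
      if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
    }
    node$grad <- NULL # release
  }
  invisible(loss)
}

#' Zero the gradients of a parameter list
#' @param params named list of `agTensor` parameters.
#' @export
agZeroGrad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}
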