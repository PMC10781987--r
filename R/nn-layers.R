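## Network building blocks and optimization on top of the autodiff engine.

## Evaluate expr under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

## ---- module container -----------------------------------------------------

mkModule <- function(config = list()) {
  m <- new.env(parent = emptyenv())
  m$params <- list()
  m$stats <- list()
  m$config <- config
  class(m) <- "glomModule"
  m
}

regParam <- function(m, name, v) {
  p <- agTensor(v, req = TRUE)
  m$params[[name]] <- p
  p
}

## DCGAN-style initialization: conv weights N(0, 0.02), biases 0.
mkConvW <- function(cout, cin, k) {
  w <- matrix(stats::rnorm(cout * k * k * cin, 0, 0.02), nrow = cout)
  attr(w, "k") <- as.integer(k)
  w
}

mkConvTW <- function(cin, cout, k) {
  w <- matrix(stats::rnorm(cin * k * k * cout, 0, 0.02), nrow = cin)
  attr(w, "k") <- as.integer(k)
  attr(w, "cout") <- as.integer(cout)
  w
}

addConv <- function(m, name, cin, cout, k, stride = 1L, pad = 0L, dil = 1L,
                    zero_init = FALSE) {
  force(stride); force(pad); force(dil); force(k)
  w0 <- mkConvW(cout, cin, k)
  if (zero_init) w0[] <- 0
  w <- regParam(m, paste0(name, ".w"), w0)
  b <- regParam(m, paste0(name, ".b"), numeric(cout))
  function(x) agConv(x, w, b, stride = as.integer(stride),
                     pad = as.integer(pad), dil = as.integer(dil))
}

addConvT <- function(m, name, cin, cout, k = 4L, stride = 2L, pad = 1L) {
  force(stride); force(pad); force(k)
  w <- regParam(m, paste0(name, ".w"), mkConvTW(cin, cout, k))
  b <- regParam(m, paste0(name, ".b"), numeric(cout))
  function(x) agConvT(x, w, b, stride = as.integer(stride),
                      pad = as.integer(pad))
}

addBN <- function(m, name, C) {
  gamma <- regParam(m, paste0(name, ".gamma"), rep(1, C))
  beta <- regParam(m, paste0(name, ".beta"), numeric(C))
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(C)
  st$var <- rep(1, C)
  m$stats[[name]] <- st
  function(x, training = TRUE) agBatchNorm(x, gamma, beta, st, training)
}

## self-attention over an (H,W,C,N) map (SAGAN-style): per spatial position
## queries/keys of width max(1, C %/% 8), values of width C, learned scalar
## gain initialized to 0 so the block starts as the identity.
addSelfAttention <- function(m, name, C) {
  d <- max(1L, C %/% 8L)
  wq <- regParam(m, paste0(name, ".wq"), matrix(stats::rnorm(C * d, 0, 0.02), C, d))
  wk <- regParam(m, paste0(name, ".wk"), matrix(stats::rnorm(C * d, 0, 0.02), C, d))
  wv <- regParam(m, paste0(name, ".wv"), matrix(stats::rnorm(C * C, 0, 0.02), C, C))
  gam <- regParam(m, paste0(name, ".gamma"), 0)
  function(x) {
    dms <- dim(x$v)
    H <- dms[1]; W <- dms[2]; N <- dms[4]
    outs <- vector("list", N)
    for (n in seq_len(N)) {
      xm <- agToMat(agSelectSample(x, n))          # (HW) x C
      q <- agMatmul(xm, wq)
      k <- agMatmul(xm, wk)
      a <- agSoftmaxRows(agMatmulTB(q, k))          # rows sum to 1
      o <- agMatmul(a, agMatmul(xm, wv))
      outs[[n]] <- agFromMat(o, H, W, C)
    }
    agAdd(x, agScaleT(agStackSamples(outs), gam))
  }
}

## ---- parameter IO ---------------------------------------------------------

moduleValues <- function(m) {
  list(params = lapply(m$params, function(p) p$v),
       stats = lapply(m$stats, function(s) list(mean = s$mean, var = s$var)))
}

moduleLoadValues <- function(m, vals) {
  for (nm in names(vals$params)) {
    if (is.null(m$params[[nm]])) stop("unknown parameter: ", nm)
    m$params[[nm]]$v <- vals$params[[nm]]
  }
  for (nm in names(vals$stats)) {
    m$stats[[nm]]$mean <- vals$stats[[nm]]$mean
    m$stats[[nm]]$var <- vals$stats[[nm]]$var
  }
  invisible(m)
}

#' Save a model checkpoint
#'
#' Single-file checkpoint holding a format version tag, the model
#' configuration and all parameter/normalization values.
#'
#' @param model a model object built by [buildGenerator()],
#'   [buildDiscriminator()], [buildSegModel()] or [buildMaskGenerator()].
#' @param path file path to write.
#' @export
writeCheckpoint <- function(model, path) {
  saveRDS(list(format = "glomopaint-ckpt", version = 1L,
               config = model$config, values = moduleValues(model)),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilds the model from the configuration stored in the checkpoint and
#' restores its weights.
#'
#' @param path checkpoint file written by [writeCheckpoint()].
#' @return The restored model.
#' @export
readCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "glomopaint-ckpt"))
    stop("not a glomopaint checkpoint: ", path)
  builder <- switch(ck$config$type,
    generator = buildGenerator,
    discriminator = buildDiscriminator,
    segmenter = buildSegModel,
    mask_generator = buildMaskGenerator,
    mask_discriminator = buildMaskDiscriminator,
    stop("unknown model type in checkpoint: ", ck$config$type))
  model <- do.call(builder, ck$config$args)
  moduleLoadValues(model, ck$values)
  model
}

## ---- Adam -----------------------------------------------------------------

adamInit <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p$v * 0)
  st$v <- lapply(params, function(p) p$v * 0)
  st$t <- 0L
  st
}

adamStep <- function(params, st, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mhat <- st$m[[nm]] / bc1
    vhat <- st$v[[nm]] / bc2
    p$v <- p$v - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(st)
}

## cosine-annealed learning rate over `total` steps
cosineLR <- function(step, total, lr0, lr_min) {
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * min(step, total) / total))
}
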