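## Pixel-level evaluation: confusion-count metrics (precision, recall, F1,
## Dice) and image-quality metrics (MAE, PSNR, SSIM).

safeDiv <- function(num, den) if (den == 0) 0 else num / den

#' Confusion-count segmentation metrics for one class
#'
#' Pixelwise TP/FP/FN/TN and the derived precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, `F1 = 2PR/(P+R)` and `Dice = 2TP/(FP+2TP+FN)`. All 0/0
#' cases resolve to 0, except the doubly-empty case (no predicted and no
#' true foreground) where every metric is 1 (trivial perfect agreement,
#' reported via a message).
#'
#' @param pred,true binary rasters of identical shape.
#' @return list with counts and metrics.
#' @export
confusionMetrics <- function(pred, true) {
  if (!all(dim(pred) == dim(true))) stop("pred/true shape mismatch")
  p <- pred > 0.5; t <- true > 0.5
  TP <- sum(p & t); FP <- sum(p & !t); FN <- sum(!p & t); TN <- sum(!p & !t)
  if (TP + FP + FN == 0) {
    message("no foreground in prediction or truth; metrics set to 1")
    return(list(TP = TP, FP = FP, FN = FN, TN = TN,
                precision = 1, recall = 1, f1 = 1, dice = 1))
  }
  precision <- safeDiv(TP, TP + FP)
  recall <- safeDiv(TP, TP + FN)
  f1 <- safeDiv(2 * precision * recall, precision + recall)
  dice <- safeDiv(2 * TP, FP + 2 * TP + FN)
  list(TP = TP, FP = FP, FN = FN, TN = TN, precision = precision,
       recall = recall, f1 = f1, dice = dice)
}

#' Pool confusion metrics across rasters
#'
#' `micro` pools pixel counts before computing metrics (the convention for
#' single-value-per-test-set reporting); `macro` averages per-raster
#' metrics.
#'
#' @param reports list of [confusionMetrics()] results.
#' @param mode `"micro"` or `"macro"`.
#' @return list of pooled metrics.
#' @export
aggregateConfusion <- function(reports, mode = c("micro", "macro")) {
  mode <- match.arg(mode)
  if (mode == "micro") {
    TP <- sum(vapply(reports, `[[`, numeric(1), "TP"))
    FP <- sum(vapply(reports, `[[`, numeric(1), "FP"))
    FN <- sum(vapply(reports, `[[`, numeric(1), "FN"))
    precision <- safeDiv(TP, TP + FP)
    recall <- safeDiv(TP, TP + FN)
    list(precision = precision, recall = recall,
         f1 = safeDiv(2 * precision * recall, precision + recall),
         dice = safeDiv(2 * TP, FP + 2 * TP + FN))
  } else {
    avg <- function(f) mean(vapply(reports, `[[`, numeric(1), f))
    list(precision = avg("precision"), recall = avg("recall"),
         f1 = avg("f1"), dice = avg("dice"))
  }
}

gaussianKernel <- function(win = 11L, sigma = 1.5) {
  r <- (win - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g <- g / sum(g)
  outer(g, g)
}

ssimChannel <- function(a, b, win = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                        L = 1) {
  win <- min(win, nrow(a), ncol(a))
  if (win %% 2 == 0) win <- win - 1L
  if (win < 1) stop("image too small for SSIM")
  k <- gaussianKernel(win, sigma)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mu1 <- cpp_conv2_valid(a, k)
  mu2 <- cpp_conv2_valid(b, k)
  s1 <- cpp_conv2_valid(a * a, k) - mu1^2
  s2 <- cpp_conv2_valid(b * b, k) - mu2^2
  s12 <- cpp_conv2_valid(a * b, k) - mu1 * mu2
  mean(((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
         ((mu1^2 + mu2^2 + C1) * (s1 + s2 + C2)))
}

#' Image-quality metrics between an original and a reconstruction
#'
#' MAE is the mean absolute difference, PSNR is `10*log10(1/MSE)` dB (peak
#' 1.0; `Inf` for identical inputs), and SSIM is the standard 11x11
#' Gaussian-windowed (sigma 1.5, K1 = 0.01, K2 = 0.03) structural similarity
#' averaged over windows (and channels for RGB). With `mask`, MAE/PSNR are
#' restricted to masked pixels and SSIM is computed on the mask's bounding
#' box.
#'
#' @param Xori,Xrec rasters in `[0, 1]`, same shape (`H x W` or `H x W x 3`).
#' @param mask optional binary `H x W` matrix.
#' @return `list(mae, psnr, ssim)`.
#' @export
imageQuality <- function(Xori, Xrec, mask = NULL) {
  if (!all((dim(Xori) %||% length(Xori)) == (dim(Xrec) %||% length(Xrec))))
    stop("shape mismatch")
  a <- Xori; b <- Xrec
  if (!is.null(mask)) {
    sel <- mask > 0.5
    if (!any(sel)) stop("empty mask")
    if (length(dim(a)) == 3) {
      av <- apply(a, 3, function(ch) ch[sel])
      bv <- apply(b, 3, function(ch) ch[sel])
    } else {
      av <- a[sel]; bv <- b[sel]
    }
    mae <- mean(abs(av - bv))
    mse <- mean((av - bv)^2)
    rows <- range(which(rowSums(sel) > 0))
    cols <- range(which(colSums(sel) > 0))
    a <- if (length(dim(a)) == 3) a[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
         else a[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    b <- if (length(dim(b)) == 3) b[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
         else b[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  } else {
    mae <- mean(abs(a - b))
    mse <- mean((a - b)^2)
  }
  psnr <- if (mse == 0) Inf else 10 * log10(1 / mse)
  ssim <- if (length(dim(a)) == 3)
    mean(vapply(1:3, function(c) ssimChannel(a[, , c], b[, , c]), numeric(1)))
  else ssimChannel(a, b)
  list(mae = mae, psnr = psnr, ssim = ssim)
}
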