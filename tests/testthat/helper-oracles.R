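# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own compiled kernels.

# point-in-polygon (even-odd) plus on-boundary test at one pixel centre
oraclePointInPoly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      if (px < xint) inside <- !inside
    }
    # boundary: distance from point to segment
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx^2 + dy^2
    t <- if (len2 > 0) max(0, min(1, ((px - xi) * dx + (py - yi) * dy) / len2)) else 0
    if (sqrt((px - (xi + t * dx))^2 + (py - (yi + t * dy))^2) < 1e-9)
      return(TRUE)
    j <- i
  }
  inside
}

oracleFillPolygon <- function(H, W, poly) {
  m <- matrix(0, H, W)
  for (y in 0:(H - 1)) for (x in 0:(W - 1))
    if (oraclePointInPoly(x, y, poly)) m[y + 1, x + 1] <- 1
  m
}

# sliding-window SSIM with an 11x11 Gaussian (sigma 1.5), valid windows only
oracleSSIM <- function(a, b, win = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  r <- (win - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2)); g <- g / sum(g)
  k <- outer(g, g)
  C1 <- K1^2; C2 <- K2^2
  H <- nrow(a); W <- ncol(a)
  vals <- c()
  for (i in 1:(H - win + 1)) for (j in 1:(W - win + 1)) {
    wa <- a[i:(i + win - 1), j:(j + win - 1)]
    wb <- b[i:(i + win - 1), j:(j + win - 1)]
    mu1 <- sum(k * wa); mu2 <- sum(k * wb)
    s1 <- sum(k * wa^2) - mu1^2
    s2 <- sum(k * wb^2) - mu2^2
    s12 <- sum(k * wa * wb) - mu1 * mu2
    vals <- c(vals, ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
                ((mu1^2 + mu2^2 + C1) * (s1 + s2 + C2)))
  }
  mean(vals)
}

# 8-connected component areas by flood fill
oracleComponentAreas <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  areas <- c()
  for (y in seq_len(H)) for (x in seq_len(W)) {
    if (mask[y, x] == 0 || seen[y, x]) next
    stack <- list(c(y, x)); seen[y, x] <- TRUE; area <- 0L
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      area <- area + 1L
      for (dy in -1:1) for (dx in -1:1) {
        ny <- p[1] + dy; nx <- p[2] + dx
        if (ny >= 1 && ny <= H && nx >= 1 && nx <= W &&
            mask[ny, nx] > 0 && !seen[ny, nx]) {
          seen[ny, nx] <- TRUE
          stack[[length(stack) + 1L]] <- c(ny, nx)
        }
      }
    }
    areas <- c(areas, area)
  }
  areas
}

# numeric gradient of scalar-valued f at x
oracleNumGrad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# small helper: fixture crops shared across training tests
smokeCrops <- function(n = 8, size = 64, seed = 11) {
  makeFixtureCrops(n, size = size, seed = seed)
}

# centred disc mask used by several suites
blobMask <- function(H = 64, W = 64, cx = 32, cy = 32, r = 12) {
  m <- matrix(0, H, W)
  for (y in seq_len(H)) for (x in seq_len(W))
    if ((x - cx)^2 + (y - cy)^2 <= r^2) m[y, x] <- 1
  m
}

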