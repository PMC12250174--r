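# Independent naive-loop reference for the dense polynomial-expansion
# optical flow: per-pixel weighted least squares for the expansion and
# literal update/averaging loops for the displacement (single pyramid
# level). Used to validate the compiled implementation.

# per-pixel quadratic fit f ~ r1 + r2*i + r3*j + r4*i^2 + r5*j^2 + r6*i*j
# (i = column offset, j = row offset), Gaussian applicability, replicate
# border
oraclePolyExpand <- function(img, polyN, sigma) {
  n <- polyN %/% 2
  H <- nrow(img); W <- ncol(img)
  off <- -n:n
  g <- exp(-off^2 / (2 * sigma^2)); g <- g / sum(g)
  grid <- expand.grid(j = off, i = off)
  w <- g[grid$i + n + 1] * g[grid$j + n + 1]
  B <- cbind(1, grid$i, grid$j, grid$i^2, grid$j^2, grid$i * grid$j)
  G <- t(B) %*% (w * B)
  a11 <- a12 <- a22 <- bx <- by <- matrix(0, H, W)
  clampIdx <- function(v, hi) pmin(pmax(v, 1), hi)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      vals <- img[cbind(clampIdx(r + grid$j, H), clampIdx(c + grid$i, W))]
      rhs <- t(B) %*% (w * vals)
      coef <- solve(G, rhs)
      bx[r, c] <- coef[2]; by[r, c] <- coef[3]
      a11[r, c] <- coef[4]; a22[r, c] <- coef[5]
      a12[r, c] <- coef[6] / 2
    }
  }
  list(a11 = a11, a12 = a12, a22 = a22, bx = bx, by = by)
}

oracleBoxBlur <- function(m, winsize) {
  n <- winsize %/% 2
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  # separable means with replicated border
  tmp <- matrix(0, H, W)
  for (c in seq_len(W)) {
    for (r in seq_len(H)) {
      rr <- pmin(pmax((r - n):(r + n), 1), H)
      tmp[r, c] <- mean(m[rr, c])
    }
  }
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      cc <- pmin(pmax((c - n):(c + n), 1), W)
      out[r, c] <- mean(tmp[r, cc])
    }
  }
  out
}

# literal single-level displacement estimation
oracleFlow <- function(im1, im2, winsize, iterations, polyN, sigma) {
  p1 <- oraclePolyExpand(im1, polyN, sigma)
  p2 <- oraclePolyExpand(im2, polyN, sigma)
  H <- nrow(im1); W <- ncol(im1)
  u <- matrix(0, H, W); v <- matrix(0, H, W)
  for (it in seq_len(iterations)) {
    G11 <- G12 <- G22 <- h1 <- h2 <- matrix(0, H, W)
    for (r in seq_len(H)) {
      for (c in seq_len(W)) {
        du <- round(u[r, c]); dv <- round(v[r, c])
        c2 <- min(max(c + du, 1), W); r2 <- min(max(r + dv, 1), H)
        a11 <- 0.5 * (p1$a11[r, c] + p2$a11[r2, c2])
        a12 <- 0.5 * (p1$a12[r, c] + p2$a12[r2, c2])
        a22 <- 0.5 * (p1$a22[r, c] + p2$a22[r2, c2])
        dbx <- -0.5 * (p2$bx[r2, c2] - p1$bx[r, c]) + a11 * du + a12 * dv
        dby <- -0.5 * (p2$by[r2, c2] - p1$by[r, c]) + a12 * du + a22 * dv
        G11[r, c] <- a11^2 + a12^2
        G12[r, c] <- a12 * (a11 + a22)
        G22[r, c] <- a12^2 + a22^2
        h1[r, c] <- a11 * dbx + a12 * dby
        h2[r, c] <- a12 * dbx + a22 * dby
      }
    }
    G11 <- oracleBoxBlur(G11, winsize); G12 <- oracleBoxBlur(G12, winsize)
    G22 <- oracleBoxBlur(G22, winsize)
    h1 <- oracleBoxBlur(h1, winsize); h2 <- oracleBoxBlur(h2, winsize)
    det <- G11 * G22 - G12^2
    ok <- abs(det) > 1e-12
    u <- ifelse(ok, (G22 * h1 - G12 * h2) / det, 0)
    v <- ifelse(ok, (G11 * h2 - G12 * h1) / det, 0)
  }
  list(u = u, v = v)
}

# independent circle rasterizer
oracleRender <- function(px, py, width, height, radius, intensity) {
  img <- matrix(0, height, width)
  for (k in seq_along(px)) {
    cc <- round(px[k] * (width - 1)); cr <- round(py[k] * (height - 1))
    for (r in seq_len(height)) {
      for (c in seq_len(width)) {
        if ((r - 1 - cr)^2 + (c - 1 - cc)^2 <= radius^2)
          img[r, c] <- intensity
      }
    }
  }
  img
}
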