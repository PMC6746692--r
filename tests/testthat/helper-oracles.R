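# Independent brute-force oracles used to validate the package's numerical
# routines. Deliberately naive implementations: exhaustive scans, dense
# linear algebra, O(V^2) Dijkstra.

# even-odd ray-casting point-in-polygon (boundary points count as inside,
# via a small tolerance on the edge distance)
oracle_point_in_polygon <- function(py, px, vy, vx, tol = 1e-9) {
  n <- length(vy)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    # on-edge check
    ex <- vx[j] - vx[i]; ey <- vy[j] - vy[i]
    len2 <- ex^2 + ey^2
    if (len2 > 0) {
      t <- ((px - vx[i]) * ex + (py - vy[i]) * ey) / len2
      if (t >= 0 && t <= 1) {
        dx <- px - (vx[i] + t * ex); dy <- py - (vy[i] + t * ey)
        if (dx^2 + dy^2 < tol) return(TRUE)
      }
    }
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_polygon_mask <- function(markers, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(shape[1]))
    for (j in seq_len(shape[2]))
      m[i, j] <- oracle_point_in_polygon(i, j, markers[, 1], markers[, 2])
  m
}

# Dijkstra on the 8-connected pixel graph; edge weight between neighbours p,q
# is euclidean_step * (cost[p] + cost[q]) / 2. O(V^2), fine for <= 32 x 32.
oracle_dijkstra <- function(cost, src_mask) {
  nr <- nrow(cost); nc <- ncol(cost); n <- nr * nc
  d <- rep(Inf, n)
  d[which(src_mask)] <- 0
  done <- rep(FALSE, n)
  steps <- expand.grid(dr = -1:1, dc = -1:1)
  steps <- steps[!(steps$dr == 0 & steps$dc == 0), ]
  for (k in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, d))
    if (!is.finite(d[u])) break
    done[u] <- TRUE
    ui <- (u - 1) %% nr + 1; uj <- (u - 1) %/% nr + 1
    for (s in seq_len(nrow(steps))) {
      vi <- ui + steps$dr[s]; vj <- uj + steps$dc[s]
      if (vi < 1 || vi > nr || vj < 1 || vj > nc) next
      v <- (vj - 1) * nr + vi
      w <- sqrt(steps$dr[s]^2 + steps$dc[s]^2) * (cost[ui, uj] + cost[vi, vj]) / 2
      if (d[u] + w < d[v]) d[v] <- d[u] + w
    }
  }
  matrix(d, nr, nc)
}

# exact euclidean distance transform by exhaustive min over source pixels
oracle_edt <- function(src_mask) {
  src <- which(src_mask, arr.ind = TRUE)
  nr <- nrow(src_mask); nc <- ncol(src_mask)
  d <- matrix(Inf, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc))
      d[i, j] <- sqrt(min((src[, 1] - i)^2 + (src[, 2] - j)^2))
  d
}

# exhaustive 3-class Otsu: minimises total intra-class variance directly on
# the binned sample
oracle_otsu3 <- function(v, n_bins) {
  bin <- pmin(floor(v * n_bins) + 1L, n_bins)
  centres <- (seq_len(n_bins) - 0.5) / n_bins
  x <- centres[bin]
  best <- Inf; best_t <- NULL
  for (t1 in 1:(n_bins - 2)) {
    for (t2 in (t1 + 1):(n_bins - 1)) {
      cl <- findInterval(bin - 0.5, c(t1, t2)) # 0,1,2
      ok <- TRUE; ss <- 0
      for (g in 0:2) {
        xs <- x[cl == g]
        if (!length(xs)) { ok <- FALSE; break }
        ss <- ss + sum((xs - mean(xs))^2)
      }
      if (ok && ss < best - 1e-12) { best <- ss; best_t <- c(t1, t2) }
    }
  }
  best_t / n_bins
}

# one modified AOS step by dense linear algebra, built independently from
# the update formulas (per-column / per-row dense tridiagonal systems)
oracle_aos_step <- function(u, g, f0, btilde, tau, alpha, eps1) {
  nr <- nrow(u); nc <- ncol(u)
  grad1 <- function(m) { # along rows
    out <- m * 0
    if (nr >= 3) out[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
    out[1, ] <- m[2, ] - m[1, ]; out[nr, ] <- m[nr, ] - m[nr - 1, ]
    out
  }
  grad2 <- function(m) { # along cols
    out <- m * 0
    if (nc >= 3) out[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
    out[, 1] <- m[, 2] - m[, 1]; out[, nc] <- m[, nc] - m[, nc - 1]
    out
  }
  G <- g / sqrt(grad1(u)^2 + grad2(u)^2 + eps1^2)
  den <- 1 + tau * alpha * btilde
  ut <- u - tau * f0 / den
  solve_dir <- function(Gv, utv, denv) {
    n <- length(Gv)
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      Gm <- if (i > 1) (Gv[i] + Gv[i - 1]) / 2 else 0
      Gp <- if (i < n) (Gv[i] + Gv[i + 1]) / 2 else 0
      if (i > 1) A[i, i - 1] <- Gm
      if (i < n) A[i, i + 1] <- Gp
      A[i, i] <- -(Gm + Gp)
    }
    M <- diag(n) - 2 * tau * diag(1 / denv) %*% A
    solve(M, utv)
  }
  x1 <- u * 0; x2 <- u * 0
  for (j in seq_len(nc)) x1[, j] <- solve_dir(G[, j], ut[, j], den[, j])
  for (i in seq_len(nr)) x2[i, ] <- solve_dir(G[i, ], ut[i, ], den[i, ])
  (x1 + x2) / 2
}

# direct (non-separable) 2-D convolution with replicate padding
oracle_conv2 <- function(x, k1) {
  r <- (length(k1) - 1) %/% 2
  nr <- nrow(x); nc <- ncol(x)
  K <- outer(k1, k1)
  out <- x * 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (a in -r:r) for (b in -r:r) {
        ii <- min(max(i + a, 1), nr); jj <- min(max(j + b, 1), nc)
        acc <- acc + K[a + r + 1, b + r + 1] * x[ii, jj]
      }
      out[i, j] <- acc
    }
  }
  out
}

# small deterministic test image: two constant blocks plus a gradient strip
toy_image <- function(nr = 12, nc = 12) {
  z <- matrix(0.2, nr, nc)
  z[3:6, 3:6] <- 0.8
  z[, nc] <- seq(0, 1, length.out = nr)
  z
}

# binary 4-neighbour dilation, used for the distance-dominance check
dilate_mask <- function(mask, times = 1) {
  for (t in seq_len(times)) {
    nr <- nrow(mask); nc <- ncol(mask)
    out <- mask
    out[-1, ] <- out[-1, ] | mask[-nr, ]
    out[-nr, ] <- out[-nr, ] | mask[-1, ]
    out[, -1] <- out[, -1] | mask[, -nc]
    out[, -nc] <- out[, -nc] | mask[, -1]
    mask <- out
  }
  mask
}
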