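# Independent from-scratch oracles used to cross-check the package's
# statistics and geometry. These deliberately use explicit scalar sums and
# enumeration, not the code paths under test.

oracle_mean <- function(x) sum(x) / length(x)
oracle_var <- function(x) {
  m <- oracle_mean(x)
  sum((x - m)^2) / (length(x) - 1)
}

oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  ma <- oracle_mean(a); mb <- oracle_mean(b)
  va <- oracle_var(a); vb <- oracle_var(b)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

oracle_cohen_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * oracle_var(a) + (nb - 1) * oracle_var(b)) /
               (na + nb - 2))
  (oracle_mean(a) - oracle_mean(b)) / sp
}

# brute-force BH step-up: q_(i) = min_{j >= i} min(1, m * p_(j) / j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in i:m) cand <- min(cand, m * ps[j] / j)
    q[i] <- min(1, cand)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

oracle_pearson <- function(x, y) {
  mx <- oracle_mean(x); my <- oracle_mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# exact hypergeometric upper tail P(X >= x) by combinatorial enumeration
oracle_hyper_tail <- function(x, K, N, n) {
  hi <- min(K, n)
  if (x > hi) return(0)
  i <- max(x, max(0, n - (N - K))):hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# multi-source shortest paths on the grid graph via igraph Dijkstra over an
# explicit edge list (weights: s orthogonal, s*sqrt(2) diagonal)
oracle_grid_distance <- function(mask, sources, s = 10, connectivity = 8) {
  nx <- nrow(mask); ny <- ncol(mask)
  id <- function(ix, iy) ix + (iy - 1L) * nx
  offs <- rbind(c(1, 0, s), c(0, 1, s))
  if (connectivity == 8)
    offs <- rbind(offs, c(1, 1, s * sqrt(2)), c(1, -1, s * sqrt(2)))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    dx <- offs[k, 1]; dy <- offs[k, 2]
    g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
    jx <- g$ix + dx; jy <- g$iy + dy
    ok <- jx >= 1 & jy >= 1 & jx <= nx & jy <= ny
    from <- c(from, id(g$ix[ok], g$iy[ok]))
    to <- c(to, id(jx[ok], jy[ok]))
    w <- c(w, rep(offs[k, 3], sum(ok)))
  }
  g <- igraph::make_graph(rbind(from, to), n = nx * ny, directed = FALSE)
  src <- id(sources$ix, sources$iy)
  dm <- igraph::distances(g, v = src, weights = w)
  matrix(apply(dm, 2, min), nx, ny)
}

# naive O(n^3) centroid-linkage trace: returns successive merge heights
# (Euclidean distance between the merged clusters' centroids)
oracle_upgmc_heights <- function(profiles) {
  clusters <- lapply(seq_len(nrow(profiles)), function(i)
    list(centroid = profiles[i, ], size = 1))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      d <- sqrt(sum((clusters[[i]]$centroid - clusters[[j]]$centroid)^2))
      if (d < best[1]) best <- c(d, i, j)
    }
    i <- best[2]; j <- best[3]
    ni <- clusters[[i]]$size; nj <- clusters[[j]]$size
    merged <- list(centroid = (ni * clusters[[i]]$centroid +
                                 nj * clusters[[j]]$centroid) / (ni + nj),
                   size = ni + nj)
    heights <- c(heights, best[1])
    clusters <- c(clusters[-c(i, j)], list(merged))
  }
  heights
}

# random blob mask: union of filled discs on a small lattice
random_blob_mask <- function(nx, ny, n_blobs = 2) {
  mask <- matrix(FALSE, nx, ny)
  cx <- stats::runif(n_blobs, 2, nx - 1)
  cy <- stats::runif(n_blobs, 2, ny - 1)
  r <- stats::runif(n_blobs, 1.5, max(2, min(nx, ny) / 3))
  for (b in seq_len(n_blobs)) {
    gx <- matrix(seq_len(nx), nx, ny)
    gy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
    mask <- mask | ((gx - cx[b])^2 + (gy - cy[b])^2 <= r[b]^2)
  }
  mask
}
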