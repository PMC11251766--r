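# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / direct formulas, never through the package's
# own computational path.

# exact two-sided signed-rank p by full enumeration of all 2^m sign vectors
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.vector(signs %*% r)
  if (w_obs > m * (m + 1) / 4) {
    p <- 2 * mean(w_all >= w_obs)
  } else {
    p <- 2 * mean(w_all <= w_obs)
  }
  min(1, p)
}

# enclosed volume by an unrelated decomposition: tetrahedra fanned from an
# interior point, determinants computed one by one with base det()
naive_volume <- function(m, tri, interior = colMeans(m)) {
  tot <- 0
  for (t in seq_len(nrow(tri))) {
    a <- m[tri[t, 1], ] - interior
    b <- m[tri[t, 2], ] - interior
    c <- m[tri[t, 3], ] - interior
    tot <- tot + det(rbind(a, b, c)) / 6
  }
  tot
}

# direct-formula centroid size with an explicit per-landmark loop
naive_centroid_size <- function(m) {
  ctr <- c(mean(m[, 1]), mean(m[, 2]), mean(m[, 3]))
  s <- 0
  for (i in seq_len(nrow(m))) s <- s + sum((m[i, ] - ctr)^2)
  sqrt(s)
}

# exhaustive local-extrema + prominence oracle: for every interior sample
# that is a local maximum, walk outwards to the nearest strictly higher
# sample on each side and record the lowest value passed on the way
naive_top_peaks <- function(x, n_peaks, min_sep) {
  cand <- c()
  for (i in 2:(length(x) - 1)) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) cand <- c(cand, i)
  }
  prom <- sapply(cand, function(p) {
    lmin <- x[p]; i <- p - 1
    while (i >= 1 && x[i] <= x[p]) { lmin <- min(lmin, x[i]); i <- i - 1 }
    if (i < 1) lmin <- min(x[seq_len(p)])
    rmin <- x[p]; i <- p + 1
    while (i <= length(x) && x[i] <= x[p]) { rmin <- min(rmin, x[i]); i <- i + 1 }
    if (i > length(x)) rmin <- min(x[p:length(x)])
    x[p] - max(lmin, rmin)
  })
  ord <- cand[order(-prom, cand)]
  sel <- integer(0)
  for (i in ord) {
    if (all(abs(i - sel) >= min_sep)) sel <- c(sel, i)
    if (length(sel) == n_peaks) break
  }
  sort(sel)
}

# dense PCA oracle: svd of the centered data matrix
svd_pca_oracle <- function(flat) {
  mu <- colMeans(flat)
  centered <- sweep(flat, 2, mu)
  s <- svd(centered)
  ev <- s$d^2 / (nrow(flat) - 1)
  scores <- centered %*% s$v
  list(eigenvalues = ev, scores = scores, loadings = s$v)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}
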