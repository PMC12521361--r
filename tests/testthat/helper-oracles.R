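# Independent brute-force oracles, written against the definitions only
# (never calling the implementation paths they check).

# exhaustive Otsu: scan all candidate bin splits for maximal between-class
# variance; ties toward the lower threshold
oracle_otsu <- function(v, nbins = 256L) {
  v <- as.numeric(v)
  mn <- min(v); mx <- max(v)
  edges <- seq(mn, mx, length.out = nbins + 1L)
  bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), nbins)
  centers <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  best_k <- NA_integer_; best_v <- -Inf
  for (k in seq_len(nbins - 1L)) {
    lo <- bin <= k
    if (!any(lo) || all(lo)) next
    w0 <- mean(lo); w1 <- 1 - w0
    m0 <- mean(centers[bin[lo]]); m1 <- mean(centers[bin[!lo]])
    sb <- w0 * w1 * (m0 - m1)^2
    if (sb > best_v + 1e-15) { best_v <- sb; best_k <- k }
  }
  edges[best_k + 1L]
}

# plain BFS flood fill (base R), 26-connectivity
oracle_components <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2) { dim(mask) <- c(d, 1L); d <- dim(mask) }
  lab <- array(0L, d)
  cur <- 0L
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  for (i in which(mask)) {
    if (lab[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      z <- (v - 1) %/% (d[1] * d[2])
      rem <- (v - 1) %% (d[1] * d[2])
      y <- rem %/% d[1]; x <- rem %% d[1]
      for (r in seq_len(nrow(nb))) {
        xx <- x + nb[r, 1]; yy <- y + nb[r, 2]; zz <- z + nb[r, 3]
        if (xx < 0 || yy < 0 || zz < 0 || xx >= d[1] || yy >= d[2] ||
            zz >= d[3]) next
        w <- zz * d[1] * d[2] + yy * d[1] + xx + 1
        if (mask[w] && lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  lab
}

# naive centered rolling median with symmetric edge shrinking
oracle_rolling_median <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    median(x[(i - h):(i + h)])
  }, numeric(1))
}

# exhaustive inscribed-sphere local thickness: per foreground voxel the
# distance to the nearest background voxel centre (capped by the volume
# border) defines a candidate sphere; every voxel strictly inside any sphere
# inherits twice its largest covering radius
oracle_local_thickness <- function(mask) {
  # squared radii are integers; keeping the arithmetic integral avoids
  # spurious boundary hits from re-squaring sqrt() values (a voxel at
  # exactly distance r from a centre lies outside the open sphere)
  d <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  r2 <- numeric(nrow(fg))
  block <- 512L
  for (s in seq(1, nrow(fg), by = block)) {
    rows <- s:min(s + block - 1L, nrow(fg))
    sub <- fg[rows, , drop = FALSE]
    border2 <- pmin(sub[, 1], d[1] - sub[, 1] + 1,
                    sub[, 2], d[2] - sub[, 2] + 1,
                    sub[, 3], d[3] - sub[, 3] + 1)^2
    if (nrow(bg) > 0) {
      dd2 <- outer(sub[, 1], bg[, 1], `-`)^2 +
        outer(sub[, 2], bg[, 2], `-`)^2 +
        outer(sub[, 3], bg[, 3], `-`)^2
      r2[rows] <- pmin(apply(dd2, 1, min), border2)
    } else r2[rows] <- border2
  }
  th <- array(0, d)
  ord <- order(r2, decreasing = TRUE)
  for (i in ord) {
    ri2 <- r2[i]
    ri <- sqrt(ri2)
    p <- fg[i, ]
    near <- abs(fg[, 1] - p[1]) < ri & abs(fg[, 2] - p[2]) < ri &
      abs(fg[, 3] - p[3]) < ri
    cand <- fg[near, , drop = FALSE]
    inside <- (cand[, 1] - p[1])^2 + (cand[, 2] - p[2])^2 +
      (cand[, 3] - p[3])^2 < ri2
    cand <- cand[inside, , drop = FALSE]
    cur <- th[cand]
    upd <- cur < 2 * ri
    if (any(upd)) th[cand[upd, , drop = FALSE]] <- 2 * ri
  }
  th
}

# smoothed random blob mask for thickness tests
random_blob_mask <- function(dim3, seed, sigma = 2, frac = 0.45) {
  set.seed(seed)
  noise <- array(rnorm(prod(dim3)), dim = dim3)
  sm <- tibiamorph:::`.cpp_gaussian_blur`(noise, as.integer(dim3),
                                          rep(sigma, 3))
  sm > quantile(sm, 1 - frac)
}
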