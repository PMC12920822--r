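# Independent brute-force oracles for the texture-matrix builders and
# connected components. Deliberately naive (nested loops / BFS) and kept
# separate from the implementation under test.

# the 13 unique 3D direction offsets at Chebyshev distance 1, in the
# documented package order
oracle_dirs13 <- function() {
  rbind(c(1,0,0), c(0,1,0), c(0,0,1),
        c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1),
        c(1,1,1), c(1,1,-1), c(1,-1,1), c(1,-1,-1))
}

oracle_glcm <- function(levels, mask, ng) {
  d <- dim(levels)
  dirs <- oracle_dirs13()
  out <- array(0, c(ng, ng, 13))
  for (dd in 1:13) {
    for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
      if (!mask[i, j, k]) next
      ii <- i + dirs[dd, 1]; jj <- j + dirs[dd, 2]; kk <- k + dirs[dd, 3]
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3])
        next
      if (!mask[ii, jj, kk]) next
      a <- levels[i, j, k]; b <- levels[ii, jj, kk]
      out[a, b, dd] <- out[a, b, dd] + 1
      out[b, a, dd] <- out[b, a, dd] + 1
    }
  }
  out
}

oracle_glrlm <- function(levels, mask, ng) {
  d <- dim(levels)
  maxlen <- max(d)
  dirs <- oracle_dirs13()
  out <- array(0, c(ng, maxlen, 13))
  inb <- function(p) all(p >= 1) && all(p <= d)
  for (dd in 1:13) {
    v <- dirs[dd, ]
    for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
      p <- c(i, j, k)
      if (inb(p - v)) next   # not a line start
      cur <- -1L; len <- 0L
      while (inb(p)) {
        lev <- if (mask[p[1], p[2], p[3]]) levels[p[1], p[2], p[3]] else -1L
        if (lev == cur && lev > 0) len <- len + 1L
        else {
          if (cur > 0) out[cur, len, dd] <- out[cur, len, dd] + 1
          cur <- lev; len <- 1L
        }
        p <- p + v
      }
      if (cur > 0) out[cur, len, dd] <- out[cur, len, dd] + 1
    }
  }
  out
}

# 26-connected BFS labelling (independent of the C++ implementation)
oracle_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  offsets <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  if (connectivity == 6) offsets <- offsets[rowSums(abs(offsets)) == 1, ]
  for (s in which(mask & lab == 0L)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      i <- (v - 1L) %% d[1] + 1L
      j <- ((v - 1L) %/% d[1]) %% d[2] + 1L
      k <- (v - 1L) %/% (d[1] * d[2]) + 1L
      for (r in seq_len(nrow(offsets))) {
        ii <- i + offsets[r, 1]; jj <- j + offsets[r, 2]; kk <- k + offsets[r, 3]
        if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3])
          next
        w <- ii + (jj - 1L) * d[1] + (kk - 1L) * d[1] * d[2]
        if (mask[w] && lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  lab
}

oracle_glszm <- function(levels, mask) {
  zones <- list()
  for (lev in sort(unique(levels[mask]))) {
    sub <- mask & (levels == lev)
    lab <- oracle_label(sub, 26)
    if (max(lab) > 0)
      for (z in 1:max(lab)) zones[[length(zones) + 1]] <- c(lev, sum(lab == z))
  }
  do.call(rbind, zones)
}

oracle_gldm <- function(levels, mask, ng, alpha = 0) {
  d <- dim(levels)
  out <- matrix(0, ng, 27)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    if (!mask[i, j, k]) next
    dep <- 0L
    for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3])
        next
      if (mask[ii, jj, kk] &&
          abs(levels[ii, jj, kk] - levels[i, j, k]) <= alpha)
        dep <- dep + 1L
    }
    out[levels[i, j, k], dep + 1] <- out[levels[i, j, k], dep + 1] + 1
  }
  out
}

oracle_ngtdm <- function(levels, mask, ng) {
  d <- dim(levels)
  out <- matrix(0, ng, 2)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    if (!mask[i, j, k]) next
    nb <- c()
    for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3])
        next
      if (mask[ii, jj, kk]) nb <- c(nb, levels[ii, jj, kk])
    }
    if (length(nb)) {
      lev <- levels[i, j, k]
      out[lev, 1] <- out[lev, 1] + 1
      out[lev, 2] <- out[lev, 2] + abs(lev - mean(nb))
    }
  }
  out
}

# digitized ball mask helper
ball_mask <- function(n = 27, r = 10) {
  cc <- (n - 1) / 2
  ax <- 0:(n - 1)
  X <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- array(rep(rep(ax, each = n), n), c(n, n, n))
  Z <- array(rep(ax, each = n * n), c(n, n, n))
  (X - cc)^2 + (Y - cc)^2 + (Z - cc)^2 <= r^2
}
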