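# Independent brute-force oracles, deliberately naive (loops over voxels),
# used to validate the vectorized/compiled implementations.

bfTopPoints <- function(arr) {
  d <- dim(arr)
  top <- integer(d[3])
  for (z in seq_len(d[3])) {
    best <- 0L
    for (x in seq_len(d[1])) for (y in seq_len(d[2]))
      if (arr[x, y, z] != 0) best <- max(best, x - 1L)
    top[z] <- best
  }
  top
}

bfRunningMax <- function(top) {
  adj <- integer(length(top))
  prev <- 0L
  for (z in seq_along(top)) {
    adj[z] <- max(top[z], prev)
    prev <- adj[z]
  }
  adj
}

bfCrop <- function(arr, adjusted) {
  d <- dim(arr)
  out <- arr
  zero <- if (is.integer(arr)) 0L else 0
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1]))
    if ((x - 1L) > adjusted[z]) out[x, y, z] <- zero
  out
}

bfDice <- function(a, b) {
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na + nb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (na + nb)
}

bfSurface <- function(m) {
  d <- dim(m)
  w <- which(m != 0, arr.ind = TRUE)
  keep <- logical(nrow(w))
  for (i in seq_len(nrow(w))) {
    p <- w[i, ]
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      q <- p; q[ax] <- q[ax] + s
      if (any(q < 1) || any(q > d) || m[q[1], q[2], q[3]] == 0) {
        keep[i] <- TRUE
      }
    }
  }
  w[keep, , drop = FALSE]
}

bfHd95 <- function(a, b, spacing = c(1, 1, 1), percentile = 0.95) {
  sa <- bfSurface(a); sb <- bfSurface(b)
  pa <- sweep(sa, 2, spacing, "*"); pb <- sweep(sb, 2, spacing, "*")
  dAB <- apply(pa, 1, function(p) min(sqrt(colSums((t(pb) - p)^2))))
  dBA <- apply(pb, 1, function(p) min(sqrt(colSums((t(pa) - p)^2))))
  quantile(c(dAB, dBA), percentile, type = 7, names = FALSE)
}

randomMask <- function(d, p = 0.2) {
  array(as.integer(runif(prod(d)) < p), dim = d)
}

asBinary <- function(arr, spacing = c(1, 1, 1)) {
  new("BinaryMask", data = arr, spacing = spacing)
}
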