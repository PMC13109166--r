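# Independent brute-force oracles. These deliberately re-derive each result
# from first principles (dense loops, flood fill, exhaustive search) and are
# kept free of any package internals beyond the public API under test.

# dense 3D Gaussian convolution with reflect boundary and the same sampled
# kernel truncation as the contract (radius floor(4*sigma + 0.5))
oracle_blur3d <- function(x, sigma) {
  d <- dim(x)
  r <- max(1L, as.integer(floor(4 * sigma + 0.5)))
  k1 <- exp(-0.5 * ((-r):r)^2 / sigma^2)
  k1 <- k1 / sum(k1)
  refl <- function(i, n) {
    i <- i %% (2L * n)
    ifelse(i >= n, 2L * n - 1L - i, i)
  }
  out <- array(0, d)
  for (zi in 0:(d[1] - 1)) for (yi in 0:(d[2] - 1)) for (xi in 0:(d[3] - 1)) {
    acc <- 0
    for (a in (-r):r) for (b in (-r):r) for (cc in (-r):r) {
      acc <- acc + k1[a + r + 1] * k1[b + r + 1] * k1[cc + r + 1] *
        x[refl(zi + a, d[1]) + 1, refl(yi + b, d[2]) + 1,
          refl(xi + cc, d[3]) + 1]
    }
    out[zi + 1, yi + 1, xi + 1] <- acc
  }
  out
}

# flood-fill connected-component labeling (queue based, label ids normalized
# by first-voxel raster order like the implementation contract)
oracle_label3d <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  nn <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  offs <- offs[nn > 0 & nn <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), ]
  labels <- array(0L, d)
  cur <- 0L
  for (x0 in 1:d[3]) for (y0 in 1:d[2]) for (z0 in 1:d[1]) {
    if (!mask[z0, y0, x0] || labels[z0, y0, x0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(z0, y0, x0))
    labels[z0, y0, x0] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (j in seq_len(nrow(offs))) {
        w <- v + c(offs$dz[j], offs$dy[j], offs$dx[j])
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- cur
          queue[[length(queue) + 1]] <- w
        }
      }
    }
  }
  labels
}

# raster-order renumbering so two labelings can be compared as partitions
# (plain array out: implementation attributes like object counts are dropped)
normalize_labels <- function(labels) {
  d <- dim(labels)
  labels <- as.integer(labels)
  seen <- unique(labels[labels > 0])
  remap <- integer(max(labels, 1L) + 1L)
  remap[seen + 1L] <- seq_along(seen)
  out <- labels
  out[labels > 0] <- remap[labels[labels > 0] + 1L]
  array(out, d)
}

# exhaustive Otsu: try all 255 interior edges of a 256-bin histogram
oracle_otsu <- function(x) {
  x <- as.numeric(x)
  rng <- range(x)
  nbins <- 256L
  bin <- pmin(nbins, 1L + as.integer((x - rng[1]) / diff(rng) * nbins))
  edges <- rng[1] + (0:nbins) / nbins * diff(rng)
  mids <- (edges[-1] + edges[-(nbins + 1)]) / 2
  h <- tabulate(bin, nbins)
  best_bcv <- -Inf; best_edge <- NA
  for (t in 1:(nbins - 1)) {
    w0 <- sum(h[1:t]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:t] * mids[1:t]) / w0
    m1 <- sum(h[(t + 1):nbins] * mids[(t + 1):nbins]) / w1
    bcv <- (w0 / sum(h)) * (w1 / sum(h)) * (m0 - m1)^2
    if (bcv > best_bcv + 1e-12) { best_bcv <- bcv; best_edge <- edges[t + 1] }
  }
  best_edge
}

# per-voxel accumulation of object measurements by explicit iteration
oracle_measure <- function(labels, intensity, spacing) {
  d <- dim(labels)
  sp <- as.numeric(spacing)
  ids <- sort(unique(labels[labels > 0]))
  res <- lapply(ids, function(id) {
    sumz <- sumy <- sumx <- dens <- 0; n <- 0L
    for (xi in 1:d[3]) for (yi in 1:d[2]) for (zi in 1:d[1]) {
      if (labels[zi, yi, xi] != id) next
      n <- n + 1L
      sumz <- sumz + (zi - 1); sumy <- sumy + (yi - 1); sumx <- sumx + (xi - 1)
      dens <- dens + intensity[zi, yi, xi]
    }
    data.frame(object_id = id, cz_vox = sumz / n, cy_vox = sumy / n,
               cx_vox = sumx / n, voxel_count = n,
               volume_um3 = n * prod(sp), integrated_density = dens)
  })
  do.call(rbind, res)
}
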