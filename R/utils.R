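# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so that library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic fan-out of one global seed into per-stage / per-replicate
# seeds, kept inside 32-bit integer range.
splitSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647L) + 1L
}

# 1D convolution of a 3D array along its first axis with replicate padding.
convolveAxis1 <- function(a, kernel) {
  d <- dim(a)
  r <- (length(kernel) - 1L) %/% 2L
  m <- matrix(a, d[1], d[2] * d[3])
  padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                  m[rep(d[1], r), , drop = FALSE])
  out <- stats::filter(padded, kernel, method = "convolution", sides = 2)
  array(out[(r + 1L):(r + d[1]), ], d)
}

# Separable Gaussian smoothing; sigma is per-axis, in voxel units.
gaussianSmooth <- function(a, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    a <- if (ax == 1L) convolveAxis1(a, k)
         else aperm(convolveAxis1(aperm(a, switch(ax, NULL, c(2, 1, 3),
                                                  c(3, 1, 2))), k),
                    switch(ax, NULL, c(2, 1, 3), c(2, 3, 1)))
  }
  a
}

# Shift a 3D array by one voxel along an axis with edge replication.
shiftArray <- function(a, ax, by) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[ax]) + by, 1L), d[ax])
  switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# Chebyshev (box) dilation of a logical mask by radius r voxels.
boxDilate <- function(mask, r) {
  out <- mask
  for (ax in 1:3) {
    acc <- out
    for (s in seq_len(r)) {
      acc <- acc | shiftArray(out, ax, s) | shiftArray(out, ax, -s)
    }
    out <- acc
  }
  out
}

# 26-connected component labelling of a set of voxels given by linear
# indices into a grid of dimension `dm`. Returns 1-based component ids in
# input order.
labelComponents26 <- function(lin, dm) {
  n <- length(lin)
  if (n == 0L) return(integer(0))
  lookup <- integer(prod(dm))
  lookup[lin] <- seq_len(n)
  coords <- arrayInd(lin, dm)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  comp <- integer(n)
  current <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    current <- current + 1L
    frontier <- i
    comp[i] <- current
    while (length(frontier) > 0L) {
      fc <- coords[frontier, , drop = FALSE]
      nb <- fc[rep(seq_len(nrow(fc)), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), nrow(fc)), , drop = FALSE]
      ok <- nb[, 1] >= 1L & nb[, 1] <= dm[1] &
            nb[, 2] >= 1L & nb[, 2] <= dm[2] &
            nb[, 3] >= 1L & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]
      nlin <- nb[, 1] + dm[1] * (nb[, 2] - 1L) + dm[1] * dm[2] * (nb[, 3] - 1L)
      hit <- lookup[nlin]
      hit <- unique(hit[hit > 0L])
      hit <- hit[comp[hit] == 0L]
      comp[hit] <- current
      frontier <- hit
    }
  }
  comp
}
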