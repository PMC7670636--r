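#' 3D patch classifier architecture
#'
#' Architecture of the false-positive refinement network: four 3x3x3
#' convolutions ("same" padding) with channels 8, 16, 32, 32, ReLU after
#' each, 2x2x2 max-pooling after each pair of convolutions (24 -> 12 -> 6),
#' one fully connected layer of 128 nodes, and a 3-way softmax output
#' trained with cross-entropy. Class codes: 1 dPVS, 2 ventricle-adjacent
#' false positive, 3 subarachnoid false positive.
#'
#' @param input_side patch edge length in voxels.
#' @param channels convolution channels, in order.
#' @param fc_nodes fully connected layer width.
#' @param n_classes number of output classes.
#' @return a `NetworkSpec` list; the forward shape trace
#'   (24 -> 12 -> 6, flattened 6^3 x 32 = 6912) must be consistent.
#' @export
networkSpec <- function(input_side = 24L, channels = c(8L, 16L, 32L, 32L),
                        fc_nodes = 128L, n_classes = 3L) {
  stopifnot(input_side %% 4L == 0L, length(channels) == 4L)
  structure(list(input_side = as.integer(input_side),
                 channels = as.integer(channels),
                 fc_nodes = as.integer(fc_nodes),
                 n_classes = as.integer(n_classes), kernel = 3L),
            class = "NetworkSpec")
}

# im2col index matrix for a 3x3x3 neighbourhood on a side^3 grid with
# "same" zero padding: entry [i, j] is the source linear index feeding
# output voxel i through kernel offset j, or n+1 for out-of-grid (a
# sentinel slot holding 0).
im2colIndex <- function(side) {
  n <- side^3
  coords <- arrayInd(seq_len(n), rep(side, 3))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  idx <- matrix(n + 1L, n, 27L)
  for (j in 1:27) {
    nb <- sweep(coords, 2, offs[j, ], `+`)
    ok <- nb[, 1] >= 1L & nb[, 1] <= side & nb[, 2] >= 1L & nb[, 2] <= side &
      nb[, 3] >= 1L & nb[, 3] <= side
    lin <- nb[, 1] + side * (nb[, 2] - 1L) + side^2 * (nb[, 3] - 1L)
    idx[ok, j] <- lin[ok]
  }
  idx
}

# 2x2x2 max-pool grouping: row i lists the 8 source voxels of pooled voxel i.
poolIndex <- function(side) {
  out <- side %/% 2L
  coords <- arrayInd(seq_len(out^3), rep(out, 3))
  offs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  idx <- matrix(0L, out^3, 8L)
  for (j in 1:8) {
    src <- sweep((coords - 1L) * 2L, 2, offs[j, ], `+`) + 1L
    idx[, j] <- src[, 1] + side * (src[, 2] - 1L) + side^2 * (src[, 3] - 1L)
  }
  idx
}

# Convolution as shift-and-add: for each of the 27 kernel offsets,
# gather the shifted input rows and accumulate a (Cin x Cout) matrix
# product. Avoids materializing the n x 27*Cin im2col buffer, which for
# 24^3 patches costs hundreds of MB per mini-batch. Weight rows are
# ordered offset-within-channel: row (c-1)*27 + j.
convForward <- function(x, W, b, idx) {
  n <- nrow(x)
  cin <- ncol(x)
  csel <- (seq_len(cin) - 1L) * 27L
  xe <- rbind(x, 0)
  z <- matrix(b, n, length(b), byrow = TRUE)
  for (j in 1:27)
    z <- z + xe[idx[, j], , drop = FALSE] %*% W[j + csel, , drop = FALSE]
  z
}

# Gradients of the shift-and-add convolution. dz: n x Cout. Returns dW,
# db and dx. Each offset maps outputs to distinct inputs, so per-offset
# scatter assignment is safe.
convGrad <- function(x, W, dz, idx, need_dx = TRUE) {
  n <- nrow(x)
  cin <- ncol(x)
  csel <- (seq_len(cin) - 1L) * 27L
  xe <- rbind(x, 0)
  dW <- matrix(0, nrow(W), ncol(W))
  dx <- if (need_dx) matrix(0, n, cin)
  for (j in 1:27) {
    src <- idx[, j]
    dW[j + csel, ] <- crossprod(xe[src, , drop = FALSE], dz)
    if (need_dx) {
      ok <- src <= n
      dx[src[ok], ] <- dx[src[ok], , drop = FALSE] +
        dz[ok, , drop = FALSE] %*% t(W[j + csel, , drop = FALSE])
    }
  }
  list(W = dW, b = colSums(dz), dx = dx)
}

#' Initialize network weights
#'
#' He-style Gaussian initialization, seeded for reproducibility.
#'
#' @param spec a [networkSpec()].
#' @param seed integer seed.
#' @return a model list with `spec`, weight matrices, and cached index
#'   tables for the two spatial resolutions.
#' @export
initNetwork <- function(spec = networkSpec(), seed = 1L) {
  withSeed(seed, {
    ch <- c(1L, spec$channels)
    convs <- lapply(1:4, function(l) {
      fanin <- 27L * ch[l]
      list(W = matrix(stats::rnorm(fanin * ch[l + 1L], 0,
                                   sqrt(2 / fanin)), fanin, ch[l + 1L]),
           b = numeric(ch[l + 1L]))
    })
    s6 <- spec$input_side %/% 4L
    nflat <- s6^3 * spec$channels[4]
    fc <- list(W = matrix(stats::rnorm(nflat * spec$fc_nodes, 0,
                                       sqrt(2 / nflat)), nflat,
                          spec$fc_nodes),
               b = numeric(spec$fc_nodes))
    out <- list(W = matrix(stats::rnorm(spec$fc_nodes * spec$n_classes, 0,
                                        sqrt(2 / spec$fc_nodes)),
                           spec$fc_nodes, spec$n_classes),
                b = numeric(spec$n_classes))
    idx <- list(full = im2colIndex(spec$input_side),
                half = im2colIndex(spec$input_side %/% 2L),
                pool_full = poolIndex(spec$input_side),
                pool_half = poolIndex(spec$input_side %/% 2L))
    structure(list(spec = spec, convs = convs, fc = fc, out = out,
                   idx = idx), class = "PatchClassifier")
  })
}

# Stack per-sample index tables for a mini-batch of B samples: sample b's
# voxels occupy rows (b-1)*n + 1..n; the out-of-grid sentinel becomes
# B*n + 1.
stackIdx <- function(idx, n, B) {
  out <- matrix(0L, n * B, ncol(idx))
  oob <- idx > n
  for (b in seq_len(B)) {
    blk <- idx + (b - 1L) * n
    blk[oob] <- n * B + 1L
    out[((b - 1L) * n + 1L):(b * n), ] <- blk
  }
  out
}

stackPool <- function(pidx, n_in, B) {
  n_out <- nrow(pidx)
  out <- matrix(0L, n_out * B, ncol(pidx))
  for (b in seq_len(B))
    out[((b - 1L) * n_out + 1L):(b * n_out), ] <- pidx + (b - 1L) * n_in
  out
}

# Batched index tables, cached on the model by batch size.
batchTables <- function(model, B) {
  key <- as.character(B)
  if (!is.null(model$bt[[key]])) return(model$bt[[key]])
  sp <- model$spec
  nF <- sp$input_side^3
  nH <- (sp$input_side %/% 2L)^3
  list(idxF = stackIdx(model$idx$full, nF, B),
       idxH = stackIdx(model$idx$half, nH, B),
       poolF = stackPool(model$idx$pool_full, nF, B),
       poolH = stackPool(model$idx$pool_half, nH, B))
}

# Forward pass for a mini-batch: X is a (side^3 x B) matrix. Returns a
# (B x n_classes) logit matrix and, if keep = TRUE, backprop intermediates.
forwardBatch <- function(model, X, bt, keep = FALSE) {
  sp <- model$spec
  B <- ncol(X)
  n6 <- (sp$input_side %/% 4L)^3
  x <- matrix(as.vector(X), ncol = 1L)

  convRelu <- function(x, layer, idx) {
    z <- convForward(x, model$convs[[layer]]$W, model$convs[[layer]]$b, idx)
    list(a = pmax(z, 0), zpos = if (keep) z > 0, input = if (keep) x)
  }
  maxPool <- function(a, pidx) {
    pooled <- matrix(-Inf, nrow(pidx), ncol(a))
    arg <- matrix(1L, nrow(pidx), ncol(a))
    for (j in 1:8) {
      v <- a[pidx[, j], , drop = FALSE]
      upd <- v > pooled
      arg[upd] <- j
      pooled[upd] <- v[upd]
    }
    list(p = pooled, arg = arg)
  }

  c1 <- convRelu(x, 1L, bt$idxF)
  c2 <- convRelu(c1$a, 2L, bt$idxF)
  p1 <- maxPool(c2$a, bt$poolF)
  c3 <- convRelu(p1$p, 3L, bt$idxH)
  c4 <- convRelu(c3$a, 4L, bt$idxH)
  p2 <- maxPool(c4$a, bt$poolH)
  # rows of p2$p are (sample-block, voxel) x channel; flatten per sample
  arr <- array(p2$p, c(n6, B, sp$channels[4]))
  flat <- matrix(aperm(arr, c(1, 3, 2)), n6 * sp$channels[4], B)
  hz <- sweep(crossprod(flat, model$fc$W), 2, model$fc$b, `+`)  # B x 128
  ha <- pmax(hz, 0)
  logits <- sweep(ha %*% model$out$W, 2, model$out$b, `+`)      # B x 3
  cache <- if (keep) list(c1 = c1, c2 = c2, p1 = p1, c3 = c3, c4 = c4,
                          p2 = p2, flat = flat, hz = hz, ha = ha, B = B)
  list(logits = logits, cache = cache)
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Backward pass for a mini-batch; gradients are summed over samples.
backwardBatch <- function(model, cache, dlogits, bt) {
  sp <- model$spec
  B <- cache$B
  n6 <- (sp$input_side %/% 4L)^3
  g <- list(convs = vector("list", 4L))

  g$out <- list(W = crossprod(cache$ha, dlogits), b = colSums(dlogits))
  dha <- dlogits %*% t(model$out$W)
  dhz <- dha * (cache$hz > 0)
  g$fc <- list(W = cache$flat %*% dhz, b = colSums(dhz))
  dflat <- model$fc$W %*% t(dhz)                       # 6912 x B
  arr <- array(dflat, c(n6, sp$channels[4], B))
  dp2 <- matrix(aperm(arr, c(1, 3, 2)), n6 * B, sp$channels[4])

  # max-pool routing is injective per offset, so vectorized linear-index
  # scatter assignment is safe
  unpool <- function(dp, arg, pidx, n_in) {
    nc <- ncol(dp)
    da <- numeric(n_in * nc)
    coloff <- (col(arg) - 1L) * n_in
    for (j in 1:8) {
      sel <- arg == j
      if (!any(sel)) next
      lin <- pidx[row(arg)[sel], j] + coloff[sel]
      da[lin] <- da[lin] + dp[sel]
    }
    matrix(da, n_in, nc)
  }
  convBack <- function(dz_in, layer, cobj, idx, need_dx = TRUE) {
    dz <- dz_in * cobj$zpos
    cg <- convGrad(cobj$input, model$convs[[layer]]$W, dz, idx, need_dx)
    g$convs[[layer]] <<- list(W = cg$W, b = cg$b)
    cg$dx
  }

  nH <- nrow(cache$c3$a)
  da4 <- unpool(dp2, cache$p2$arg, bt$poolH, nH)
  da3 <- convBack(da4, 4L, cache$c4, bt$idxH)
  dp1 <- convBack(da3, 3L, cache$c3, bt$idxH)
  nF <- nrow(cache$c1$a)
  da2 <- unpool(dp1, cache$p1$arg, bt$poolF, nF)
  da1 <- convBack(da2, 2L, cache$c2, bt$idxF)
  convBack(da1, 1L, cache$c1, bt$idxF, need_dx = FALSE)
  g
}

#' Extract 24^3 patches around candidate components
#'
#' Cuts one intensity patch per connected component from the normalized
#' image, centred at the component centroid rounded to the nearest voxel;
#' regions outside the grid are zero-filled.
#'
#' @param img a normalized [ImageVolume-class].
#' @param candidates a [CandidateSet-class].
#' @param side patch edge length in voxels.
#' @return a `PatchBatch` list: `patches` (side^3 x N matrix, one column
#'   per component), `component_id`, `centers` (0-based), `side`; `labels`
#'   is NULL until assigned.
#' @export
extractPatches <- function(img, candidates, side = 24L) {
  vals <- imageData(img)
  dm <- dim(vals)
  ncomp <- length(candidates@region)
  patches <- matrix(0, side^3, ncomp)
  centers <- matrix(0L, ncomp, 3)
  half <- side %/% 2L
  for (k in seq_len(ncomp)) {
    cen <- round(colMeans(
      candidates@coords[candidates@component == k, , drop = FALSE]))
    centers[k, ] <- as.integer(cen)
    # patch spans cen-half .. cen+half-1 in 0-based coordinates
    p <- array(0, rep(side, 3))
    src_lo <- pmax(cen - half, 0L) + 1L          # 1-based source
    src_hi <- pmin(cen + half - 1L, dm - 1L) + 1L
    if (all(src_lo <= src_hi)) {
      dst_lo <- src_lo - (cen - half) # 1-based destination
      dst_hi <- dst_lo + (src_hi - src_lo)
      p[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
        vals[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
    }
    patches[, k] <- as.vector(p)
  }
  structure(list(patches = patches, component_id = seq_len(ncomp),
                 centers = centers, side = as.integer(side), labels = NULL),
            class = "PatchBatch")
}

#' Merge patch batches
#'
#' Pools patches (and labels, when all batches carry them) from several
#' images, e.g. to build a training set spanning multiple phantoms.
#'
#' @param batches list of `PatchBatch` objects with equal patch side.
#' @return a combined `PatchBatch`.
#' @export
mergePatchBatches <- function(batches) {
  stopifnot(length(batches) > 0L)
  side <- unique(vapply(batches, `[[`, integer(1), "side"))
  if (length(side) != 1L) stop("patch sides differ between batches")
  labs <- lapply(batches, `[[`, "labels")
  structure(list(patches = do.call(cbind, lapply(batches, `[[`, "patches")),
                 component_id = unlist(lapply(batches, `[[`,
                                              "component_id")),
                 centers = do.call(rbind, lapply(batches, `[[`, "centers")),
                 side = side,
                 labels = if (!any(vapply(labs, is.null, logical(1))))
                   unlist(labs) else NULL),
            class = "PatchBatch")
}

#' Assign training classes to candidate components from phantom truth
#'
#' Components overlapping true dPVS voxels are class 1; components within
#' `margin` voxels (Chebyshev) of a ventricle label are class 2; remaining
#' components (typically abutting the bright subarachnoid shell) are
#' class 3.
#'
#' @param candidates a [CandidateSet-class].
#' @param truth a `PhantomTruth`, or a [LabelVolume-class] using the same
#'   label codes.
#' @param margin dilation radius in voxels for the ventricle-adjacency test.
#' @return integer vector of classes, one per component.
#' @export
makeTrainingLabels <- function(candidates, truth, margin = 2L) {
  lab <- if (is(truth, "LabelVolume")) imageData(truth)
         else imageData(truth$labels)
  dm <- dim(lab)
  dpvs <- lab == 3L
  vent <- boxDilate(lab == 4L, margin)
  ncomp <- length(candidates@region)
  cls <- integer(ncomp)
  lin <- candidates@coords[, 1] + 1L + dm[1] * candidates@coords[, 2] +
    dm[1] * dm[2] * candidates@coords[, 3]
  for (k in seq_len(ncomp)) {
    l <- lin[candidates@component == k]
    cls[k] <- if (any(dpvs[l])) 1L else if (any(vent[l])) 2L else 3L
  }
  cls
}

#' Augment a labelled patch batch
#'
#' Applies, independently per patch: random axis flips, additive Gaussian
#' noise, an additive bias constant and a multiplicative scaling factor.
#' Labels are unchanged. With all amplitudes zero and `flip_prob = 0` the
#' transform is the identity.
#'
#' @param batch a `PatchBatch` with labels.
#' @param seed integer seed.
#' @param flip_prob per-axis flip probability.
#' @param noise_sd additive noise SD.
#' @param bias_range bias drawn uniformly in +/- this value.
#' @param scale_range scale factor drawn uniformly in 1 +/- this value.
#' @return an augmented `PatchBatch`.
#' @export
augmentPatches <- function(batch, seed = 1L, flip_prob = 0.5,
                           noise_sd = 0.05, bias_range = 0.1,
                           scale_range = 0.1) {
  withSeed(seed, {
    side <- batch$side
    n <- ncol(batch$patches)
    out <- batch
    for (i in seq_len(n)) {
      p <- array(batch$patches[, i], rep(side, 3))
      for (ax in 1:3) {
        if (stats::runif(1) < flip_prob) {
          p <- switch(ax, p[side:1, , , drop = FALSE],
                      p[, side:1, , drop = FALSE],
                      p[, , side:1, drop = FALSE])
        }
      }
      sc <- 1 + stats::runif(1, -scale_range, scale_range)
      bs <- stats::runif(1, -bias_range, bias_range)
      p <- p * sc + bs
      if (noise_sd > 0) p <- p + array(stats::rnorm(side^3, 0, noise_sd),
                                       rep(side, 3))
      out$patches[, i] <- as.vector(p)
    }
    out
  })
}

#' Train the patch classifier
#'
#' Stochastic gradient descent with momentum on the cross-entropy loss.
#' Mini-batches draw each class with equal probability regardless of raw
#' class counts, so imbalanced candidate sets do not collapse onto the
#' majority class.
#'
#' @param batch a `PatchBatch` with `labels` set (all three classes must be
#'   present).
#' @param spec a [networkSpec()].
#' @param epochs training epochs (one epoch = one pass-worth of balanced
#'   draws).
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param batch_size mini-batch size.
#' @param seed integer seed.
#' @return a trained `PatchClassifier` with a `loss_history` element.
#' @export
trainClassifier <- function(batch, spec = networkSpec(), epochs = 20L,
                            lr = 0.003, momentum = 0.9, batch_size = 8L,
                            seed = 1L) {
  labels <- batch$labels
  if (is.null(labels)) stop("training requires a labelled batch")
  for (cl in seq_len(spec$n_classes))
    if (!any(labels == cl))
      stop(sprintf("class %d absent from training labels", cl))
  if (batch$side != spec$input_side)
    stop("patch side does not match the network input side")
  model <- initNetwork(spec, seed = seed)
  vel <- rapply(model[c("convs", "fc", "out")],
                function(w) w * 0, how = "replace")
  byclass <- split(seq_along(labels), labels)
  n <- length(labels)
  steps <- max(1L, ceiling(n / batch_size))
  loss_hist <- numeric(epochs)
  bt <- batchTables(model, batch_size)
  withSeed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      eploss <- 0
      for (st in seq_len(steps)) {
        cls_draw <- sample(spec$n_classes, batch_size, replace = TRUE)
        ids <- vapply(cls_draw, function(cl) {
          pool <- byclass[[as.character(cl)]]
          pool[sample.int(length(pool), 1L)]
        }, integer(1))
        fw <- forwardBatch(model, batch$patches[, ids, drop = FALSE], bt,
                           keep = TRUE)
        pr <- softmaxRows(fw$logits)
        picked <- pr[cbind(seq_along(ids), labels[ids])]
        bl <- -sum(log(pmax(picked, 1e-12)))
        dlog <- pr
        dlog[cbind(seq_along(ids), labels[ids])] <-
          dlog[cbind(seq_along(ids), labels[ids])] - 1
        grad <- backwardBatch(model, fw$cache, dlog, bt)
        upd <- function(v, gr) momentum * v - (lr / batch_size) * gr
        for (l in 1:4) {
          vel$convs[[l]]$W <- upd(vel$convs[[l]]$W, grad$convs[[l]]$W)
          vel$convs[[l]]$b <- upd(vel$convs[[l]]$b, grad$convs[[l]]$b)
          model$convs[[l]]$W <- model$convs[[l]]$W + vel$convs[[l]]$W
          model$convs[[l]]$b <- model$convs[[l]]$b + vel$convs[[l]]$b
        }
        vel$fc$W <- upd(vel$fc$W, grad$fc$W)
        vel$fc$b <- upd(vel$fc$b, grad$fc$b)
        model$fc$W <- model$fc$W + vel$fc$W
        model$fc$b <- model$fc$b + vel$fc$b
        vel$out$W <- upd(vel$out$W, grad$out$W)
        vel$out$b <- upd(vel$out$b, grad$out$b)
        model$out$W <- model$out$W + vel$out$W
        model$out$b <- model$out$b + vel$out$b
        eploss <- eploss + bl / batch_size
      }
      loss_hist[ep] <- eploss / steps
    }
  })
  model$loss_history <- loss_hist
  model
}

#' Classify patches
#'
#' @param model a trained `PatchClassifier`.
#' @param batch a `PatchBatch`.
#' @return list with `class` (integer per patch) and `prob` (N x n_classes
#'   softmax matrix, rows summing to 1).
#' @export
predictClasses <- function(model, batch) {
  if (batch$side != model$spec$input_side)
    stop("patch side does not match the network input side")
  n <- ncol(batch$patches)
  prob <- matrix(0, n, model$spec$n_classes)
  chunk <- 8L
  bt <- batchTables(model, chunk)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    ids <- i:j
    X <- batch$patches[, ids, drop = FALSE]
    btu <- if (length(ids) == chunk) bt else batchTables(model, length(ids))
    prob[ids, ] <- softmaxRows(forwardBatch(model, X, btu)$logits)
    i <- j + 1L
  }
  list(class = max.col(prob), prob = prob)
}

#' Refine a candidate set with the trained classifier
#'
#' Keeps components classified as dPVS (class 1) with all their voxels and
#' removes ventricle-adjacent and subarachnoid components entirely. The
#' result is always a subset of the input candidates.
#'
#' @param candidates a [CandidateSet-class].
#' @param model a trained `PatchClassifier`.
#' @param img the normalized [ImageVolume-class] the candidates came from.
#' @return a refined [CandidateSet-class].
#' @export
refineCandidates <- function(candidates, model, img) {
  ncomp <- length(candidates@region)
  if (ncomp == 0L) return(candidates)
  batch <- extractPatches(img, candidates, side = model$spec$input_side)
  pred <- predictClasses(model, batch)
  keep <- which(pred$class == 1L)
  sel <- candidates@component %in% keep
  newcomp <- match(candidates@component[sel], keep)
  new("CandidateSet", coords = candidates@coords[sel, , drop = FALSE],
      component = as.integer(newcomp),
      region = candidates@region[keep],
      dim = candidates@dim, spacing = candidates@spacing)
}

#' Save / load a trained classifier
#'
#' The model file embeds the [networkSpec()] so a loaded model validates
#' patch sizes on use.
#'
#' @param model a `PatchClassifier`.
#' @param path file path.
#' @return `loadClassifier` returns the model.
#' @export
saveClassifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "PatchClassifier")) stop("not a classifier file")
  m
}
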