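#' Vesselness filter parameters
#'
#' Parameters of the multiscale Hessian tubularity (vesselness) measure for
#' bright tubes on a darker background, as used to flag potential dPVS
#' voxels on T2-like images. The plate/blob sensitivity constants default
#' to alpha = beta = 0.5; the structureness constant gamma defaults to half
#' the maximum second-order structure norm over the brain, recomputed per
#' scale (set `gamma` to fix it). Scales default to 0.7--1.4 mm so the
#' filter spans the sub-3 mm dPVS diameter range; responses are combined
#' across scales by per-voxel maximum. The default threshold (0.10) was
#' calibrated on noise-free phantoms with known tube volume so that the
#' extracted candidate volume is approximately unbiased; it is exposed
#' because the appropriate cutoff depends on contrast and noise.
#'
#' @param scales_mm positive Gaussian scales in mm.
#' @param alpha,beta,gamma positive sensitivity constants; `gamma = NULL`
#'   selects the adaptive half-max rule.
#' @param threshold cutoff in (0, 1) applied to the combined vesselness.
#' @return a `VesselnessParams` list.
#' @export
vesselnessParams <- function(scales_mm = c(0.7, 1.05, 1.4), alpha = 0.5,
                             beta = 0.5, gamma = NULL, threshold = 0.10) {
  stopifnot(all(scales_mm > 0), alpha > 0, beta > 0,
            is.null(gamma) || gamma > 0,
            threshold > 0, threshold <= 1)
  structure(list(scales_mm = scales_mm, alpha = alpha, beta = beta,
                 gamma = gamma, threshold = threshold),
            class = "VesselnessParams")
}

#' Normalize image intensity within a brain mask
#'
#' Standardizes intensities to mean 0 and standard deviation 1 over the
#' masked voxels (population convention, divide by n) and zeroes everything
#' outside the mask, so that vesselness and patch intensities are
#' comparable across subjects.
#'
#' @param img an [ImageVolume-class].
#' @param brain_mask a [LabelVolume-class] (mask = labels > 0) or logical
#'   array on the same grid.
#' @return a standardized [ImageVolume-class].
#' @export
normalizeIntensity <- function(img, brain_mask) {
  vals <- imageData(img)
  mask <- if (is(brain_mask, "LabelVolume")) imageData(brain_mask) > 0L
          else brain_mask
  if (!identical(dim(mask), dim(vals)))
    stop("brain mask grid does not match the image grid")
  if (!any(mask)) stop("brain mask is empty")
  v <- vals[mask]
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))
  if (sdv == 0) stop("constant intensity within the brain mask")
  out <- array(0, dim(vals))
  out[mask] <- (v - mu) / sdv
  imageVolume(out, spacingMm(img))
}

# Eigenvalues of a field of symmetric 3x3 matrices, closed-form
# (trigonometric) solve vectorized over voxels. Entries are vectors of
# equal length; returns a list(l1, l2, l3) ordered |l1| <= |l2| <= |l3|.
symEigen3 <- function(a11, a22, a33, a12, a13, a23) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  pe <- ifelse(p > 0, p, 1)
  b11 <- (a11 - q) / pe; b22 <- (a22 - q) / pe; b33 <- (a33 - q) / pe
  b12 <- a12 / pe; b13 <- a13 / pe; b23 <- a23 / pe
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  degen <- p2 <= 0
  if (any(degen)) { e1[degen] <- q[degen]; e2[degen] <- q[degen]
                    e3[degen] <- q[degen] }
  # sort each triple by absolute value (3-element sorting network)
  swp <- function(x, y) {
    s <- abs(x) > abs(y)
    t <- x[s]; x[s] <- y[s]; y[s] <- t
    list(x, y)
  }
  o <- swp(e1, e2); e1 <- o[[1]]; e2 <- o[[2]]
  o <- swp(e2, e3); e2 <- o[[1]]; e3 <- o[[2]]
  o <- swp(e1, e2); e1 <- o[[1]]; e2 <- o[[2]]
  list(l1 = e1, l2 = e2, l3 = e3)
}

#' Hessian eigenvalues of an image at a Gaussian scale
#'
#' Smooths the image with an isotropic (in mm) Gaussian of the given scale,
#' forms the scale-normalized Hessian (second central differences in
#' physical mm units, multiplied by scale^2) and returns the three real
#' eigenvalues at every voxel, ordered |l1| <= |l2| <= |l3|.
#'
#' @param img an [ImageVolume-class].
#' @param scale_mm Gaussian scale in mm; should not be below the voxel
#'   spacing.
#' @return list of three arrays `l1`, `l2`, `l3` on the image grid.
#' @export
hessianEigenvalues <- function(img, scale_mm) {
  vals <- imageData(img)
  h <- spacingMm(img)
  stopifnot(scale_mm > 0)
  sm <- gaussianSmooth(vals, scale_mm / h)
  d1 <- function(ax) (shiftArray(sm, ax, 1L) - shiftArray(sm, ax, -1L)) /
    (2 * h[ax])
  d2 <- function(ax) (shiftArray(sm, ax, 1L) - 2 * sm +
                      shiftArray(sm, ax, -1L)) / h[ax]^2
  dcross <- function(ax1, ax2) {
    g <- d1(ax1)
    (shiftArray(g, ax2, 1L) - shiftArray(g, ax2, -1L)) / (2 * h[ax2])
  }
  s2 <- scale_mm^2
  e <- symEigen3(as.vector(d2(1L)) * s2, as.vector(d2(2L)) * s2,
                 as.vector(d2(3L)) * s2, as.vector(dcross(1L, 2L)) * s2,
                 as.vector(dcross(1L, 3L)) * s2,
                 as.vector(dcross(2L, 3L)) * s2)
  dm <- dim(vals)
  list(l1 = array(e$l1, dm), l2 = array(e$l2, dm), l3 = array(e$l3, dm))
}

#' Vesselness measure from ordered Hessian eigenvalues
#'
#' Single-scale tubularity response for bright tubes: zero wherever
#' l2 > 0 or l3 > 0 (a bright tube has two large negative curvatures), and
#' otherwise
#' \deqn{V = (1 - e^{-R_A^2/2\alpha^2})\; e^{-R_B^2/2\beta^2}\;
#'        (1 - e^{-S^2/2\gamma^2})}
#' with \eqn{R_A = |l2|/|l3|} (plate vs line), \eqn{R_B = |l1|/\sqrt{|l2 l3|}}
#' (blobness) and \eqn{S = \sqrt{l1^2+l2^2+l3^2}} (structure norm).
#' Voxels with l3 = 0 have no structure and return 0.
#'
#' @param eigs list with arrays `l1`, `l2`, `l3` ordered by magnitude.
#' @param alpha,beta,gamma positive constants; if `gamma` is `NULL` it is
#'   set to half the maximum of S over `mask`.
#' @param mask optional logical array restricting the adaptive gamma rule.
#' @return array of vesselness values in \[0, 1\].
#' @export
vesselnessFromEigen <- function(eigs, alpha = 0.5, beta = 0.5,
                                gamma = NULL, mask = NULL) {
  l1 <- eigs$l1; l2 <- eigs$l2; l3 <- eigs$l3
  S <- sqrt(l1^2 + l2^2 + l3^2)
  if (is.null(gamma)) {
    smax <- if (is.null(mask)) max(S) else max(S[mask])
    gamma <- smax / 2
    if (gamma <= 0) gamma <- 1  # flat volume; response is 0 anyway
  }
  al3 <- abs(l3)
  RA <- ifelse(al3 > 0, abs(l2) / al3, 0)
  denom <- sqrt(abs(l2 * l3))
  RB <- ifelse(denom > 0, abs(l1) / denom, 0)
  V <- (1 - exp(-RA^2 / (2 * alpha^2))) * exp(-RB^2 / (2 * beta^2)) *
    (1 - exp(-S^2 / (2 * gamma^2)))
  V[l2 > 0 | l3 > 0 | al3 == 0] <- 0
  V
}

#' Multiscale vesselness field
#'
#' Computes [vesselnessFromEigen()] at each configured scale and combines
#' across scales by per-voxel maximum.
#'
#' @param img a normalized [ImageVolume-class].
#' @param params a [vesselnessParams()] object.
#' @param mask optional logical array for the adaptive gamma rule (defaults
#'   to nonzero voxels of `img`).
#' @return array of vesselness values in \[0, 1\] on the image grid.
#' @export
vesselnessFilter <- function(img, params = vesselnessParams(), mask = NULL) {
  if (is.null(mask)) mask <- imageData(img) != 0
  out <- NULL
  for (s in params$scales_mm) {
    eigs <- hessianEigenvalues(img, s)
    V <- vesselnessFromEigen(eigs, params$alpha, params$beta, params$gamma,
                             mask)
    out <- if (is.null(out)) V else pmax(out, V)
  }
  out
}

#' Extract candidate dPVS voxels by thresholding vesselness
#'
#' Thresholds the vesselness field, restricts to the union of the WM and
#' BG masks, groups surviving voxels into 26-connected components and tags
#' each component with the region holding the majority of its voxels (ties
#' toward WM).
#'
#' @param vess vesselness array.
#' @param wm_mask,bg_mask logical arrays (or [LabelVolume-class]s with
#'   positive labels) on the same grid; must be disjoint.
#' @param params a [vesselnessParams()] (supplies the threshold).
#' @return a [CandidateSet-class].
#' @export
extractCandidates <- function(vess, wm_mask, bg_mask,
                              params = vesselnessParams()) {
  toMask <- function(m) if (is(m, "LabelVolume")) imageData(m) > 0L else m
  wm <- toMask(wm_mask); bg <- toMask(bg_mask)
  spacing <- if (is(wm_mask, "LabelVolume")) spacingMm(wm_mask)
             else rep(1, 3)
  if (!identical(dim(wm), dim(vess)) || !identical(dim(bg), dim(vess)))
    stop("mask grid does not match the vesselness grid")
  if (any(wm & bg)) stop("WM and BG masks must be disjoint")
  dm <- dim(vess)
  lin <- which(vess > params$threshold & (wm | bg))
  comp <- labelComponents26(lin, dm)
  ncomp <- if (length(comp)) max(comp) else 0L
  region <- character(ncomp)
  if (ncomp > 0L) {
    in_wm <- wm[lin]
    for (k in seq_len(ncomp)) {
      w <- sum(in_wm[comp == k])
      b <- sum(comp == k) - w
      region[k] <- if (w >= b) "WM" else "BG"
    }
  }
  coords <- if (length(lin)) arrayInd(lin, dm) - 1L
            else matrix(integer(0), 0, 3)
  new("CandidateSet", coords = coords, component = as.integer(comp),
      region = region, dim = as.integer(dm), spacing = as.numeric(spacing))
}

#' Run the full stage-1 dPVS segmentation on a phantom or image
#'
#' Convenience wrapper: normalize intensity over the brain mask, compute
#' the multiscale vesselness field, and extract candidates within the WM
#' and BG masks.
#'
#' @param img an [ImageVolume-class].
#' @param wm_mask,bg_mask,brain_mask logical arrays on the image grid.
#' @param params a [vesselnessParams()].
#' @param spacing voxel spacing to record in the candidate set (defaults to
#'   the image spacing).
#' @return list with `candidates` ([CandidateSet-class]), `vesselness`
#'   array, and `normalized` image.
#' @export
segmentPVS <- function(img, wm_mask, bg_mask, brain_mask,
                       params = vesselnessParams(), spacing = NULL) {
  norm <- normalizeIntensity(img, brain_mask)
  vess <- vesselnessFilter(norm, params, mask = brain_mask)
  cand <- extractCandidates(vess, wm_mask, bg_mask, params)
  cand@spacing <- if (is.null(spacing)) spacingMm(img) else spacing
  list(candidates = cand, vesselness = vess, normalized = norm)
}

#' Component summary table for a candidate set
#'
#' @param candidates a [CandidateSet-class].
#' @return data.frame with component id, region, voxel count and centroid
#'   (0-based voxel coordinates).
#' @export
componentTable <- function(candidates) {
  ncomp <- length(candidates@region)
  if (ncomp == 0L)
    return(data.frame(component_id = integer(0), region = character(0),
                      n_voxels = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), centroid_z = numeric(0)))
  out <- data.frame(component_id = seq_len(ncomp),
                    region = candidates@region,
                    n_voxels = as.integer(tabulate(candidates@component,
                                                   ncomp)))
  cen <- t(vapply(seq_len(ncomp), function(k)
    colMeans(candidates@coords[candidates@component == k, , drop = FALSE]),
    numeric(3)))
  out$centroid_x <- cen[, 1]; out$centroid_y <- cen[, 2]
  out$centroid_z <- cen[, 3]
  out
}

#' Binary mask array from a candidate set
#'
#' @param candidates a [CandidateSet-class].
#' @return logical array of the originating grid dimension.
#' @export
candidateMask <- function(candidates) {
  m <- array(FALSE, candidates@dim)
  if (nrow(candidates@coords) > 0L) {
    lin <- candidates@coords[, 1] + 1L +
      candidates@dim[1] * candidates@coords[, 2] +
      candidates@dim[1] * candidates@dim[2] * candidates@coords[, 3]
    m[lin] <- TRUE
  }
  m
}
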