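#' Specification of a synthetic dPVS phantom
#'
#' Defines the geometry, intensity and noise model of a schematic 3D
#' T2-like phantom: a spherical "brain" with a white-matter (WM) interior,
#' two basal-ganglia (BG) blobs, bright ventricles adjacent to the BG, a
#' bright subarachnoid shell at the brain surface, and bright capsule-shaped
#' tubes standing in for dilated perivascular spaces. Tube radii are
#' constrained so that diameters stay below 3 mm, matching the radiological
#' definition of a dPVS.
#'
#' @param grid_shape integer(3) voxels per axis.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param n_tubes_wm,n_tubes_bg number of tubes per region.
#' @param n_confounders_vent,n_confounders_shell number of tubular CSF
#'   confounders attached to the ventricle boundary and to the brain
#'   surface (emulating choroid-fissure-like channels and sulcal CSF, the
#'   structures the patch classifier must reject).
#' @param tube_radius_range_mm min/max tube radius (diameter kept < 3 mm).
#' @param tube_length_range_mm min/max tube length in mm.
#' @param intensity_tissue,intensity_csf,intensity_background intensity
#'   levels for parenchyma, CSF-like structures (tubes, ventricles, shell)
#'   and outside-brain background.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param bias_field_amplitude amplitude of the smooth multiplicative bias.
#' @param seed integer seed; phantoms are bit-reproducible given the seed.
#' @return a `PhantomSpec` list.
#' @export
phantomSpec <- function(grid_shape = c(96L, 96L, 96L), voxel_size_mm = 0.7,
                        n_tubes_wm = 6L, n_tubes_bg = 3L,
                        n_confounders_vent = 2L, n_confounders_shell = 3L,
                        tube_radius_range_mm = c(0.35, 1.4),
                        tube_length_range_mm = c(3, 10),
                        intensity_tissue = 1.0, intensity_csf = 2.0,
                        intensity_background = 0.0,
                        noise_sd = 0.05, bias_field_amplitude = 0.1,
                        seed = 1L) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  grid_shape <- as.integer(grid_shape)
  stopifnot(all(grid_shape > 0L), voxel_size_mm > 0,
            length(tube_radius_range_mm) == 2L,
            tube_radius_range_mm[1] > 0,
            diff(tube_radius_range_mm) >= 0)
  if (2 * tube_radius_range_mm[2] >= 3)
    stop("tube diameters must stay below 3 mm (dPVS definition)")
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 n_tubes_wm = as.integer(n_tubes_wm),
                 n_tubes_bg = as.integer(n_tubes_bg),
                 n_confounders_vent = as.integer(n_confounders_vent),
                 n_confounders_shell = as.integer(n_confounders_shell),
                 tube_radius_range_mm = tube_radius_range_mm,
                 tube_length_range_mm = tube_length_range_mm,
                 intensity_tissue = intensity_tissue,
                 intensity_csf = intensity_csf,
                 intensity_background = intensity_background,
                 noise_sd = noise_sd,
                 bias_field_amplitude = bias_field_amplitude,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

# Voxel-centre coordinates (mm) along each axis.
axisCoords <- function(n, h) (seq_len(n) - 0.5) * h

# Logical mask of an axis-aligned ellipsoid, centre and semi-axes in mm.
ellipsoidMask <- function(dm, h, centre, semi) {
  x <- axisCoords(dm[1], h); y <- axisCoords(dm[2], h); z <- axisCoords(dm[3], h)
  dx2 <- ((x - centre[1]) / semi[1])^2
  dy2 <- ((y - centre[2]) / semi[2])^2
  dz2 <- ((z - centre[3]) / semi[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# Capsule rasterization (segment p0-p1 with radius r, mm), restricted to a
# bounding box. Returns the linear indices of voxels whose centre lies
# inside the capsule (the ground-truth voxels) plus a partial-volume
# coverage weight in [0, 1] for every voxel within half a voxel of the
# surface, emulating the partial-volume averaging of sub-voxel tubes at
# MRI resolution.
capsuleVoxels <- function(dm, h, p0, p1, r) {
  margin <- r + h
  lo <- pmax(1L, floor((pmin(p0, p1) - margin) / h))
  hi <- pmin(dm, ceiling((pmax(p0, p1) + margin) / h + 1))
  empty <- list(inside = integer(0), pv_lin = integer(0), pv_w = numeric(0))
  if (any(lo > hi)) return(empty)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  g <- expand.grid(x = (ix - 0.5) * h, y = (iy - 0.5) * h, z = (iz - 0.5) * h)
  d <- p1 - p0
  len2 <- sum(d^2)
  px <- g$x - p0[1]; py <- g$y - p0[2]; pz <- g$z - p0[3]
  t <- if (len2 > 0) pmin(pmax((px * d[1] + py * d[2] + pz * d[3]) / len2, 0), 1)
       else 0
  dist <- sqrt((px - t * d[1])^2 + (py - t * d[2])^2 + (pz - t * d[3])^2)
  w <- pmin(pmax((r - dist) / h + 0.5, 0), 1)
  keep <- w > 0
  if (!any(keep)) return(empty)
  gi <- expand.grid(i = ix, j = iy, k = iz)
  lin <- gi$i + dm[1] * (gi$j - 1L) + dm[1] * dm[2] * (gi$k - 1L)
  list(inside = lin[dist <= r], pv_lin = lin[keep], pv_w = w[keep])
}

# Smooth multiplicative bias field: low-frequency cosine modulation with a
# random phase, 1 +/- amplitude.
biasField <- function(dm, amplitude) {
  if (amplitude <= 0) return(array(1, dm))
  ph <- stats::runif(3, 0, 2 * pi)
  fx <- cos(2 * pi * (seq_len(dm[1]) - 1) / dm[1] + ph[1])
  fy <- cos(2 * pi * (seq_len(dm[2]) - 1) / dm[2] + ph[2])
  fz <- cos(2 * pi * (seq_len(dm[3]) - 1) / dm[3] + ph[3])
  f <- (outer(outer(fx, fy, `+`), fz, `+`)) / 3
  1 + amplitude * array(f, dm)
}

#' Generate a synthetic dPVS phantom with ground truth
#'
#' Renders the schematic anatomy described in [phantomSpec()] and returns
#' the noisy image together with its noise-free version and a ground-truth
#' label volume (codes: 0 background, 1 WM, 2 BG, 3 dPVS, 4 ventricle,
#' 5 subarachnoid shell). Tubes are rendered as capsules (cylinder with
#' hemispherical caps) entirely inside their host region; placement retries
#' a bounded number of times and fails loudly if a region cannot host a
#' tube. The true dPVS volume per region is the voxel count times the voxel
#' volume.
#'
#' @param spec a `PhantomSpec`.
#' @return a `PhantomTruth` list with elements `image` (observed
#'   [ImageVolume-class]), `clean` (noise- and bias-free ImageVolume),
#'   `labels` ([LabelVolume-class]), `dpvs_region` (factor per dPVS voxel,
#'   aligned with `dpvs_lin` linear indices), `true_dpvs_volume_mm3`
#'   (named numeric, WM and BG), and `spec`.
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  withSeed(spec$seed, {
    dm <- spec$grid_shape
    h <- spec$voxel_size_mm
    ext <- min(dm) * h
    centre <- dm * h / 2

    labels <- array(0L, dm)
    brain <- ellipsoidMask(dm, h, centre, rep(0.45 * ext, 3))
    shell_inner <- ellipsoidMask(dm, h, centre, rep(0.45 * ext - 2 * h, 3))
    labels[brain] <- 1L                      # WM
    labels[brain & !shell_inner] <- 5L       # subarachnoid shell
    bg1 <- ellipsoidMask(dm, h, centre + c(-0.13, 0, 0) * ext,
                         c(0.10, 0.14, 0.10) * ext)
    bg2 <- ellipsoidMask(dm, h, centre + c(0.13, 0, 0) * ext,
                         c(0.10, 0.14, 0.10) * ext)
    labels[(bg1 | bg2) & shell_inner] <- 2L  # BG
    v1 <- ellipsoidMask(dm, h, centre + c(-0.035, 0.02, 0.03) * ext,
                        c(0.035, 0.12, 0.05) * ext)
    v2 <- ellipsoidMask(dm, h, centre + c(0.035, 0.02, 0.03) * ext,
                        c(0.035, 0.12, 0.05) * ext)
    labels[(v1 | v2) & shell_inner] <- 4L    # ventricles

    tube_cov <- array(0, dm)
    conf_cov <- array(0, dm)

    # Tubular CSF confounders: capsules anchored at a structure boundary,
    # relabelled to the structure's code so they are CSF-continuous with
    # it and count as false positives if segmented.
    placeConfounders <- function(anchor_lin, allowed, modifiable, new_code,
                                 n, what) {
      for (t in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(200L)) {
          r <- stats::runif(1, spec$tube_radius_range_mm[1],
                            spec$tube_radius_range_mm[2])
          len <- stats::runif(1, spec$tube_length_range_mm[1],
                              spec$tube_length_range_mm[2])
          a_lin <- anchor_lin[sample.int(length(anchor_lin), 1L)]
          ctr <- (arrayInd(a_lin, dm) - 0.5) * h
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          vox <- capsuleVoxels(dm, h, as.numeric(ctr),
                               as.numeric(ctr + u * len), r)
          if (length(vox$inside) > 0L &&
              all(labels[vox$pv_lin] %in% allowed)) {
            sel <- vox$inside[labels[vox$inside] %in% modifiable]
            labels[sel] <<- new_code
            conf_cov[vox$pv_lin] <<- pmax(conf_cov[vox$pv_lin], vox$pv_w)
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop(sprintf("could not place %s confounder %d after %d tries",
                       what, t, 200L))
      }
    }
    if (spec$n_confounders_vent > 0L) {
      vent_edge <- which(labels == 4L &
                           boxDilate(array(labels %in% c(1L, 2L), dm), 1L))
      placeConfounders(vent_edge, c(1L, 2L, 4L), c(1L, 2L), 4L,
                       spec$n_confounders_vent, "ventricle")
    }
    if (spec$n_confounders_shell > 0L) {
      placeConfounders(which(labels == 5L), c(0L, 1L, 5L), c(1L), 5L,
                       spec$n_confounders_shell, "shell")
    }

    placeTubes <- function(region_code, n_tubes, region_name) {
      placed <- vector("list", n_tubes)
      if (n_tubes == 0L) return(placed)
      region_lin <- which(labels == region_code)
      for (t in seq_len(n_tubes)) {
        ok <- FALSE
        for (try in seq_len(200L)) {
          r <- stats::runif(1, spec$tube_radius_range_mm[1],
                            spec$tube_radius_range_mm[2])
          len <- stats::runif(1, spec$tube_length_range_mm[1],
                              spec$tube_length_range_mm[2])
          ctr_lin <- region_lin[sample.int(length(region_lin), 1L)]
          ctr <- (arrayInd(ctr_lin, dm) - 0.5) * h
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          p0 <- as.numeric(ctr - u * len / 2)
          p1 <- as.numeric(ctr + u * len / 2)
          vox <- capsuleVoxels(dm, h, p0, p1, r)
          if (length(vox$inside) > 0L &&
              all(labels[vox$pv_lin] == region_code)) {
            placed[[t]] <- vox$inside
            tube_cov[vox$pv_lin] <<- pmax(tube_cov[vox$pv_lin], vox$pv_w)
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop(sprintf("could not place tube %d in region %s after %d tries",
                       t, region_name, 200L))
        labels[placed[[t]]] <<- 3L
      }
      placed
    }

    wm_tubes <- placeTubes(1L, spec$n_tubes_wm, "WM")
    bg_tubes <- placeTubes(2L, spec$n_tubes_bg, "BG")

    dpvs_lin <- c(unlist(wm_tubes), unlist(bg_tubes))
    dpvs_region <- factor(rep(c("WM", "BG"),
                              c(length(unlist(wm_tubes)),
                                length(unlist(bg_tubes)))),
                          levels = c("WM", "BG"))
    vox_vol <- h^3
    true_vol <- c(WM = sum(dpvs_region == "WM") * vox_vol,
                  BG = sum(dpvs_region == "BG") * vox_vol)

    intens <- array(spec$intensity_background, dm)
    intens[labels == 1L] <- spec$intensity_tissue
    intens[labels == 2L] <- spec$intensity_tissue * 1.05
    intens[labels %in% c(4L, 5L)] <- spec$intensity_csf
    # tubes and confounders rendered with partial-volume coverage, as at
    # MRI resolution
    cov <- pmax(tube_cov, conf_cov)
    pv <- cov > 0
    intens[pv] <- intens[pv] * (1 - cov[pv]) + spec$intensity_csf * cov[pv]

    bias <- biasField(dm, spec$bias_field_amplitude)
    noisy <- intens * bias +
      if (spec$noise_sd > 0) array(stats::rnorm(prod(dm), 0, spec$noise_sd), dm)
      else 0

    structure(list(image = imageVolume(noisy, h),
                   clean = imageVolume(intens, h),
                   labels = labelVolume(labels, h),
                   dpvs_lin = dpvs_lin, dpvs_region = dpvs_region,
                   true_dpvs_volume_mm3 = true_vol, spec = spec),
              class = "PhantomTruth")
  })
}

#' Generate a test-retest replicate of a phantom
#'
#' Keeps the phantom geometry (labels, true volumes) fixed and applies an
#' independent noise and bias realization to the noise-free image, emulating
#' a second MRI acquisition of the same subject for test-retest reliability.
#'
#' @param truth a `PhantomTruth` from [generatePhantom()].
#' @param noise_seed integer seed for the new realization.
#' @return an [ImageVolume-class] with identical geometry, new noise.
#' @export
generateRetest <- function(truth, noise_seed) {
  stopifnot(inherits(truth, "PhantomTruth"))
  spec <- truth$spec
  withSeed(noise_seed, {
    dm <- dim(imageData(truth$clean))
    bias <- biasField(dm, spec$bias_field_amplitude)
    vals <- imageData(truth$clean) * bias +
      if (spec$noise_sd > 0) array(stats::rnorm(prod(dm), 0, spec$noise_sd), dm)
      else 0
    imageVolume(vals, spacingMm(truth$clean))
  })
}

#' Region masks for segmentation from phantom ground truth
#'
#' Returns WM and BG masks as used by the segmentation stage. dPVS voxels
#' carry their own label code in the truth, so they are merged back into
#' their host region here (a tissue segmentation would include them in the
#' region mask).
#'
#' @param truth a `PhantomTruth`.
#' @return list with logical arrays `wm`, `bg`, `brain`.
#' @export
regionMasks <- function(truth) {
  lab <- imageData(truth$labels)
  wm <- lab == 1L
  bg <- lab == 2L
  if (length(truth$dpvs_lin) > 0L) {
    wm[truth$dpvs_lin[truth$dpvs_region == "WM"]] <- TRUE
    bg[truth$dpvs_lin[truth$dpvs_region == "BG"]] <- TRUE
  }
  list(wm = wm, bg = bg, brain = lab > 0L)
}

#' Loose region masks emulating imperfect tissue segmentation
#'
#' Dilates the WM and BG masks by a margin (BG toward the ventricles, WM
#' toward the subarachnoid shell) so that bright CSF boundaries leak into
#' the candidate search region. Real tissue masks are imperfect in exactly
#' this way, and it is these leaks that produce the ventricle-adjacent and
#' subarachnoid false positives the patch classifier is trained to remove.
#'
#' @param truth a `PhantomTruth`.
#' @param margin dilation radius in voxels.
#' @return list with logical arrays `wm`, `bg`, `brain` (masks disjoint;
#'   BG has priority where dilations overlap).
#' @export
looseRegionMasks <- function(truth, margin = 3L) {
  rm_ <- regionMasks(truth)
  brain <- rm_$brain
  bg <- boxDilate(rm_$bg, margin) & brain
  wm <- boxDilate(rm_$wm, margin) & brain & !bg
  list(wm = wm, bg = bg, brain = brain)
}
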