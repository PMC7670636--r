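#' Regional dPVS volumes from a final candidate set
#'
#' Volume per region is the number of retained voxels times the volume of
#' one voxel (the product of the spacing components; 0.343 mm^3 at 0.7 mm
#' isotropic).
#'
#' @param final a [CandidateSet-class].
#' @param spacing_mm voxel edge lengths in mm; defaults to the spacing
#'   recorded in the candidate set.
#' @param subject_id optional identifier carried into the output.
#' @return data.frame with `subject_id`, `bg_dpvs_mm3`, `wm_dpvs_mm3`,
#'   `voxel_volume_mm3`.
#' @export
computeVolumes <- function(final, spacing_mm = NULL, subject_id = NA) {
  if (is.null(spacing_mm)) spacing_mm <- spacingMm(final)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  stopifnot(all(spacing_mm > 0))
  vox <- prod(spacing_mm)
  reg <- final@region[final@component]
  data.frame(subject_id = subject_id,
             bg_dpvs_mm3 = sum(reg == "BG") * vox,
             wm_dpvs_mm3 = sum(reg == "WM") * vox,
             voxel_volume_mm3 = vox)
}

#' One-way random-effects intraclass correlation (single measure)
#'
#' ICC(1,1) from ANOVA mean squares: with two measurements per unit,
#' (MSB - MSW) / (MSB + MSW). Member order within a unit does not affect
#' the result, which makes this the natural flavour both for test-retest
#' volumes and for within-pair twin resemblance.
#'
#' @param values n x 2 numeric matrix (or data.frame), one row per unit.
#' @param model `"oneway"` (default) or `"twoway"` for the two-way
#'   random-effects absolute-agreement single-measure ICC(A,1).
#' @return list with `icc`, `n_units` and `icc_model`.
#' @export
iccPairs <- function(values, model = c("oneway", "twoway")) {
  model <- match.arg(model)
  x <- as.matrix(values)
  stopifnot(ncol(x) == 2L)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 units")
  k <- 2L
  grand <- mean(x)
  rowm <- rowMeans(x)
  msb <- k * sum((rowm - grand)^2) / (n - 1)
  msw <- sum((x - rowm)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0)
    stop("zero between- and within-unit variance: ICC undefined")
  if (model == "oneway") {
    icc <- (msb - msw) / (msb + (k - 1) * msw)
  } else {
    colm <- colMeans(x)
    msc <- n * sum((colm - grand)^2) / (k - 1)
    sst <- sum((x - grand)^2)
    ssb <- k * sum((rowm - grand)^2)
    ssc <- n * sum((colm - grand)^2)
    sse <- sst - ssb - ssc
    mse <- sse / ((n - 1) * (k - 1))
    msr <- ssb / (n - 1)
    icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  }
  list(icc = icc, n_units = n,
       icc_model = if (model == "oneway") "oneway-single"
                   else "twoway-absolute-single")
}

#' False-positive and false-negative volume fractions
#'
#' Compares an automated segmentation with ground truth:
#' `fp_fraction` is the automated volume outside the truth divided by the
#' total automated volume; `fn_fraction` is the truth volume missed divided
#' by the total truth volume. An empty automated set leaves fp undefined
#' (NA) with fn still computed, and symmetrically for empty truth.
#'
#' @param auto a [CandidateSet-class] or logical array.
#' @param truth a [LabelVolume-class] (dPVS = code 3) or logical array on
#'   the same grid.
#' @return named numeric `c(fp_fraction, fn_fraction)`, each in \[0, 1\]
#'   or NA.
#' @export
validityFractions <- function(auto, truth) {
  am <- if (is(auto, "CandidateSet")) candidateMask(auto) else auto
  tm <- if (is(truth, "LabelVolume")) imageData(truth) == 3L else truth
  if (!identical(dim(am), dim(tm)))
    stop("automated and truth grids do not match")
  na <- sum(am)
  nt <- sum(tm)
  fp <- if (na > 0) sum(am & !tm) / na else NA_real_
  fn <- if (nt > 0) sum(tm & !am) / nt else NA_real_
  c(fp_fraction = fp, fn_fraction = fn)
}
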