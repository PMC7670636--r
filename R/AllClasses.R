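#' @import methods
NULL

#' ImageVolume: a 3D scalar intensity grid with voxel spacing
#'
#' Container for a T2-weighted-like 3D volume. Holds the voxel array and the
#' physical voxel edge lengths in millimetres; all filtering operations take
#' spacing into account so that scales and volumes are expressed in mm.
#'
#' @slot values numeric 3D array of intensities.
#' @slot spacing numeric(3), voxel edge lengths in mm (strictly positive).
#'
#' @seealso [imageVolume()], [labelVolume()]
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(values = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@values)) != 3L)
      return("values must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be three strictly positive finite values")
    if (any(!is.finite(object@values)))
      return("values must be finite")
    TRUE
  }
)

#' LabelVolume: an integer-coded region mask aligned to an ImageVolume
#'
#' Integer labels on the same grid as an [ImageVolume-class]. The phantom
#' generator uses codes 0 background, 1 white matter (WM), 2 basal ganglia
#' (BG), 3 dPVS, 4 ventricle, 5 subarachnoid shell.
#'
#' @slot labels integer 3D array.
#' @slot spacing numeric(3), voxel edge lengths in mm.
#'
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(labels = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@labels)) != 3L)
      return("labels must be a 3D array")
    if (!is.integer(object@labels))
      return("labels must be integer-typed")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be three strictly positive values")
    TRUE
  }
)

#' CandidateSet: voxels flagged as potential dPVS, with component structure
#'
#' Result of thresholding the vesselness field inside the WM/BG masks.
#' Voxel coordinates are 0-based indices into the originating grid; voxels
#' are grouped into 26-connected components, each tagged with the region
#' ("WM" or "BG") holding the majority of its voxels.
#'
#' @slot coords integer matrix (n x 3) of 0-based voxel indices.
#' @slot component integer(n), 1-based component id per voxel.
#' @slot region character, region tag per component ("WM"/"BG").
#' @slot dim integer(3), grid dimensions of the originating volume.
#' @slot spacing numeric(3), voxel edge lengths in mm.
#'
#' @exportClass CandidateSet
setClass("CandidateSet",
  representation(coords = "matrix", component = "integer",
                 region = "character", dim = "integer",
                 spacing = "numeric"),
  validity = function(object) {
    n <- nrow(object@coords)
    if (ncol(object@coords) != 3L) return("coords must have 3 columns")
    if (length(object@component) != n)
      return("component must have one entry per voxel")
    if (n > 0L) {
      if (min(object@component) < 1L ||
          max(object@component) > length(object@region))
        return("component ids must index the region vector")
      if (any(object@coords < 0L) ||
          any(sweep(object@coords, 2, object@dim, ">=")))
        return("coords out of grid bounds")
    }
    if (!all(object@region %in% c("WM", "BG")))
      return("region tags must be WM or BG")
    TRUE
  }
)

#' ACEFit: a fitted univariate twin variance-component model
#'
#' Maximum-likelihood fit of the classical-twin ACE model (or its AE/CE/E
#' submodels) on paired phenotypes with group-specific additive-genetic
#' relatedness (1 for MZ, 0.5 for DZ and non-twin siblings). Path
#' coefficients a, c, e are constrained nonnegative; heritability is
#' h2 = a^2 / (a^2 + c^2 + e^2).
#'
#' @slot model character, one of "ACE", "AE", "CE", "E".
#' @slot paths named numeric (a, c, e).
#' @slot mu numeric, shared trait mean.
#' @slot loglik numeric, maximized log-likelihood.
#' @slot npairs named integer, pairs per group.
#' @slot convergence logical.
#'
#' @exportClass ACEFit
setClass("ACEFit",
  representation(model = "character", paths = "numeric", mu = "numeric",
                 loglik = "numeric", npairs = "integer",
                 convergence = "logical", statistics = "list"),
  validity = function(object) {
    if (!object@model %in% c("ACE", "AE", "CE", "E"))
      return("model must be ACE, AE, CE or E")
    if (!all(c("a", "c", "e") %in% names(object@paths)))
      return("paths must be named a, c, e")
    if (any(object@paths < 0)) return("paths must be nonnegative")
    v <- sum(object@paths^2)
    if (v <= 0) return("total variance must be positive")
    TRUE
  }
)

#' CholeskyFit: a fitted bivariate Cholesky ACE model
#'
#' Two-trait twin model in which each variance component's implied 2x2
#' covariance matrix is parameterized as L %*% t(L) for a lower-triangular
#' path matrix L with nonnegative diagonal (off-diagonals free in sign).
#' Genetic correlation and shared heritability are derived from the fitted
#' paths; see [geneticCorrelation()] and [sharedHeritability()].
#'
#' @slot LA,LC,LE numeric 2x2 lower-triangular path matrices.
#' @slot mu numeric(2), trait means.
#' @slot loglik numeric.
#' @slot npairs named integer, pairs per group.
#' @slot convergence logical.
#'
#' @exportClass CholeskyFit
setClass("CholeskyFit",
  representation(LA = "matrix", LC = "matrix", LE = "matrix",
                 mu = "numeric", loglik = "numeric", npairs = "integer",
                 convergence = "logical", statistics = "list"),
  validity = function(object) {
    for (nm in c("LA", "LC", "LE")) {
      L <- slot(object, nm)
      if (!all(dim(L) == c(2L, 2L))) return(paste(nm, "must be 2x2"))
      if (abs(L[1, 2]) > 1e-12) return(paste(nm, "must be lower-triangular"))
      if (L[1, 1] < 0 || L[2, 2] < 0)
        return(paste(nm, "diagonal must be nonnegative"))
    }
    if (length(object@mu) != 2L) return("mu must have length 2")
    TRUE
  }
)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ImageVolume %dx%dx%d, spacing %s mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = "x"),
              min(object@values), max(object@values)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  tab <- table(object@labels)
  cat(sprintf("LabelVolume %dx%dx%d, codes: %s\n", d[1], d[2], d[3],
              paste(names(tab), collapse = " ")))
})

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet: %d voxels in %d components (%d WM, %d BG)\n",
              nrow(object@coords), length(object@region),
              sum(object@region == "WM"), sum(object@region == "BG")))
})

setMethod("show", "ACEFit", function(object) {
  p <- object@paths
  v <- p^2
  cat(sprintf("%s fit: a2=%.3f c2=%.3f e2=%.3f  h2=%.3f  loglik=%.3f\n",
              object@model, v["a"], v["c"], v["e"], v["a"] / sum(v),
              object@loglik))
})

setMethod("show", "CholeskyFit", function(object) {
  cat(sprintf(
    "Bivariate Cholesky ACE fit: rg=%.3f shared_h2=%.3f loglik=%.3f\n",
    geneticCorrelation(object), sharedHeritability(object), object@loglik))
})
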