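#' Accessors for volume and fit classes
#'
#' `imageData` returns the raw voxel array, `spacingMm` the voxel edge
#' lengths in mm, `varianceComponents` the squared path coefficients of a
#' twin-model fit, and `heritability` the narrow-sense heritability
#' a^2 / (a^2 + c^2 + e^2).
#'
#' @param x an [ImageVolume-class], [LabelVolume-class], [CandidateSet-class]
#'   or fit object, as applicable.
#' @return `imageData`: an array; `spacingMm`: numeric(3);
#'   `varianceComponents`: named numeric; `heritability`: a scalar in
#'   \[0, 1\].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @rdname accessors
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))

#' @rdname accessors
#' @export
setGeneric("varianceComponents",
           function(x) standardGeneric("varianceComponents"))

#' @rdname accessors
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' @rdname accessors
#' @export
setMethod("imageData", "ImageVolume", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("imageData", "LabelVolume", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("spacingMm", "ImageVolume", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("spacingMm", "LabelVolume", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("spacingMm", "CandidateSet", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("varianceComponents", "ACEFit", function(x) {
  v <- x@paths^2
  c(a2 = unname(v["a"]), c2 = unname(v["c"]), e2 = unname(v["e"]))
})

#' @rdname accessors
#' @export
setMethod("varianceComponents", "CholeskyFit", function(x) {
  list(A = x@LA %*% t(x@LA), C = x@LC %*% t(x@LC), E = x@LE %*% t(x@LE))
})

#' @rdname accessors
#' @export
setMethod("heritability", "ACEFit", function(x) {
  v <- x@paths^2
  unname(v["a"] / sum(v))
})

#' Number of candidate voxels
#'
#' @param x a [CandidateSet-class].
#' @return integer voxel count.
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "CandidateSet", function(x) nrow(x@coords))

#' Construct an ImageVolume
#'
#' @param values numeric 3D array.
#' @param spacing voxel edge lengths in mm; a scalar is recycled to 3.
#' @return an [ImageVolume-class].
#' @export
imageVolume <- function(values, spacing = 0.7) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ImageVolume", values = values, spacing = as.numeric(spacing))
}

#' Construct a LabelVolume
#'
#' @param labels integer 3D array (coerced with `storage.mode<-`).
#' @param spacing voxel edge lengths in mm; a scalar is recycled to 3.
#' @return a [LabelVolume-class].
#' @export
labelVolume <- function(labels, spacing = 0.7) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels, spacing = as.numeric(spacing))
}
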