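#' Read / write volumes as NIfTI-1
#'
#' Images and label masks are exchanged as NIfTI-1 files with voxel spacing
#' (mm) in the header. Label volumes round-trip as integer arrays.
#'
#' @param vol an [ImageVolume-class] or [LabelVolume-class].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `readImageVolume` returns an [ImageVolume-class];
#'   `readLabelVolume` a [LabelVolume-class].
#' @export
writeVolume <- function(vol, path) {
  arr <- imageData(vol)
  img <- RNifti::asNifti(arr, reference = NULL)
  RNifti::pixdim(img) <- spacingMm(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readImageVolume <- function(path) {
  img <- RNifti::readNifti(path)
  imageVolume(array(as.numeric(img), dim(img)), RNifti::pixdim(img)[1:3])
}

#' @rdname writeVolume
#' @export
readLabelVolume <- function(path) {
  img <- RNifti::readNifti(path)
  labelVolume(array(as.integer(round(img)), dim(img)),
              RNifti::pixdim(img)[1:3])
}
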