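#' Image volume container
#'
#' Light-weight container for a 2D slice or 3D volume of intensities together
#' with its voxel geometry, modality tag and an optional foreground mask.
#' All segmentation and fusion functions in the package accept and return
#' `image_volume` objects; plain matrices/arrays are wrapped on the fly.
#'
#' @param data numeric matrix (2D) or 3D array of finite intensities.
#' @param voxel_size numeric vector, mm per axis (recycled to the
#'   dimensionality of `data`).
#' @param modality `"anatomical"` or `"functional"`.
#' @param mask optional logical array of the same shape marking foreground
#'   voxels; `NULL` means all voxels are foreground.
#' @return An object of class `image_volume`: a list with elements `data`,
#'   `voxel_size`, `modality`, `mask`.
#' @examples
#' img <- image_volume(matrix(runif(64), 8, 8))
#' dim(img$data)
#' @export
image_volume <- function(data,
                         voxel_size = rep(1, length(dim(data))),
                         modality = c("anatomical", "functional"),
                         mask = NULL) {
  modality <- match.arg(modality)
  if (is.null(dim(data))) stop("`data` must be a matrix or array")
  if (!length(dim(data)) %in% c(2L, 3L)) {
    stop("`data` must be 2D or 3D")
  }
  data <- array(as.double(data), dim = dim(data))
  if (!all(is.finite(data))) stop("`data` must be finite")
  voxel_size <- rep_len(as.double(voxel_size), length(dim(data)))
  if (any(voxel_size <= 0)) stop("`voxel_size` must be positive")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(data))) {
      stop("`mask` shape must match `data`")
    }
    mask <- array(as.logical(mask), dim = dim(data))
  }
  structure(list(data = data, voxel_size = voxel_size,
                 modality = modality, mask = mask),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s, %s, voxel %s mm, %s\n",
              paste(dim(x$data), collapse = "x"), x$modality,
              paste(signif(x$voxel_size, 3), collapse = "x"),
              if (is.null(x$mask)) "no mask"
              else sprintf("%d foreground voxels", sum(x$mask))))
  invisible(x)
}

#' Coerce to an image volume
#'
#' @param x an `image_volume`, matrix or array.
#' @param ... passed on to [image_volume()].
#' @return An `image_volume`.
#' @export
as_image_volume <- function(x, ...) {
  if (inherits(x, "image_volume")) return(x)
  image_volume(x, ...)
}

mask_of <- function(img) {
  if (is.null(img$mask)) array(TRUE, dim = dim(img$data)) else img$mask
}

#' Read a NIfTI volume
#'
#' Thin wrapper around [RNifti::readNifti()] returning an [image_volume()].
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param modality modality tag to attach.
#' @param mask optional logical array.
#' @return An `image_volume`.
#' @export
read_volume <- function(path, modality = c("anatomical", "functional"),
                        mask = NULL) {
  nii <- RNifti::readNifti(path)
  pix <- attr(nii, "pixdim")
  d <- dim(nii)
  image_volume(array(as.double(nii), dim = d),
               voxel_size = if (!is.null(pix)) pix[seq_along(d)] else rep(1, length(d)),
               modality = match.arg(modality), mask = mask)
}

#' Write a volume to NIfTI
#'
#' @param img an `image_volume` or numeric array.
#' @param path output path (`.nii` recommended for byte-reproducible output).
#' @param datatype NIfTI datatype, e.g. `"float"` or `"int16"`.
#' @return The path, invisibly.
#' @export
write_volume <- function(img, path, datatype = "float") {
  img <- as_image_volume(img)
  nii <- RNifti::asNifti(img$data)
  RNifti::pixdim(nii) <- img$voxel_size
  RNifti::writeNifti(nii, path, datatype = datatype)
  invisible(path)
}
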