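#' Min-max intensity normalization
#'
#' Rescales foreground intensities linearly so that the masked minimum maps to
#' 0 and the masked maximum to 1, giving every image the same dynamic range.
#' The ordering of voxel intensities is preserved; the operation is
#' idempotent. Background (off-mask) voxels are set to 0.
#'
#' @param img an [image_volume()] (or matrix/array).
#' @return The normalized `image_volume`.
#' @examples
#' img <- image_volume(matrix(c(10, 20, 30, 40), 2, 2))
#' range(normalize_intensity(img)$data)
#' @export
normalize_intensity <- function(img) {
  img <- as_image_volume(img)
  msk <- mask_of(img)
  v <- img$data[msk]
  lo <- min(v); hi <- max(v)
  if (hi - lo <= 0) {
    stop("constant image: min-max normalization is undefined")
  }
  out <- img$data
  out[msk] <- (img$data[msk] - lo) / (hi - lo)
  out[!msk] <- 0
  img$data <- out
  img
}

#' Additive white Gaussian noise
#'
#' Adds zero-mean Gaussian noise with standard deviation
#' `level * (max - min)` of the masked input intensities, i.e. a noise level
#' quoted as a percentage of the image dynamic range. Used to study
#' segmentation robustness across noise levels.
#'
#' @param img an [image_volume()].
#' @param level noise level as a fraction of the dynamic range (>= 0).
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return The noisy `image_volume`.
#' @export
add_gaussian_noise <- function(img, level, seed = NULL) {
  img <- as_image_volume(img)
  stopifnot_scalar(level, "level", lower = 0)
  if (level == 0) return(img)
  msk <- mask_of(img)
  v <- img$data[msk]
  sdev <- level * (max(v) - min(v))
  noise <- with_seed(seed, stats::rnorm(sum(msk), mean = 0, sd = sdev))
  img$data[msk] <- img$data[msk] + noise
  img
}

# reflect-shift a matrix by (di, dj): out[i, j] = x[reflect(i + di), reflect(j + dj)]
shift_reflect <- function(x, di, dj) {
  n <- nrow(x); m <- ncol(x)
  ri <- seq_len(n) + di
  rj <- seq_len(m) + dj
  ri <- ifelse(ri < 1L, 2L - ri, ifelse(ri > n, 2L * n - ri, ri))
  rj <- ifelse(rj < 1L, 2L - rj, ifelse(rj > m, 2L * m - rj, rj))
  x[ri, rj, drop = FALSE]
}

hybrid_median_slice <- function(x) {
  if (nrow(x) < 3L || ncol(x) < 3L) {
    stop("hybrid median filter needs at least a 3x3 image")
  }
  # plus-shaped: N, S, W, E + centre; X-shaped: 4 diagonals + centre
  plus <- cbind(as.vector(shift_reflect(x, -1L, 0L)),
                as.vector(shift_reflect(x,  1L, 0L)),
                as.vector(shift_reflect(x,  0L, -1L)),
                as.vector(shift_reflect(x,  0L,  1L)),
                as.vector(x))
  diag_ <- cbind(as.vector(shift_reflect(x, -1L, -1L)),
                 as.vector(shift_reflect(x, -1L,  1L)),
                 as.vector(shift_reflect(x,  1L, -1L)),
                 as.vector(shift_reflect(x,  1L,  1L)),
                 as.vector(x))
  med5 <- function(m) apply(m, 1L, stats::median)
  mp <- med5(plus)
  mx <- med5(diag_)
  out <- apply(cbind(mp, mx, as.vector(x)), 1L, stats::median)
  matrix(out, nrow(x), ncol(x))
}

#' Hybrid median filter
#'
#' Edge-preserving 3x3 hybrid median: per pixel, the output is the median of
#' three values — the median of the plus-shaped (4-connected) neighbours plus
#' centre, the median of the X-shaped (diagonal) neighbours plus centre, and
#' the centre itself. Unlike a plain median it preserves ideal step edges and
#' corners exactly while removing impulse noise. Image borders are handled by
#' reflection; 3D volumes are filtered slice-by-slice along the last axis.
#'
#' @param img an [image_volume()] or matrix/array.
#' @return The filtered `image_volume`.
#' @export
hybrid_median_filter <- function(img) {
  img <- as_image_volume(img)
  d <- dim(img$data)
  if (length(d) == 2L) {
    img$data <- hybrid_median_slice(img$data)
  } else {
    for (k in seq_len(d[3L])) {
      img$data[, , k] <- hybrid_median_slice(img$data[, , k])
    }
  }
  img
}
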