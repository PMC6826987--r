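#' Phantom specification
#'
#' Parameters for the synthetic multimodal brain phantom: nested tissue
#' regions (a CSF core, a GM ring and a WM exterior inside a circular/spherical
#' brain mask), linear partial-volume mixing across region boundaries, a
#' smooth additive intensity-inhomogeneity (bias) field, and additive white
#' Gaussian noise quoted as a fraction of the image dynamic range.
#'
#' Defaults emulate the study conditions used throughout the package: three
#' tissues, a 20% bias-field amplitude, and noise levels in the 1%–20% range.
#'
#' @param shape integer vector of length 2 or 3, grid dimensions.
#' @param n_tissues number of tissues (currently 3: CSF, GM, WM).
#' @param tissue_means_anat per-tissue mean intensity in `[0,1]` for the
#'   anatomical (T1-like) modality; CSF dark, WM bright.
#' @param tissue_means_func per-tissue mean intensity for the functional
#'   (FDG-like) modality; GM bright, CSF dark.
#' @param pv_width partial-volume boundary width in voxels (>= 0).
#' @param bias_amplitude additive bias-field amplitude as a fraction of the
#'   dynamic range (0.20 mirrors a 20% intensity non-uniformity).
#' @param snr_noise additive Gaussian noise level as a fraction of the dynamic
#'   range, typically in `[0.01, 0.20]`; 0 gives a noiseless phantom.
#' @param seed RNG seed controlling the noise realisation.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L),
                         n_tissues = 3L,
                         tissue_means_anat = c(csf = 0.15, gm = 0.50, wm = 0.85),
                         tissue_means_func = c(csf = 0.05, gm = 0.85, wm = 0.45),
                         pv_width = 2,
                         bias_amplitude = 0.20,
                         snr_noise = 0.05,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (!length(shape) %in% c(2L, 3L) || any(shape < 1L)) {
    stop("`shape` must be 2 or 3 positive integers")
  }
  if (n_tissues != 3L) stop("only the 3-tissue (CSF/GM/WM) phantom is supported")
  for (v in list(tissue_means_anat, tissue_means_func)) {
    if (length(v) != 3L || any(v < 0) || any(v > 1)) {
      stop("tissue means must be 3 values in [0,1]")
    }
    if (anyDuplicated(v)) stop("tissue means must be distinct within a modality")
  }
  stopifnot_scalar(pv_width, "pv_width", lower = 0)
  stopifnot_scalar(bias_amplitude, "bias_amplitude", lower = 0, upper = 1)
  stopifnot_scalar(snr_noise, "snr_noise", lower = 0, upper = 0.99)
  # geometry: radii at 15% / 30% / 45% of the smallest grid dimension
  r <- 0.5 * min(shape) * c(0.30, 0.60, 0.90)
  if (min(shape) < 12L || r[1] <= pv_width / 2 + 1 || (r[2] - r[1]) <= pv_width) {
    stop("shape too small to host the tissue regions at this pv_width")
  }
  structure(list(shape = shape, n_tissues = 3L,
                 tissue_means_anat = tissue_means_anat,
                 tissue_means_func = tissue_means_func,
                 pv_width = pv_width, bias_amplitude = bias_amplitude,
                 snr_noise = snr_noise, seed = as.integer(seed),
                 radii = r),
            class = "phantom_spec")
}

# radial distance of every voxel from the grid centre, in voxels
radial_grid <- function(shape) {
  ctr <- (shape + 1) / 2
  ax <- lapply(seq_along(shape), function(k) (seq_len(shape[k]) - ctr[k])^2)
  if (length(shape) == 2L) {
    sqrt(outer(ax[[1]], ax[[2]], `+`))
  } else {
    r2 <- outer(ax[[1]], ax[[2]], `+`)
    sqrt(outer(r2, ax[[3]], `+`))
  }
}

# smooth off-centre Gaussian bump, rescaled to [-1, 1] over the mask
bias_bump <- function(shape, msk) {
  ctr <- (shape + 1) / 2 + 0.2 * shape   # off-centre to break symmetry
  sig <- 0.5 * min(shape)
  ax <- lapply(seq_along(shape), function(k) (seq_len(shape[k]) - ctr[k])^2)
  d2 <- if (length(shape) == 2L) outer(ax[[1]], ax[[2]], `+`) else
    outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  g <- exp(-d2 / (2 * sig^2))
  v <- g[msk]
  if (max(v) - min(v) <= 0) return(array(0, dim = shape))
  out <- array(0, dim = shape)
  out[msk] <- 2 * (g[msk] - min(v)) / (max(v) - min(v)) - 1
  out
}

#' Generate a synthetic multimodal phantom
#'
#' Builds a paired anatomical/functional phantom with known ground truth:
#' per-voxel tissue mixing fractions (summing to 1 on the brain mask), the
#' argmax label map, the noiseless mixed image per modality, a smooth additive
#' bias field scaled so its maximum magnitude is
#' `bias_amplitude * dynamic range`, and additive Gaussian noise with standard
#' deviation `snr_noise * dynamic range`. Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_sample`: list with `anat`, `func`
#'   ([image_volume()]s with the brain mask attached), `truth_labels`
#'   (integer array, 0 = background, 1 = CSF, 2 = GM, 3 = WM),
#'   `truth_fractions` (array `shape x 3`), `noiseless` and `bias` per
#'   modality, and the `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(32, 32), snr_noise = 0))
#' table(ph$truth_labels)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  shape <- spec$shape
  r <- radial_grid(shape)
  r1 <- spec$radii[1]; r2 <- spec$radii[2]; r3 <- spec$radii[3]
  msk <- r < r3
  w <- spec$pv_width
  ramp <- function(x) clamp01(x)
  if (w > 0) {
    f_csf <- ramp((r1 + w / 2 - r) / w)
    f_wm  <- ramp((r - r2 + w / 2) / w)
  } else {
    f_csf <- (r < r1) * 1.0
    f_wm  <- (r >= r2) * 1.0
  }
  f_gm <- pmax(0, 1 - f_csf - f_wm)
  fr <- array(c(f_csf, f_gm, f_wm), dim = c(shape, 3L))
  # zero all fractions off-mask
  frm <- array(rep(as.numeric(msk), 3L), dim = dim(fr))
  fr <- fr * frm
  # renormalise (guards the corner where the WM ramp is cut by the mask edge)
  tot <- f_csf + f_gm + f_wm
  tot[tot == 0] <- 1
  fr <- sweep(fr, seq_along(shape), tot, "/") * frm

  flat <- matrix(fr, ncol = 3L)
  labels <- array(0L, dim = shape)
  labels[msk] <- max.col(flat[as.vector(msk), , drop = FALSE], ties.method = "first")

  mix <- function(means) {
    img <- array(as.vector(flat %*% means), dim = shape)
    img[!msk] <- 0
    img
  }
  clean_anat <- mix(spec$tissue_means_anat)
  clean_func <- mix(spec$tissue_means_func)

  bump <- bias_bump(shape, msk)
  dyn <- function(img) {
    v <- img[msk]; d <- max(v) - min(v); if (d <= 0) 1 else d
  }
  bias_anat <- spec$bias_amplitude * dyn(clean_anat) * bump
  bias_func <- spec$bias_amplitude * dyn(clean_func) * bump

  noisy <- with_seed(spec$seed, {
    na <- clean_anat; nf <- clean_func
    na[msk] <- na[msk] + bias_anat[msk] +
      stats::rnorm(sum(msk), 0, spec$snr_noise * dyn(clean_anat))
    nf[msk] <- nf[msk] + bias_func[msk] +
      stats::rnorm(sum(msk), 0, spec$snr_noise * dyn(clean_func))
    list(anat = na, func = nf)
  })

  structure(list(
    anat = image_volume(noisy$anat, modality = "anatomical", mask = msk),
    func = image_volume(noisy$func, modality = "functional", mask = msk),
    truth_labels = labels,
    truth_fractions = fr,
    noiseless = list(anat = clean_anat, func = clean_func),
    bias = list(anat = bias_anat, func = bias_func),
    spec = spec
  ), class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %s, %d foreground voxels, noise %.0f%%, bias %.0f%%\n",
              paste(x$spec$shape, collapse = "x"), sum(mask_of(x$anat)),
              100 * x$spec$snr_noise, 100 * x$spec$bias_amplitude))
  invisible(x)
}

#' Write a phantom sample to disk
#'
#' Writes the anatomical/functional images, label map and per-tissue fraction
#' volumes as NIfTI files plus a JSON sidecar with the generating parameters.
#'
#' @param sample a [generate_phantom()] result.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(sample, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(sample$anat, file.path(dir, "anat.nii"))
  write_volume(sample$func, file.path(dir, "func.nii"))
  write_volume(image_volume(array(as.double(sample$truth_labels),
                                  dim = dim(sample$truth_labels))),
               file.path(dir, "truth_labels.nii"), datatype = "int16")
  spec <- sample$spec
  sidecar <- list(shape = spec$shape, pv_width = spec$pv_width,
                  bias_amplitude = spec$bias_amplitude,
                  snr_noise = spec$snr_noise, seed = spec$seed,
                  tissue_means_anat = as.list(spec$tissue_means_anat),
                  tissue_means_func = as.list(spec$tissue_means_func))
  writeLines(to_json(sidecar), file.path(dir, "spec.json"))
  invisible(dir)
}

# minimal JSON writer for flat named lists / numeric vectors (avoids a hard
# jsonlite dependency in the package itself)
to_json <- function(x) {
  enc <- function(v) {
    if (is.list(v)) {
      paste0("{", paste(sprintf('"%s": %s', names(v),
                                vapply(v, enc, "")), collapse = ", "), "}")
    } else if (length(v) > 1L) {
      paste0("[", paste(vapply(unname(as.list(v)), enc, ""), collapse = ", "), "]")
    } else if (is.character(v)) {
      sprintf('"%s"', v)
    } else {
      format(v, digits = 15)
    }
  }
  enc(x)
}

#' Generate a one-class classification fixture
#'
#' Draws a Gaussian target blob (unit isotropic spread) at the origin and an
#' outlier blob displaced by `separation` along the first feature axis, in
#' units of the blob standard deviation. Used to exercise the SVDD classifier
#' with a known geometry.
#'
#' @param n_target number of target points (>= 1).
#' @param n_outlier number of outlier points (>= 0).
#' @param dim feature dimensionality (>= 1).
#' @param separation displacement of the outlier blob centre, in target-blob
#'   standard deviations; 0 makes the two distributions identical.
#' @param seed RNG seed.
#' @return An object of class `oneclass_dataset`: list with `target` and
#'   `outliers` feature matrices, the stacked matrix `x` and factor `y`
#'   (`"target"`/`"outlier"`).
#' @export
generate_oneclass <- function(n_target, n_outlier, dim = 2L,
                              separation = 4, seed = 1L) {
  if (n_target < 1L) stop("`n_target` must be >= 1")
  if (n_outlier < 0L) stop("`n_outlier` must be >= 0")
  if (dim < 1L) stop("`dim` must be >= 1")
  stopifnot_scalar(separation, "separation", lower = 0)
  with_seed(seed, {
    tgt <- matrix(stats::rnorm(n_target * dim), n_target, dim)
    out <- if (n_outlier > 0L) {
      o <- matrix(stats::rnorm(n_outlier * dim), n_outlier, dim)
      o[, 1L] <- o[, 1L] + separation
      o
    } else {
      matrix(numeric(0), 0L, dim)
    }
    structure(list(target = tgt, outliers = out,
                   x = rbind(tgt, out),
                   y = factor(rep(c("target", "outlier"),
                                  c(n_target, n_outlier)),
                              levels = c("target", "outlier"))),
              class = "oneclass_dataset")
  })
}
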