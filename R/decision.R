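#' Label map from fused possibility maps
#'
#' Maximum-possibility rule: each foreground voxel is assigned to the tissue
#' with the largest fused possibility. Exact ties are broken by the fixed
#' priority CSF, GM, WM (the number of ties is recorded in the `"n_ties"`
#' attribute). Voxels where every possibility is 0 — and off-mask voxels —
#' are labelled 0 (background).
#'
#' @param fused a [fuse_all()] result (or a named list of per-tissue arrays).
#' @return Integer array of labels (0 background, 1 CSF, 2 GM, 3 WM) with
#'   attributes `tissues` and `n_ties`.
#' @export
decide_labels <- function(fused) {
  maps <- if (inherits(fused, "fused_map_set")) fused$maps else fused
  shp <- dim(maps$csf)
  P <- cbind(as.vector(maps$csf), as.vector(maps$gm), as.vector(maps$wm))
  fg <- rowSums(P) > 0
  if (inherits(fused, "fused_map_set") && !is.null(fused$mask)) {
    fg <- fg & as.vector(fused$mask)
  }
  lab <- integer(nrow(P))
  if (any(fg)) {
    lab[fg] <- max.col(P[fg, , drop = FALSE], ties.method = "first")
  }
  rowmax <- apply(P[fg, , drop = FALSE], 1L, max)
  n_ties <- sum(rowSums(P[fg, , drop = FALSE] == rowmax) > 1L)
  out <- array(lab, dim = shp)
  attr(out, "tissues") <- c("csf", "gm", "wm")
  attr(out, "n_ties") <- n_ties
  out
}

#' Partial-volume fractions
#'
#' Normalises the fused possibility degrees into per-tissue mixing fractions,
#' \eqn{p_T(v) = \pi_T(v) / \sum_i \pi_i(v)}: on every foreground voxel the
#' fractions sum to 1. Voxels with all-zero possibilities get all-zero
#' fractions (background).
#'
#' @param fused a [fuse_all()] result (or named list of per-tissue arrays).
#' @return An object of class `partial_volume_set`: named list of fraction
#'   arrays `csf`, `gm`, `wm`.
#' @export
partial_volumes <- function(fused) {
  maps <- if (inherits(fused, "fused_map_set")) fused$maps else fused
  shp <- dim(maps$csf)
  tot <- maps$csf + maps$gm + maps$wm
  denom <- ifelse(tot > 0, tot, 1)
  out <- lapply(maps[c("csf", "gm", "wm")], function(mp) {
    p <- mp / denom
    dim(p) <- shp
    p
  })
  structure(out, class = "partial_volume_set")
}

#' Synthesis image
#'
#' Builds the anatomo-functional synthesis image by mixing per-tissue mean
#' functional activities with the partial-volume fractions:
#' \eqn{v = \sum_T b_T \, p_T(v)}. `b_T` is typically the functional-modality
#' PFCM centroid of tissue T, so the output combines anatomical tissue
#' geometry with functional intensity levels. The operation is linear in `b`
#' and the output range is contained in `[min(b) , max(b)]` on foreground.
#'
#' @param fused a [fuse_all()] result, or a [partial_volumes()] result.
#' @param b named numeric vector of per-tissue mean functional activity
#'   (`csf`, `gm`, `wm`).
#' @return A functional [image_volume()].
#' @export
synthesize <- function(fused, b) {
  pv <- if (inherits(fused, "partial_volume_set")) fused else partial_volumes(fused)
  if (is.null(names(b))) names(b) <- c("csf", "gm", "wm")
  img <- b[["csf"]] * pv$csf + b[["gm"]] * pv$gm + b[["wm"]] * pv$wm
  image_volume(array(img, dim = dim(pv$csf)), modality = "functional")
}

#' Tissue volume report
#'
#' Per-tissue voxel counts and volumes: the hard volume counts labelled
#' voxels, the soft volume integrates the partial-volume fractions
#' (\eqn{\sum_v p_T(v) \times} voxel volume), which respects mixed voxels at
#' tissue interfaces. Soft volumes sum to the total foreground volume.
#'
#' @param pv a [partial_volumes()] result.
#' @param labels a [decide_labels()] result.
#' @param voxel_size numeric vector, mm per axis.
#' @return A `data.frame` with columns `tissue`, `n_voxels`, `hard_volume`,
#'   `soft_volume` (mm^3).
#' @export
quantify <- function(pv, labels, voxel_size = rep(1, length(dim(labels)))) {
  vox <- prod(voxel_size)
  tissues <- c("csf", "gm", "wm")
  data.frame(
    tissue = tissues,
    n_voxels = vapply(1:3, function(i) sum(labels == i), 0L),
    hard_volume = vapply(1:3, function(i) sum(labels == i) * vox, 0),
    soft_volume = vapply(tissues, function(t) sum(pv[[t]]) * vox, 0),
    row.names = NULL
  )
}
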