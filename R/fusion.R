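#' Possibility map set
#'
#' Per-tissue, per-modality possibility distributions \eqn{\pi_T(v) \in [0,1]}
#' on a common voxel grid — the bridge between the per-modality PFCM
#' typicality maps and the fusion stage.
#'
#' @param anat named list of per-tissue possibility arrays from the
#'   anatomical modality (names `csf`, `gm`, `wm`).
#' @param func matching list for the functional modality.
#' @param mask optional logical foreground mask shared by all maps.
#' @return An object of class `possibility_map_set`.
#' @export
possibility_map_set <- function(anat, func, mask = NULL) {
  tissues <- c("csf", "gm", "wm")
  for (nm in tissues) {
    if (is.null(anat[[nm]]) || is.null(func[[nm]])) {
      stop("both modalities need maps named csf, gm, wm")
    }
    if (!identical(dim(anat[[nm]]), dim(func[[nm]]))) {
      stop("modalities must share the voxel grid")
    }
    for (mp in list(anat[[nm]], func[[nm]])) {
      if (min(mp) < -1e-9 || max(mp) > 1 + 1e-9) {
        stop("possibility values must lie in [0,1]")
      }
    }
  }
  structure(list(anat = lapply(anat[tissues], clamp01),
                 func = lapply(func[tissues], clamp01),
                 tissues = tissues, mask = mask),
            class = "possibility_map_set")
}

#' Agreement between two possibility distributions
#'
#' \eqn{h = 1 - \mathrm{mean}_v |\pi_1(v) - \pi_2(v)|}: 1 for identical maps,
#' 0 for maximally conflicting ones. The mean runs over the foreground mask
#' when one is given. `h` drives the adaptive fusion operators — high
#' agreement lets the conjunctive (min) branch dominate, low agreement makes
#' the operators cautious.
#'
#' @param pi1,pi2 possibility arrays on the same grid, values in `[0,1]`.
#' @param mask optional logical array restricting the average.
#' @return Scalar `h` in `[0,1]`.
#' @examples
#' agreement(c(1, 0.5, 0), c(0.5, 0.5, 0.5))  # 2/3
#' @export
agreement <- function(pi1, pi2, mask = NULL) {
  if (!identical(dim(pi1), dim(pi2)) || length(pi1) != length(pi2)) {
    stop("maps must share the same grid")
  }
  if (!is.null(mask)) {
    pi1 <- pi1[mask]; pi2 <- pi2[mask]
  }
  if (length(pi1) == 0L) stop("empty grid")
  if (min(pi1, pi2) < -1e-9 || max(pi1, pi2) > 1 + 1e-9) {
    stop("possibility values must lie in [0,1]")
  }
  1 - mean(abs(pi1 - pi2))
}

#' Context-dependent possibilistic fusion operators
#'
#' Applies one of four fusion operators voxel-wise to a pair of possibility
#' maps, adapting to their global agreement `h`:
#' \describe{
#'   \item{FOP1}{\eqn{\max(\min(\pi_1,\pi_2)/h,\; 1-h)}}
#'   \item{FOP2}{\eqn{\min(1,\; \min(\pi_1,\pi_2)/h + 1-h)}}
#'   \item{FOP3}{\eqn{\min(\pi_1,\pi_2) + 1-h}}
#'   \item{FOP4}{\eqn{\max(\min(\pi_1,\pi_2)/h,\;
#'     \min(\max(\pi_1,\pi_2),\, 1-h))}}
#' }
#' When the sources agree (`h` near 1) all four reduce to the conjunctive
#' T-norm `min`; as agreement drops the `1-h` branches take over and the
#' operators act cautiously. `h` is floored at `1e-6` before division and
#' results are clamped to `[0,1]` (the renormalised T-norm can exceed 1 as
#' written).
#'
#' @param k operator id, 1–4.
#' @param pi1,pi2 possibility arrays (same shape).
#' @param h agreement scalar in `[0,1]`, e.g. from [agreement()].
#' @return Fused possibility array, values in `[0,1]`.
#' @export
fop <- function(k, pi1, pi2, h) {
  if (!k %in% 1:4) stop("operator id must be 1, 2, 3 or 4")
  stopifnot_scalar(h, "h", lower = 0, upper = 1)
  hh <- max(h, 1e-6)
  lo <- pmin(pi1, pi2)
  out <- switch(as.character(k),
    "1" = pmax(lo / hh, 1 - h),
    "2" = pmin(1, lo / hh + 1 - h),
    "3" = lo + 1 - h,
    "4" = pmax(lo / hh, pmin(pmax(pi1, pi2), 1 - h))
  )
  out <- clamp01(out)
  if (!is.null(dim(pi1))) dim(out) <- dim(pi1)
  out
}

#' Fuse a multimodal possibility map set
#'
#' GM and WM maps are fused with the selected operator using a per-tissue
#' agreement `h`; the CSF fused map is copied from the anatomical modality
#' unchanged, because functional images carry no reliable CSF information.
#'
#' @param maps a [possibility_map_set()].
#' @param k fusion operator id (1–4); FOP4 is the default used by the full
#'   pipeline.
#' @return An object of class `fused_map_set`: list with `maps` (per-tissue
#'   fused arrays), `operator`, `h` (named agreement per tissue), `mask`.
#' @export
fuse_all <- function(maps, k = 4) {
  if (!inherits(maps, "possibility_map_set")) {
    stop("`maps` must be a possibility_map_set")
  }
  h <- vapply(maps$tissues, function(t) {
    agreement(maps$anat[[t]], maps$func[[t]], maps$mask)
  }, 0)
  fused <- list(
    csf = maps$anat$csf,   # anatomical passthrough
    gm  = fop(k, maps$anat$gm, maps$func$gm, h[["gm"]]),
    wm  = fop(k, maps$anat$wm, maps$func$wm, h[["wm"]])
  )
  structure(list(maps = fused, operator = as.integer(k), h = h,
                 mask = maps$mask),
            class = "fused_map_set")
}
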