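#' Pipeline configuration
#'
#' Bundles all stage configurations of the end-to-end segmentation/fusion/
#' classification pipeline, plus the fixed tissue ordering that makes label
#' ids reproducible. Converged cluster centroids are matched to tissue names
#' by sorting them by intensity and applying the per-modality order:
#' anatomical (T1-like) images rank CSF < GM < WM, functional (FDG-like)
#' images rank CSF < WM < GM.
#'
#' @param cluster a [cluster_config()].
#' @param ga a [ga_config()].
#' @param fusion_operator fusion operator id (1–4), default FOP4.
#' @param svdd an [svdd_config()].
#' @param bias_correct if `TRUE` (default), the modeling stage refits BCFCM
#'   from the GA-refined centroids and hands PFCM the bias-compensated
#'   intensities `x - beta` — intensity-inhomogeneity correction is the
#'   reason BCFCM sits at the head of the chain. The field uses the
#'   planar basis of [cluster_config()]'s `bias_degree` default, which
#'   cannot absorb genuine large-scale tissue contrast; on bias-free input
#'   the estimated field is essentially zero, so the correction is safe to
#'   leave on.
#' @param tissue_order_anat,tissue_order_func tissue names in order of
#'   increasing mean intensity per modality.
#' @param seed master seed; every stochastic stage derives its seed from it,
#'   so a fixed master seed determines every artifact.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cluster = cluster_config(),
                            ga = ga_config(),
                            fusion_operator = 4L,
                            svdd = svdd_config(),
                            tissue_order_anat = c("csf", "gm", "wm"),
                            tissue_order_func = c("csf", "wm", "gm"),
                            bias_correct = TRUE,
                            seed = 1L) {
  if (!fusion_operator %in% 1:4) stop("`fusion_operator` must be in 1..4")
  structure(list(cluster = cluster, ga = ga,
                 fusion_operator = as.integer(fusion_operator),
                 svdd = svdd, bias_correct = isTRUE(bias_correct),
                 tissues = c("csf", "gm", "wm"),
                 tissue_order_anat = tissue_order_anat,
                 tissue_order_func = tissue_order_func,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# map converged cluster columns to tissue names via the per-modality
# intensity ordering
tissue_assignment <- function(centers, order_names) {
  stopifnot(length(order_names) == nrow(as.matrix(centers)))
  ord <- order(as.matrix(centers)[, 1L])
  out <- integer(length(ord))
  out[ord] <- seq_along(ord)
  # cluster i is the out[i]-th darkest -> tissue order_names[out[i]]
  stats::setNames(order_names[out], paste0("cluster", seq_along(ord)))
}

# reshape a masked N x C matrix of degrees into per-tissue full-grid arrays
maps_from_matrix <- function(M, tissue_of, shape, msk) {
  tissues <- c("csf", "gm", "wm")
  out <- lapply(tissues, function(t) {
    arr <- array(0, dim = shape)
    col <- which(tissue_of == t)
    arr[msk] <- M[, col]
    arr
  })
  names(out) <- tissues
  out
}

#' Per-modality modeling: BCFCM init, GA refinement, PFCM maps
#'
#' The modeling stage of the pipeline: the image is min-max normalized, a
#' population of BCFCM runs initialises the genetic algorithm, the GA's best
#' centroid set (with its induced fuzzy partition) initialises PFCM, and the
#' PFCM typicality matrix — absolute degrees of compatibility — becomes the
#' per-tissue possibility maps \eqn{\pi_T}. The fuzzy partition `u` is
#' retained for inspection.
#'
#' @param img an [image_volume()] (or array).
#' @param cfg a [pipeline_config()].
#' @param modality overrides the image's modality tag.
#' @param seed stage seed; defaults to the config's master seed.
#' @return List of class `modeling_result`: `maps` (per-tissue possibility
#'   arrays), `u_maps` (fuzzy counterparts), `centers` (named per tissue),
#'   `tissue_of` (cluster to tissue map), `pfcm`, `ga`, `mask`.
#' @export
run_modeling <- function(img, cfg = pipeline_config(), modality = NULL,
                         seed = NULL) {
  img <- as_image_volume(img)
  modality <- modality %||% img$modality
  img <- normalize_intensity(img)
  seed <- seed %||% cfg$seed
  msk <- mask_of(img)
  shape <- dim(img$data)
  X <- img$data[msk]

  ga_cfg <- cfg$ga
  ga_cfg$seed <- derive_seed(seed, 1L)
  pop <- ga_init_population(img, cfg$cluster, ga_cfg, method = "bcfcm")
  evo <- ga_evolve(pop, X, ga_cfg, m = cfg$cluster$m)
  beta <- NULL
  if (isTRUE(cfg$bias_correct)) {
    # refit BCFCM from the GA-refined centroids and hand PFCM the
    # bias-compensated intensities
    bc <- bcfcm_fit(img, cfg$cluster, init = evo$centers)
    beta <- bc$beta
    X <- X - beta
  }
  pf <- pfcm_fit(X, cfg$cluster, init = list(centers = evo$centers, u = evo$u))

  ord <- if (modality == "functional") cfg$tissue_order_func else cfg$tissue_order_anat
  tissue_of <- tissue_assignment(pf$centers, ord)
  maps <- maps_from_matrix(pf$t, tissue_of, shape, msk)
  u_maps <- maps_from_matrix(pf$u, tissue_of, shape, msk)
  centers <- stats::setNames(as.numeric(pf$centers), tissue_of)

  structure(list(maps = maps, u_maps = u_maps,
                 centers = centers[c("csf", "gm", "wm")],
                 tissue_of = tissue_of, pfcm = pf, ga = evo, beta = beta,
                 mask = msk, modality = modality),
            class = "modeling_result")
}

#' Full anatomo-functional pipeline
#'
#' Runs modeling on both modalities, fuses the possibility maps
#' (CSF passes through from the anatomical modality), and applies the
#' decision stage: label map, partial-volume fractions, tissue volume
#' report, and the synthesis image built from the functional PFCM centroids.
#'
#' @param anat,func co-registered anatomical and functional
#'   [image_volume()]s on the same grid.
#' @param cfg a [pipeline_config()].
#' @return List of class `pipeline_result` with `modeling` (per modality),
#'   `fused`, `labels`, `pv`, `synthesis`, `volumes`.
#' @export
run_full <- function(anat, func, cfg = pipeline_config()) {
  anat <- as_image_volume(anat, modality = "anatomical")
  func <- as_image_volume(func)
  if (!identical(dim(anat$data), dim(func$data))) {
    stop("modalities must share the voxel grid")
  }
  stage_seed <- derive_seed(cfg$seed, 11L)
  ma <- run_modeling(anat, cfg, modality = "anatomical", seed = stage_seed)
  mf <- run_modeling(func, cfg, modality = "functional", seed = stage_seed)
  pms <- possibility_map_set(ma$maps, mf$maps, mask = ma$mask)
  fused <- fuse_all(pms, cfg$fusion_operator)
  labels <- decide_labels(fused)
  pv <- partial_volumes(fused)
  synth <- synthesize(pv, mf$centers)
  vols <- quantify(pv, labels, anat$voxel_size)
  structure(list(modeling = list(anat = ma, func = mf), fused = fused,
                 labels = labels, pv = pv, synthesis = synth,
                 volumes = vols),
            class = "pipeline_result")
}

# the 15 baseline clustering schemes of the benchmark grid
variant_table <- function() {
  data.frame(
    id = 1:15,
    model = c("fcm",
              rep("pcm", 5), rep("fpcm", 5), rep("pfcm", 4)),
    init = c("random",
             rep(c("random", "fcm", "fcm_ga", "bcfcm", "bcfcm_ga"), 2),
             c("random", "fcm", "fcm_ga", "bcfcm")),
    stringsAsFactors = FALSE
  )
}

variant_scheme <- function(id) {
  if (identical(id, "proposed")) {
    return(list(model = "pfcm", init = "bcfcm_ga"))
  }
  tab <- variant_table()
  row <- tab[tab$id == id, ]
  if (nrow(row) != 1L) stop(sprintf("unknown clustering variant '%s'", id))
  list(model = row$model, init = row$init)
}

# run one clustering scheme on a (normalized) image; returns a label array
run_variant <- function(img, scheme, cfg = pipeline_config(), seed = 1L) {
  img <- normalize_intensity(as_image_volume(img))
  msk <- mask_of(img)
  X <- img$data[msk]
  ccfg <- cfg$cluster
  ccfg$seed <- derive_seed(seed, 2L)

  init <- switch(scheme$init,
    random = NULL,
    fcm = {
      f <- fcm_fit(X, ccfg)
      list(centers = f$centers, u = f$u)
    },
    fcm_ga = {
      ga_cfg <- cfg$ga; ga_cfg$seed <- derive_seed(seed, 3L)
      pop <- ga_init_population(X, ccfg, ga_cfg, method = "fcm")
      evo <- ga_evolve(pop, X, ga_cfg, m = ccfg$m)
      list(centers = evo$centers, u = evo$u)
    },
    bcfcm = {
      f <- bcfcm_fit(img, ccfg)
      list(centers = f$centers, u = f$u)
    },
    bcfcm_ga = {
      ga_cfg <- cfg$ga; ga_cfg$seed <- derive_seed(seed, 3L)
      pop <- ga_init_population(img, ccfg, ga_cfg, method = "bcfcm")
      evo <- ga_evolve(pop, X, ga_cfg, m = ccfg$m)
      list(centers = evo$centers, u = evo$u)
    },
    stop("unknown init scheme"))

  if (isTRUE(cfg$bias_correct) && !is.null(init) &&
      scheme$init %in% c("bcfcm", "bcfcm_ga")) {
    bc <- bcfcm_fit(img, ccfg, init = init$centers)
    X <- X - bc$beta
  }

  fit <- switch(scheme$model,
    fcm = fcm_fit(X, ccfg, init = init$centers),
    pcm = {
      if (is.null(init)) pcm_fit(X, ccfg) else {
        ccfg$gamma <- ccfg$gamma %||%
          estimate_gamma(X, init$u, init$centers, ccfg)
        pcm_fit(X, ccfg, init = init$centers)
      }
    },
    fpcm = fpcm_fit(X, ccfg, init = init$centers),
    pfcm = {
      if (is.null(init)) {
        B0 <- init_centers(matrix(X, ncol = 1L), ccfg$C, ccfg$seed)
        pfcm_fit(X, ccfg, init = list(centers = B0))
      } else {
        pfcm_fit(X, ccfg, init = init)
      }
    },
    stop("unknown model"))

  M <- if (!is.null(fit$t)) fit$t else fit$u
  tissue_of <- tissue_assignment(fit$centers, cfg$tissue_order_anat)
  maps <- maps_from_matrix(M, tissue_of, dim(img$data), msk)
  labels <- array(0L, dim = dim(img$data))
  flat <- cbind(as.vector(maps$csf), as.vector(maps$gm), as.vector(maps$wm))
  labels[msk] <- max.col(flat[as.vector(msk), , drop = FALSE],
                         ties.method = "first")
  list(labels = labels, fit = fit, maps = maps)
}

#' Benchmark clustering schemes across noise levels
#'
#' Reruns the comparison grid on phantoms: for every requested scheme id
#' (1–15, or `"proposed"` for the hybrid BCFCM/GA-initialised PFCM) and noise
#' level, a phantom is generated, segmented on its anatomical image, and the
#' per-tissue Tanimoto coefficient and Jaccard similarity against the ground
#' truth are recorded.
#'
#' @param variants vector of scheme ids (subset of 1–15 and/or
#'   `"proposed"`).
#' @param noise_levels noise fractions to sweep (e.g. `seq(0.01, 0.20, by = 0.05)`).
#' @param spec base [phantom_spec()]; its `snr_noise` and `seed` are
#'   overridden per cell.
#' @param seeds seeds (one phantom + fit per seed and cell).
#' @param cfg a [pipeline_config()].
#' @param filter if `TRUE` (default) each noisy phantom image is hybrid
#'   median filtered before segmentation, the same denoising step every
#'   scheme sees in the preprocessing protocol.
#' @return A long `data.frame`: `variant`, `model`, `init`, `noise`, `seed`,
#'   `tissue`, `tc`, `js`.
#' @export
run_benchmark <- function(variants = c(1L, 15L, "proposed"),
                          noise_levels = c(0.01, 0.10, 0.20),
                          spec = phantom_spec(shape = c(32L, 32L)),
                          seeds = 1L,
                          cfg = pipeline_config(),
                          filter = TRUE) {
  rows <- list()
  for (v in variants) {
    vv <- if (v == "proposed") "proposed" else as.integer(v)
    scheme <- variant_scheme(vv)
    for (nl in noise_levels) {
      for (sd in seeds) {
        sp <- spec
        sp$snr_noise <- nl
        sp$seed <- derive_seed(sd, round(1000 * nl))
        ph <- generate_phantom(sp)
        img <- if (filter) hybrid_median_filter(ph$anat) else ph$anat
        res <- run_variant(img, scheme, cfg, seed = sp$seed)
        for (ti in 1:3) {
          rows[[length(rows) + 1L]] <- data.frame(
            variant = as.character(v), model = scheme$model,
            init = scheme$init, noise = nl, seed = sd,
            tissue = c("csf", "gm", "wm")[ti],
            tc = tanimoto(res$labels, ph$truth_labels, ti),
            js = jaccard(res$labels == ti, ph$truth_labels == ti),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
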