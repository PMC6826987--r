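#' Clustering configuration
#'
#' Shared configuration for the fuzzy/possibilistic clustering kernels.
#'
#' @param C number of clusters (tissue classes), >= 2 for image segmentation.
#' @param m fuzzifier (> 1); `m = 2` is the conventional choice and the one
#'   used throughout the package's own experiments.
#' @param eta possibilistic exponent (> 1), controls how fast typicality
#'   decays with distance; values around 3–5 give well-behaved typicalities.
#' @param a,b PFCM trade-off weights (> 0) balancing the fuzzy (`a`) and
#'   possibilistic (`b`) terms in the objective and centroid update.
#' @param alpha BCFCM neighbourhood weight; larger values enforce more
#'   spatial smoothness (useful at low SNR), 0 disables the neighbour term.
#' @param eps convergence threshold on `|J(k+1) - J(k)|`.
#' @param max_iter iteration safety cap.
#' @param gamma optional per-cluster possibilistic penalties; estimated from
#'   the initial fuzzy partition via [estimate_gamma()] when `NULL`.
#' @param bias_degree polynomial total degree of the BCFCM bias-field basis.
#'   The default planar field (degree 1) corrects global intensity gradients
#'   without risking absorption of large-scale tissue structure; raise it
#'   when the tissue geometry is spatially rough relative to the
#'   inhomogeneity.
#' @param gamma_mult multiplier applied to the estimated gamma.
#' @param seed RNG seed used for random centroid initialisation.
#' @return An object of class `cluster_config`.
#' @export
cluster_config <- function(C = 3L, m = 2, eta = 4, a = 1, b = 1,
                           alpha = 0.7, eps = 0.005, max_iter = 200L,
                           gamma = NULL, gamma_mult = 1, bias_degree = 1L,
                           seed = NULL) {
  stopifnot_scalar(m, "m", lower = 1, strict_lower = TRUE)
  stopifnot_scalar(eta, "eta", lower = 1, strict_lower = TRUE)
  stopifnot_scalar(a, "a", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(b, "b", lower = 0)
  stopifnot_scalar(alpha, "alpha", lower = 0)
  stopifnot_scalar(eps, "eps", lower = 0, strict_lower = TRUE)
  if (C < 1L) stop("`C` must be >= 1")
  if (!is.null(gamma) && any(gamma <= 0)) stop("`gamma` must be positive")
  structure(list(C = as.integer(C), m = m, eta = eta, a = a, b = b,
                 alpha = alpha, eps = eps, max_iter = as.integer(max_iter),
                 gamma = gamma, gamma_mult = gamma_mult,
                 bias_degree = as.integer(bias_degree), seed = seed),
            class = "cluster_config")
}

as_feature_matrix <- function(X) {
  if (inherits(X, "image_volume")) X <- X$data[mask_of(X)]
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("features must be finite")
  X
}

# random init: C distinct data points, seeded
init_centers <- function(X, C, seed = NULL) {
  N <- nrow(X)
  if (N < C) stop("need at least C observations")
  idx <- with_seed(seed, sample.int(N, C))
  X[idx, , drop = FALSE]
}

as_center_matrix <- function(init, d) {
  B <- as.matrix(init)
  if (ncol(B) != d) B <- matrix(as.double(init), ncol = d)
  storage.mode(B) <- "double"
  B
}

# FCM membership update with zero-distance convention: a point sitting exactly
# on a centroid gets full membership there.
fcm_memberships <- function(D2, m) {
  N <- nrow(D2); C <- ncol(D2)
  u <- matrix(0, N, C)
  zero <- D2 < 1e-300
  hit <- rowSums(zero) > 0L
  if (any(!hit)) {
    tmp <- D2[!hit, , drop = FALSE]^(-1 / (m - 1))
    u[!hit, ] <- tmp / rowSums(tmp)
  }
  if (any(hit)) {
    # zero-distance convention: full membership on the touched centroid(s),
    # split equally if several coincide there
    z <- zero[hit, , drop = FALSE]
    u[hit, ] <- z / rowSums(z)
  }
  u
}

warn_coincident <- function(B) {
  C <- nrow(B)
  if (C < 2L) return(invisible())
  d2 <- dist2_matrix(B, B)
  d2[upper.tri(d2, diag = TRUE)] <- Inf
  if (min(d2) < 1e-16) {
    warning("coincident cluster centroids detected", call. = FALSE)
  }
  invisible()
}

#' Fuzzy c-means clustering
#'
#' Classic FCM: alternates the column-stochastic membership update
#' \eqn{u_{ij} \propto d_{ij}^{-2/(m-1)}} and the fuzzily weighted centroid
#' update until the objective \eqn{J = \sum u^m d^2} changes by less than
#' `eps`. The objective trace is non-increasing (block coordinate descent).
#'
#' @param X numeric matrix (N observations x d features), vector, or
#'   [image_volume()] (masked intensities are used).
#' @param cfg a [cluster_config()].
#' @param init initial centroids (C x d matrix) or `NULL` for a seeded random
#'   draw of C data points.
#' @return List of class `fcm_fit`: `u` (N x C memberships, rows sum to 1),
#'   `centers` (C x d), `objective` (trace of J), `iterations`, `converged`.
#' @examples
#' X <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 6), ncol = 2))
#' fit <- fcm_fit(X, cluster_config(C = 2, seed = 1))
#' fit$centers
#' @export
fcm_fit <- function(X, cfg = cluster_config(), init = NULL) {
  X <- as_feature_matrix(X)
  C <- cfg$C; m <- cfg$m
  if (nrow(X) < C) stop("N must be >= C")
  B <- if (is.null(init)) init_centers(X, C, cfg$seed) else as_center_matrix(init, ncol(X))
  trace <- numeric(0)
  converged <- FALSE
  for (k in seq_len(cfg$max_iter)) {
    D2 <- dist2_matrix(X, B)
    u <- fcm_memberships(D2, m)
    um <- u^m
    wsum <- colSums(um)
    wsum[wsum == 0] <- .Machine$double.xmin
    B <- (t(um) %*% X) / wsum
    J <- sum(um * dist2_matrix(X, B))
    trace <- c(trace, J)
    if (k > 1L && abs(trace[k] - trace[k - 1L]) < cfg$eps) {
      converged <- TRUE
      break
    }
  }
  warn_coincident(B)
  structure(list(u = u, centers = B, objective = trace,
                 iterations = length(trace), converged = converged,
                 m = m),
            class = "fcm_fit")
}

#' Estimate possibilistic penalty terms
#'
#' Per-cluster penalty \eqn{\gamma_i = K \sum_j u_{ij}^m d^2(x_j, b_i) /
#' \sum_j u_{ij}^m}: the fuzzily weighted within-cluster spread of the
#' initialising partition (Krishnapuram–Keller convention, `K = 1`).
#' A vanishing spread (all points at the centroid) is degenerate and is
#' flagged with a warning; gammas are floored at `1e-12` to stay positive.
#'
#' @param X feature matrix, vector or [image_volume()].
#' @param u N x C fuzzy partition.
#' @param centers C x d centroid matrix.
#' @param cfg a [cluster_config()]; uses `m` and `gamma_mult`.
#' @return Numeric vector of C positive penalties.
#' @export
estimate_gamma <- function(X, u, centers, cfg = cluster_config()) {
  X <- as_feature_matrix(X)
  B <- as_center_matrix(centers, ncol(X))
  um <- u^cfg$m
  D2 <- dist2_matrix(X, B)
  g <- cfg$gamma_mult * colSums(um * D2) / colSums(um)
  if (any(g < 1e-12)) {
    warning("degenerate cluster spread: gamma floored at 1e-12", call. = FALSE)
    g <- pmax(g, 1e-12)
  }
  g
}

#' Possibilistic c-means clustering
#'
#' PCM: typicalities depend only on the distance to each cluster's own
#' centroid, \eqn{t_{ij} = 1/(1 + (d^2/\gamma_i)^{1/(\eta-1)})}, with
#' typicality-weighted centroid updates. Clusters are estimated
#' independently, so coincident centroids can occur on poorly separated data
#' (reported as a warning).
#'
#' @inheritParams fcm_fit
#' @return List of class `pcm_fit`: `t` (N x C typicalities), `centers`,
#'   `gamma`, `objective`, `iterations`, `converged`.
#' @export
pcm_fit <- function(X, cfg = cluster_config(), init = NULL) {
  X <- as_feature_matrix(X)
  C <- cfg$C; eta <- cfg$eta
  B <- if (is.null(init)) init_centers(X, C, cfg$seed) else as_center_matrix(init, ncol(X))
  gamma <- cfg$gamma
  if (is.null(gamma)) {
    u0 <- fcm_memberships(dist2_matrix(X, B), cfg$m)
    gamma <- estimate_gamma(X, u0, B, cfg)
  }
  if (any(gamma <= 0)) stop("`gamma` must be positive")
  trace <- numeric(0); converged <- FALSE
  for (k in seq_len(cfg$max_iter)) {
    D2 <- dist2_matrix(X, B)
    tt <- 1 / (1 + sweep(D2, 2L, gamma, "/")^(1 / (eta - 1)))
    te <- tt^eta
    wsum <- colSums(te)
    wsum[wsum == 0] <- .Machine$double.xmin
    B <- (t(te) %*% X) / wsum
    D2 <- dist2_matrix(X, B)
    J <- sum(te * D2) + sum(gamma * colSums((1 - tt)^eta))
    trace <- c(trace, J)
    if (k > 1L && abs(trace[k] - trace[k - 1L]) < cfg$eps) {
      converged <- TRUE; break
    }
  }
  warn_coincident(B)
  structure(list(t = tt, centers = B, gamma = gamma, objective = trace,
                 iterations = length(trace), converged = converged),
            class = "pcm_fit")
}

#' Fuzzy-possibilistic c-means clustering
#'
#' FPCM combines FCM memberships (columns over clusters sum to 1 per
#' observation) with typicalities normalised over observations (each
#' cluster's typicalities sum to 1 across the data set). Centroids are
#' updated with `u^m + t^eta` weights. Serves as a baseline scheme in the
#' benchmark grid.
#'
#' @inheritParams fcm_fit
#' @return List of class `fpcm_fit`: `u`, `t`, `centers`, `objective`,
#'   `iterations`, `converged`.
#' @export
fpcm_fit <- function(X, cfg = cluster_config(), init = NULL) {
  X <- as_feature_matrix(X)
  C <- cfg$C; m <- cfg$m; eta <- cfg$eta
  B <- if (is.null(init)) init_centers(X, C, cfg$seed) else as_center_matrix(init, ncol(X))
  trace <- numeric(0); converged <- FALSE
  for (k in seq_len(cfg$max_iter)) {
    D2 <- dist2_matrix(X, B)
    u <- fcm_memberships(D2, m)
    # typicalities: normalised over observations within each cluster
    tt <- matrix(0, nrow(D2), C)
    for (i in seq_len(C)) {
      di <- D2[, i]
      if (any(di < 1e-300)) {
        z <- di < 1e-300
        tt[z, i] <- 1 / sum(z)
      } else {
        w <- di^(-1 / (eta - 1))
        tt[, i] <- w / sum(w)
      }
    }
    wt <- u^m + tt^eta
    wsum <- colSums(wt)
    wsum[wsum == 0] <- .Machine$double.xmin
    B <- (t(wt) %*% X) / wsum
    J <- sum((u^m + tt^eta) * dist2_matrix(X, B))
    trace <- c(trace, J)
    if (k > 1L && abs(trace[k] - trace[k - 1L]) < cfg$eps) {
      converged <- TRUE; break
    }
  }
  warn_coincident(B)
  structure(list(u = u, t = tt, centers = B, objective = trace,
                 iterations = length(trace), converged = converged),
            class = "fpcm_fit")
}

# ---- BCFCM ------------------------------------------------------------------

# Neighbour bookkeeping for image-structured data. Every masked voxel gets
# exactly R = 3^d - 1 neighbour slots; out-of-grid offsets are reflected and
# off-mask neighbours fall back to the voxel itself, so each row of `idx` has
# constant cardinality (keeps the closed-form centroid/bias updates exact).
build_neighbors <- function(shape, mask = NULL) {
  d <- length(shape)
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  flat_mask <- as.vector(mask)
  row_of <- integer(prod(shape))          # full-grid flat index -> mask row
  row_of[flat_mask] <- seq_len(sum(flat_mask))
  coords <- which(mask, arr.ind = TRUE)
  if (d == 2L) coords <- cbind(coords, 0L)[, 1:d, drop = FALSE]
  offs <- as.matrix(expand.grid(rep(list(-1:1), d)))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  R <- nrow(offs)
  N <- nrow(coords)
  idx <- matrix(0L, N, R)
  strides <- cumprod(c(1L, shape[-d]))
  for (s in seq_len(R)) {
    cc <- coords
    for (a in seq_len(d)) {
      v <- coords[, a] + offs[s, a]
      v <- ifelse(v < 1L, 2L - v, ifelse(v > shape[a], 2L * shape[a] - v, v))
      cc[, a] <- v
    }
    flat <- as.integer(1L + (cc - 1L) %*% strides)
    r <- ifelse(flat_mask[flat], row_of[flat], seq_len(N))
    idx[, s] <- r
  }
  list(idx = idx, R = R)
}

# neighbour-summed copy of a masked per-voxel matrix (N x C)
neighbor_sum <- function(W, nb) {
  out <- matrix(0, nrow(W), ncol(W))
  for (s in seq_len(nb$R)) out <- out + W[nb$idx[, s], , drop = FALSE]
  out
}

# transpose-incidence sum: for each voxel j, sum of W rows over all voxels j'
# that list j as a neighbour (with multiplicity)
neighbor_sum_t <- function(W, nb) {
  out <- matrix(0, nrow(W), ncol(W))
  for (s in seq_len(nb$R)) {
    agg <- rowsum(W, group = nb$idx[, s])
    out[as.integer(rownames(agg)), ] <- out[as.integer(rownames(agg)), ] + agg
  }
  out
}

# polynomial design matrix (total degree <= `degree`) on the masked voxel
# coordinates, each axis scaled to [-1, 1]
poly_basis <- function(shape, mask, degree = 3L) {
  coords <- which(mask, arr.ind = TRUE)
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1L)
  d <- length(shape)
  Z <- sapply(seq_len(d), function(a) {
    if (shape[a] == 1L) rep(0, nrow(coords)) else
      2 * (coords[, a] - 1) / (shape[a] - 1) - 1
  })
  Z <- matrix(Z, ncol = d)
  pows <- as.matrix(expand.grid(rep(list(0:degree), d)))
  pows <- pows[rowSums(pows) <= degree, , drop = FALSE]
  Phi <- matrix(1, nrow(Z), nrow(pows))
  for (k in seq_len(nrow(pows))) {
    for (a in seq_len(d)) {
      if (pows[k, a] > 0L) Phi[, k] <- Phi[, k] * Z[, a]^pows[k, a]
    }
  }
  Phi
}

#' BCFCM objective function
#'
#' The bias-corrected FCM objective: the classic fuzzy within-cluster
#' distance on bias-compensated intensities plus an `alpha`-weighted copy of
#' the same term averaged over each voxel's immediate neighbourhood,
#' \deqn{J = \sum_{i,j} u_{ij}^m \|x_j-\beta_j-b_i\|^2 + \frac{\alpha}{N_R}
#'   \sum_{i,j} u_{ij}^m \sum_{k \in N(j)} \|x_k-\beta_k-b_i\|^2.}
#' The neighbour term regularises towards piecewise-homogeneous labelings.
#'
#' @param img image-structured input ([image_volume()] or matrix/array).
#' @param u N x C fuzzy partition on masked voxels.
#' @param centers C x 1 centroid matrix (intensity features).
#' @param beta per-masked-voxel bias estimate.
#' @param cfg a [cluster_config()]; uses `m` and `alpha`.
#' @param neighbors optional precomputed [build_neighbors()] structure.
#' @return Scalar objective value (>= 0).
#' @export
bcfcm_objective <- function(img, u, centers, beta, cfg = cluster_config(),
                            neighbors = NULL) {
  if (!inherits(img, "image_volume") && is.null(dim(img))) {
    if (cfg$alpha > 0) stop("alpha > 0 requires image-structured input")
    img <- image_volume(matrix(img, ncol = 1L))
  }
  img <- as_image_volume(img)
  msk <- mask_of(img)
  x <- img$data[msk]
  nb <- neighbors %||% build_neighbors(dim(img$data), img$mask)
  b <- as.numeric(centers)
  y <- x - beta
  W <- outer(y, b, function(a, bb) (a - bb)^2)
  um <- u^cfg$m
  J_main <- sum(um * W)
  if (cfg$alpha > 0) {
    J_nb <- sum(um * neighbor_sum(W, nb)) * cfg$alpha / nb$R
  } else {
    J_nb <- 0
  }
  J_main + J_nb
}

#' Bias-corrected fuzzy c-means segmentation
#'
#' BCFCM augments FCM with (i) a per-voxel additive bias field \eqn{\beta_j}
#' compensating smooth intensity inhomogeneity and (ii) a neighbourhood
#' regularisation term weighted by `alpha` (see [bcfcm_objective()]). Each
#' iteration updates memberships, centroids and the bias field in turn; every
#' update is the exact minimiser of the objective for its block, so the
#' returned objective trace is non-increasing. Iteration stops when
#' `|J(k+1) - J(k)| < eps`.
#'
#' Two bias-field models are available. The default (`bias_model = "poly"`)
#' constrains \eqn{\beta} to a low-order polynomial in the voxel
#' coordinates — the natural model for a smooth scanner inhomogeneity — and
#' updates its coefficients by exact weighted least squares, which keeps the
#' descent monotone while preventing the field from absorbing genuine tissue
#' contrast. `bias_model = "voxel"` leaves \eqn{\beta_j} free per voxel and
#' applies the exact per-voxel minimiser, which with `alpha = 0` reduces to
#' the familiar \eqn{\beta_j = x_j - \sum_i u_{ij}^m b_i / \sum_i u_{ij}^m};
#' an unconstrained field fits any structure, so this variant is mainly of
#' didactic and diagnostic interest.
#'
#' @param img an [image_volume()] or numeric matrix/array of intensities.
#' @param cfg a [cluster_config()]; `alpha` controls the neighbour term.
#' @param init initial centroids (C values) or `NULL` for a seeded draw.
#' @param bias if `FALSE` the bias field is held at zero during iteration
#'   (plain neighbourhood-regularised FCM); a one-shot estimate from the
#'   converged partition is still returned in `beta_post`.
#' @param bias_model `"poly"` (smooth polynomial field, default) or
#'   `"voxel"` (free per-voxel field).
#' @param bias_degree polynomial total degree for `bias_model = "poly"`.
#' @return List of class `bcfcm_fit`: `u`, `centers` (sorted as supplied),
#'   `beta` (masked vector), `beta_image` (full-grid array, 0 off-mask),
#'   `beta_post`, `objective`, `iterations`, `converged`, `neighbors`.
#' @export
bcfcm_fit <- function(img, cfg = cluster_config(), init = NULL, bias = TRUE,
                      bias_model = c("poly", "voxel"),
                      bias_degree = cfg$bias_degree %||% 1L) {
  img <- as_image_volume(img)
  bias_model <- match.arg(bias_model)
  if (cfg$eps <= 0) stop("`eps` must be positive")
  msk <- mask_of(img)
  x <- img$data[msk]
  N <- length(x)
  C <- cfg$C; m <- cfg$m; alpha <- cfg$alpha
  if (N < C) stop("N must be >= C")
  nb <- build_neighbors(dim(img$data), img$mask)
  Phi <- if (bias && bias_model == "poly") {
    poly_basis(dim(img$data), msk, bias_degree)
  } else NULL
  X1 <- matrix(x, ncol = 1L)
  B <- if (is.null(init)) init_centers(X1, C, cfg$seed) else as_center_matrix(init, 1L)
  beta <- numeric(N)
  trace <- numeric(0); converged <- FALSE
  for (k in seq_len(cfg$max_iter)) {
    y <- x - beta
    W <- outer(y, as.numeric(B), function(a, bb) (a - bb)^2)
    D <- if (alpha > 0) W + (alpha / nb$R) * neighbor_sum(W, nb) else W
    u <- fcm_memberships(D, m)
    um <- u^m
    # centroid update
    ynb <- if (alpha > 0) {
      rowSums_nb <- numeric(N)
      for (s in seq_len(nb$R)) rowSums_nb <- rowSums_nb + y[nb$idx[, s]]
      rowSums_nb
    } else NULL
    num <- if (alpha > 0) y + (alpha / nb$R) * ynb else y
    wsum <- colSums(um)
    wsum[wsum == 0] <- .Machine$double.xmin
    B <- matrix(colSums(um * num) / ((1 + alpha) * wsum), ncol = 1L)
    # bias update: exact block minimiser of the objective over the chosen
    # field class (J is quadratic and separable in beta with per-voxel
    # curvature sum_i c_ij, so the constrained update is a weighted LS fit)
    if (bias) {
      cmat <- if (alpha > 0) um + (alpha / nb$R) * neighbor_sum_t(um, nb) else um
      wts <- rowSums(cmat)
      resid <- x - as.numeric(cmat %*% B) / wts
      if (is.null(Phi)) {
        beta <- resid
      } else {
        wls <- stats::lm.wfit(Phi, resid, w = wts)
        beta <- as.numeric(Phi %*% ifelse(is.na(wls$coefficients), 0,
                                          wls$coefficients))
      }
    }
    # objective with the freshly updated state
    y <- x - beta
    W <- outer(y, as.numeric(B), function(a, bb) (a - bb)^2)
    J <- sum(u^m * W) +
      if (alpha > 0) (alpha / nb$R) * sum(u^m * neighbor_sum(W, nb)) else 0
    trace <- c(trace, J)
    if (k > 1L && abs(trace[k] - trace[k - 1L]) < cfg$eps) {
      converged <- TRUE; break
    }
  }
  warn_coincident(B)
  um <- u^m
  beta_post <- x - as.numeric(um %*% B) / rowSums(um)
  beta_image <- array(0, dim = dim(img$data))
  beta_image[msk] <- beta
  structure(list(u = u, centers = B, beta = beta, beta_image = beta_image,
                 beta_post = beta_post, objective = trace,
                 iterations = length(trace), converged = converged,
                 neighbors = nb, mask = msk),
            class = "bcfcm_fit")
}

#' PFCM objective function
#'
#' \deqn{J = \sum_{i,j} (a u_{ij}^m + b t_{ij}^\eta) \|x_j-b_i\|^2 +
#'   \sum_i \gamma_i \sum_j (1-t_{ij})^\eta.}
#'
#' @param X feature matrix, vector or [image_volume()].
#' @param u N x C fuzzy partition.
#' @param t N x C typicality matrix.
#' @param centers C x d centroid matrix.
#' @param gamma per-cluster possibilistic penalties (> 0).
#' @param cfg a [cluster_config()]; uses `m`, `eta`, `a`, `b`.
#' @return Scalar objective value.
#' @export
pfcm_objective <- function(X, u, t, centers, gamma, cfg = cluster_config()) {
  X <- as_feature_matrix(X)
  B <- as_center_matrix(centers, ncol(X))
  D2 <- dist2_matrix(X, B)
  sum((cfg$a * u^cfg$m + cfg$b * t^cfg$eta) * D2) +
    sum(gamma * colSums((1 - t)^cfg$eta))
}

#' Possibilistic fuzzy c-means clustering
#'
#' PFCM produces three outputs simultaneously: a column-stochastic fuzzy
#' partition `u` (relative memberships), a typicality matrix `t` (absolute
#' degrees of compatibility, robust to noise and partial-volume mixing), and
#' the centroids `b`. Updates alternate
#' \eqn{u_{ij} \propto d_{ij}^{-2/(m-1)}},
#' \eqn{t_{ij} = 1/(1 + (b\,d_{ij}^2/\gamma_i)^{1/(\eta-1)})} and the
#' `a u^m + b t^eta` weighted centroid mean until the objective changes by
#' less than `eps`. An initial partition must be supplied — in the full
#' pipeline it comes from the BCFCM + genetic-algorithm stage.
#'
#' @param X feature matrix, vector or [image_volume()].
#' @param cfg a [cluster_config()].
#' @param init list with elements `centers` (C x d) and optionally `u`
#'   (used for gamma estimation), e.g. a [bcfcm_fit()] or [ga_evolve()]
#'   result.
#' @return List of class `pfcm_fit`: `u`, `t`, `centers`, `gamma`,
#'   `objective`, `iterations`, `converged`.
#' @export
pfcm_fit <- function(X, cfg = cluster_config(), init) {
  X <- as_feature_matrix(X)
  if (missing(init) || is.null(init)) stop("`init` is required (BCFCM/GA output)")
  if (is.list(init) && !is.null(init$centers)) {
    B <- as_center_matrix(init$centers, ncol(X))
    u0 <- init$u
  } else {
    B <- as_center_matrix(init, ncol(X))
    u0 <- NULL
  }
  C <- cfg$C; m <- cfg$m; eta <- cfg$eta; a <- cfg$a; b <- cfg$b
  if (nrow(B) != C) stop("init centers must have C rows")
  gamma <- cfg$gamma
  if (is.null(gamma)) {
    if (is.null(u0)) u0 <- fcm_memberships(dist2_matrix(X, B), m)
    gamma <- estimate_gamma(X, u0, B, cfg)
  }
  if (any(gamma <= 0)) stop("`gamma` must be positive")
  trace <- numeric(0); converged <- FALSE
  for (k in seq_len(cfg$max_iter)) {
    D2 <- dist2_matrix(X, B)
    u <- fcm_memberships(D2, m)
    tt <- 1 / (1 + sweep(b * D2, 2L, gamma, "/")^(1 / (eta - 1)))
    wt <- a * u^m + b * tt^eta
    wsum <- colSums(wt)
    wsum[wsum == 0] <- .Machine$double.xmin
    B <- (t(wt) %*% X) / wsum
    J <- pfcm_objective(X, u, tt, B, gamma, cfg)
    trace <- c(trace, J)
    if (k > 1L && abs(trace[k] - trace[k - 1L]) < cfg$eps) {
      converged <- TRUE; break
    }
  }
  warn_coincident(B)
  structure(list(u = u, t = tt, centers = B, gamma = gamma,
                 objective = trace, iterations = length(trace),
                 converged = converged),
            class = "pfcm_fit")
}
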