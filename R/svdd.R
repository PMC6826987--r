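#' SVDD configuration
#'
#' @param C penalty in `(0, 1]` trading hypersphere volume against training
#'   errors; feasibility of the equality constraint requires `C >= 1/N`.
#' @param sigma RBF kernel width (> 0); 0 selects the linear kernel.
#' @param kernel `"rbf"` or `"linear"`.
#' @param tol KKT / solver tolerance.
#' @param k_clusters divide-and-conquer cluster count (1 = plain training).
#' @param max_iter solver iteration cap.
#' @param seed RNG seed (used by the divide-and-conquer k-means).
#' @return An object of class `svdd_config`.
#' @export
svdd_config <- function(C = 0.1, sigma = 1, kernel = c("rbf", "linear"),
                        tol = 1e-6, k_clusters = 1L, max_iter = 100000L,
                        seed = NULL) {
  kernel <- match.arg(kernel)
  stopifnot_scalar(C, "C", lower = 0, upper = 1, strict_lower = TRUE)
  stopifnot_scalar(sigma, "sigma", lower = 0)
  if (sigma == 0) kernel <- "linear"   # convention: zero width = linear kernel
  if (kernel == "rbf" && sigma <= 0) stop("`sigma` must be > 0 for rbf")
  structure(list(C = C, sigma = sigma, kernel = kernel, tol = tol,
                 k_clusters = as.integer(k_clusters),
                 max_iter = as.integer(max_iter), seed = seed),
            class = "svdd_config")
}

kernel_matrix <- function(X, Y = NULL, kernel = "rbf", sigma = 1) {
  X <- as.matrix(X)
  Y <- if (is.null(Y)) X else as.matrix(Y)
  if (kernel == "linear") return(X %*% t(Y))
  xx <- rowSums(X * X); yy <- rowSums(Y * Y)
  d2 <- outer(xx, yy, `+`) - 2 * X %*% t(Y)
  d2[d2 < 0] <- 0
  exp(-d2 / sigma^2)
}

kernel_diag <- function(X, kernel = "rbf") {
  if (kernel == "linear") rowSums(as.matrix(X)^2) else rep(1, nrow(as.matrix(X)))
}

#' Train a support vector data description
#'
#' Fits the minimum-volume hypersphere enclosing the target data in kernel
#' space by solving the dual
#' \deqn{\max_\alpha \sum_i \alpha_i K(x_i,x_i) - \sum_{i,j}
#'   \alpha_i\alpha_j K(x_i,x_j), \quad \sum_i \alpha_i = 1, \;
#'   0 \le \alpha_i \le C,}
#' with a deterministic SMO-style pairwise coordinate ascent: at each step the
#' pair with the largest KKT violation exchanges mass along the equality
#' constraint. Points with \eqn{0 < \alpha_i < C} lie on the sphere boundary
#' and define the squared radius \eqn{R^2} (their mean squared distance to
#' the centre); bounded points (\eqn{\alpha_i = C}) may fall outside.
#'
#' @param X training feature matrix (targets only), N x d.
#' @param cfg an [svdd_config()]; requires `C >= 1/N`.
#' @return An object of class `svdd_model`: `alphas`, `sv_index`, `X_sv`,
#'   `alpha_sv`, `R2`, `quad` (cached \eqn{\alpha' K \alpha}), `kernel`,
#'   `sigma`, `C`, `n_train`, `dual_objective`.
#' @examples
#' X <- matrix(rnorm(60), ncol = 2)
#' m <- svdd_train(X, svdd_config(C = 0.2, sigma = 2))
#' sum(m$alphas)
#' @export
svdd_train <- function(X, cfg = svdd_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  N <- nrow(X)
  if (N < 1L) stop("need at least one training point")
  if (cfg$C < 1 / N - 1e-12) {
    stop(sprintf("C = %g < 1/N = %g: equality constraint infeasible", cfg$C, 1 / N))
  }
  K <- kernel_matrix(X, kernel = cfg$kernel, sigma = cfg$sigma)
  dK <- diag(K)
  alpha <- rep(1 / N, N)
  Ka <- as.numeric(K %*% alpha)
  tol <- cfg$tol
  if (N > 1L) {
    for (it in seq_len(cfg$max_iter)) {
      g <- dK - 2 * Ka                     # dual gradient
      up <- alpha < cfg$C - 1e-14          # can receive mass
      dn <- alpha > 1e-14                  # can give mass
      i <- which(up)[which.max(g[up])]
      j <- which(dn)[which.min(g[dn])]
      if (length(i) == 0L || length(j) == 0L || g[i] - g[j] <= tol) break
      eta2 <- dK[i] - 2 * K[i, j] + dK[j]
      hi <- min(cfg$C - alpha[i], alpha[j])
      delta <- if (eta2 > 1e-14) min(hi, (g[i] - g[j]) / (2 * eta2)) else hi
      if (delta <= 0) break
      alpha[i] <- alpha[i] + delta
      alpha[j] <- alpha[j] - delta
      Ka <- Ka + delta * (K[, i] - K[, j])
    }
  }
  quad <- sum(alpha * Ka)
  dist2 <- dK - 2 * Ka + quad
  sv_tol <- max(1e-8, tol)
  sv <- which(alpha > sv_tol)
  unbounded <- which(alpha > sv_tol & alpha < cfg$C - sv_tol)
  R2 <- if (length(unbounded) > 0L) mean(dist2[unbounded]) else
    if (length(sv) > 0L) max(dist2[sv]) else 0
  R2 <- max(R2, 0)
  structure(list(alphas = alpha, sv_index = sv, X_sv = X[sv, , drop = FALSE],
                 alpha_sv = alpha[sv], R2 = R2, quad = quad,
                 kernel = cfg$kernel, sigma = cfg$sigma, C = cfg$C,
                 tol = tol, n_train = N,
                 dual_objective = sum(alpha * dK) - quad,
                 train_dist2 = dist2),
            class = "svdd_model")
}

#' @export
print.svdd_model <- function(x, ...) {
  cat(sprintf("<svdd_model> %s kernel%s, C = %g, %d/%d SVs, R^2 = %.4g\n",
              x$kernel,
              if (x$kernel == "rbf") sprintf(" (sigma = %g)", x$sigma) else "",
              x$C, length(x$sv_index), x$n_train, x$R2))
  invisible(x)
}

#' Squared distance to the SVDD centre
#'
#' \eqn{\|z-a\|^2 = K(z,z) - 2\sum_i \alpha_i K(z,x_i) +
#' \sum_{i,j}\alpha_i\alpha_j K(x_i,x_j)} (the last term is cached in the
#' model).
#'
#' @param model an [svdd_train()] result.
#' @param z feature vector or matrix of query points (rows).
#' @return Numeric vector of squared distances.
#' @export
svdd_distance2 <- function(model, z) {
  Z <- if (is.null(dim(z))) matrix(z, nrow = 1L) else as.matrix(z)
  Kz <- kernel_matrix(Z, model$X_sv, kernel = model$kernel, sigma = model$sigma)
  kernel_diag(Z, model$kernel) - 2 * as.numeric(Kz %*% model$alpha_sv) + model$quad
}

#' SVDD accept/reject decision
#'
#' Accepts a query point when its squared distance to the sphere centre is at
#' most \eqn{R^2} (boundary points are accepted); a small numerical slack of
#' `tol * (1 + R^2)` absorbs solver round-off at the KKT tolerance.
#'
#' @param model an [svdd_train()] result.
#' @param z query vector or matrix.
#' @return Factor with levels `accept`, `reject`.
#' @export
svdd_predict <- function(model, z) {
  d2 <- svdd_distance2(model, z)
  slack <- (model$tol %||% 1e-6) * (1 + model$R2)
  factor(ifelse(d2 <= model$R2 + slack, "accept", "reject"),
         levels = c("accept", "reject"))
}

#' Continuous SVDD outlier score
#'
#' `distance^2 - R^2`: negative inside the sphere, positive outside. Used as
#' the continuous score for ROC construction.
#'
#' @inheritParams svdd_predict
#' @return Numeric score vector.
#' @export
svdd_score <- function(model, z) {
  svdd_distance2(model, z) - model$R2
}

#' Grid search over (sigma, C)
#'
#' Exhaustive evaluation of every kernel-width/penalty combination by k-fold
#' one-class cross-validation on the target set: each candidate is scored by
#' the mean of the held-out target accept rate and (when outliers are
#' supplied) the outlier reject rate. Ties are broken towards smaller `C`,
#' then smaller `sigma`. Deterministic under `seed`.
#'
#' @param X_target target training matrix.
#' @param X_outlier optional outlier matrix used for reject-rate scoring.
#' @param sigmas,Cs candidate values (a `sigma` of 0 selects the linear
#'   kernel).
#' @param n_folds folds over the target set.
#' @param seed RNG seed for the fold assignment.
#' @return List: `best` (list with `sigma`, `C`, `score`) and `table`
#'   (data.frame of all candidates with scores).
#' @export
svdd_grid_search <- function(X_target, X_outlier = NULL,
                             sigmas = c(0.5, 1, 2, 4),
                             Cs = c(0.05, 0.1, 0.25, 0.5, 1),
                             n_folds = 5L, seed = 1L) {
  X_target <- as.matrix(X_target)
  N <- nrow(X_target)
  n_folds <- min(n_folds, N)
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), N)))
  grid <- expand.grid(sigma = sigmas, C = Cs, KEEP.OUT.ATTRS = FALSE)
  grid$score <- NA_real_
  for (r in seq_len(nrow(grid))) {
    scores <- numeric(0)
    feasible <- TRUE
    for (f in seq_len(n_folds)) {
      tr <- X_target[folds != f, , drop = FALSE]
      te <- X_target[folds == f, , drop = FALSE]
      if (nrow(tr) == 0L || grid$C[r] < 1 / nrow(tr)) {
        feasible <- FALSE
        break
      }
      cfg <- svdd_config(C = grid$C[r], sigma = grid$sigma[r])
      mod <- svdd_train(tr, cfg)
      acc_t <- mean(svdd_predict(mod, te) == "accept")
      if (!is.null(X_outlier) && nrow(X_outlier) > 0L) {
        rej_o <- mean(svdd_predict(mod, X_outlier) == "reject")
        scores <- c(scores, (acc_t + rej_o) / 2)
      } else {
        scores <- c(scores, acc_t)
      }
    }
    if (feasible) grid$score[r] <- mean(scores)
  }
  ok <- which(!is.na(grid$score))
  if (length(ok) == 0L) stop("no feasible (sigma, C) candidate")
  # best score; ties towards smaller C then smaller sigma
  ord <- ok[order(-grid$score[ok], grid$C[ok], grid$sigma[ok])]
  best <- grid[ord[1L], ]
  list(best = list(sigma = best$sigma, C = best$C, score = best$score),
       table = grid)
}

#' Divide-and-conquer SVDD training
#'
#' Scales SVDD to larger target sets: the data are partitioned into `k`
#' clusters with (seeded, multi-start) k-means, a local SVDD expert is
#' trained on each cluster, and a final SVDD is retrained on the union of the
#' local support vectors only. With a QP cost of \eqn{O(N^3)} this reduces
#' the work to roughly \eqn{k\,O((N/k)^3)} plus a small retraining term; the
#' estimate is reported in the returned model. Subproblems whose size makes
#' the supplied `C` infeasible use `max(C, 1/n_cluster)` locally.
#'
#' @param X target training matrix.
#' @param cfg an [svdd_config()] with `k_clusters` set (`1` falls back to
#'   plain [svdd_train()]).
#' @return An `svdd_model` fitted on the union of local support vectors, with
#'   an extra `dac` element: `k`, `cluster_sizes`, `local_sv_counts`,
#'   `n_final_train`, `work_plain`, `work_dac`, and the row indices
#'   `sv_rows` of the final training subset in `X`.
#' @export
svdd_dac_train <- function(X, cfg = svdd_config()) {
  X <- as.matrix(X)
  N <- nrow(X)
  k <- cfg$k_clusters
  if (k > N) stop("`k_clusters` must be <= N")
  if (k <= 1L) return(svdd_train(X, cfg))
  km <- with_seed(cfg$seed %||% 1L,
                  stats::kmeans(X, centers = k, nstart = 10L, iter.max = 50L))
  cl <- km$cluster
  sv_rows <- integer(0)
  local_counts <- integer(0)
  for (g in sort(unique(cl))) {
    rows <- which(cl == g)
    cfg_g <- cfg
    cfg_g$C <- min(1, max(cfg$C, 1 / length(rows)))
    mod_g <- svdd_train(X[rows, , drop = FALSE], cfg_g)
    sv_rows <- c(sv_rows, rows[mod_g$sv_index])
    local_counts <- c(local_counts, length(mod_g$sv_index))
  }
  sv_rows <- sort(unique(sv_rows))
  cfg_f <- cfg
  cfg_f$C <- min(1, max(cfg$C, 1 / length(sv_rows)))
  model <- svdd_train(X[sv_rows, , drop = FALSE], cfg_f)
  abar <- mean(local_counts)
  model$dac <- list(k = k, cluster_sizes = as.integer(table(cl)),
                    local_sv_counts = local_counts,
                    n_final_train = length(sv_rows),
                    sv_rows = sv_rows,
                    work_plain = N^3,
                    work_dac = k * N + k * (N / k)^3 + (abar * k)^3)
  model
}
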