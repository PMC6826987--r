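# Shared fixtures and independent brute-force oracles used across the suite.

# two well-separated Gaussian blobs in d dimensions
make_blobs <- function(n_per = 25, centers = list(c(0, 0), c(10, 10)),
                       sd = 0.3, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(centers, function(ctr) {
    matrix(rnorm(n_per * length(ctr), mean = rep(ctr, each = n_per), sd = sd),
           n_per, length(ctr))
  }))
}

# per-voxel label array from a modeling result's possibility maps
labels_from_maps <- function(maps, mask) {
  lab <- array(0L, dim = dim(maps$csf))
  m <- as.vector(mask)
  flat <- cbind(as.vector(maps$csf), as.vector(maps$gm), as.vector(maps$wm))
  lab[m] <- max.col(flat[m, , drop = FALSE], ties.method = "first")
  lab
}

# brute-force single-cluster PCM fixed point in 1D (typicality <-> centroid)
bf_pcm_1d <- function(x, gamma, eta, b_init, iters = 500) {
  b <- b_init
  for (k in seq_len(iters)) {
    tt <- 1 / (1 + ((x - b)^2 / gamma)^(1 / (eta - 1)))
    b <- sum(tt^eta * x) / sum(tt^eta)
  }
  list(t = tt, b = b)
}

# brute-force FPCM fixed point on a tiny 1D instance
bf_fpcm_1d <- function(x, C, m, eta, b_init, iters = 500) {
  b <- b_init
  N <- length(x)
  for (k in seq_len(iters)) {
    D2 <- outer(x, b, function(a, bb) (a - bb)^2)
    u <- t(apply(D2, 1, function(dr) {
      w <- dr^(-1 / (m - 1)); w / sum(w)
    }))
    tt <- apply(D2, 2, function(dc) {
      w <- dc^(-1 / (eta - 1)); w / sum(w)
    })
    wt <- u^m + tt^eta
    b <- colSums(wt * x) / colSums(wt)
  }
  list(u = u, t = tt, b = b)
}

# pairwise-concordance AUC (Mann-Whitney with ties = 1/2)
bf_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# random feasible points for the SVDD dual (sum alpha = 1, 0 <= alpha <= C)
bf_svdd_random_search <- function(K, C, n_draws = 2000, seed = 1) {
  set.seed(seed)
  N <- nrow(K)
  best <- -Inf
  for (r in seq_len(n_draws)) {
    a <- rexp(N)
    a <- a / sum(a)
    if (any(a > C)) next
    obj <- sum(a * diag(K)) - as.numeric(t(a) %*% K %*% a)
    best <- max(best, obj)
  }
  best
}

# direct 3x3 hybrid median at one pixel of a matrix with reflection padding
bf_hybrid_median_pixel <- function(x, i, j) {
  n <- nrow(x); m <- ncol(x)
  refl <- function(v, k) ifelse(v < 1, 2 - v, ifelse(v > k, 2 * k - v, v))
  at <- function(di, dj) x[refl(i + di, n), refl(j + dj, m)]
  plus <- c(at(-1, 0), at(1, 0), at(0, -1), at(0, 1), at(0, 0))
  diag_ <- c(at(-1, -1), at(-1, 1), at(1, -1), at(1, 1), at(0, 0))
  median(c(median(plus), median(diag_), at(0, 0)))
}
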