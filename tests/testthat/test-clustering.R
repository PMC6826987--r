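cfg_tight <- cluster_config(C = 2, eps = 1e-10, max_iter = 500)

test_that("FCM recovers separated cloud means and matches an external oracle", {
  X <- make_blobs(n_per = 30, centers = list(c(0, 0), c(100, 100)), sd = 0.3)
  fit <- fcm_fit(X, cfg_tight, init = rbind(c(5, 5), c(95, 95)))
  ord <- order(fit$centers[, 1])
  expect_equal(fit$centers[ord, ], rbind(colMeans(X[1:30, ]), colMeans(X[31:60, ])),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(fit$u[1:30, ord[1]] > 0.99))
  expect_true(all(fit$u[31:60, ord[2]] > 0.99))
  # cross-check against an independent implementation
  skip_if_not_installed("e1071")
  ext <- e1071::cmeans(X, centers = fit$centers, m = 2, iter.max = 300)
  expect_equal(ext$centers, fit$centers, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("FCM zero-distance and equidistance conventions hold", {
  X <- matrix(c(0, 5, 10), ncol = 1)
  B <- matrix(c(0, 10), ncol = 1)
  u <- fuzzyfuse:::fcm_memberships(fuzzyfuse:::dist2_matrix(X, B), m = 2)
  expect_equal(u[1, ], c(1, 0))          # exactly on centroid 1
  expect_equal(u[3, ], c(0, 1))
  expect_equal(u[2, ], c(0.5, 0.5))      # equidistant
})

test_that("FCM memberships are column-stochastic at every iteration", {
  X <- make_blobs(n_per = 20, sd = 1, seed = 3)
  fit <- fcm_fit(X, cluster_config(C = 3, eps = 1e-9, seed = 1))
  expect_true(all(abs(rowSums(fit$u) - 1) < 1e-12))
})

test_that("coincident data with C >= 2 triggers the degeneracy warning", {
  X <- matrix(1, 10, 1)
  expect_warning(fcm_fit(X, cluster_config(C = 2, seed = 1)), "coincident")
})

test_that("PCM typicality formula and fixed point match the brute-force oracle", {
  # d2 = gamma, eta = 2 -> t = 0.5
  cfg <- cluster_config(C = 1, eta = 2, gamma = 1, eps = 1e-12)
  fit <- pcm_fit(matrix(c(0, 2), ncol = 1), cfg, init = matrix(1))
  expect_equal(as.numeric(fit$t), c(0.5, 0.5), tolerance = 1e-9)
  # d = 0 -> t = 1
  fit0 <- pcm_fit(matrix(c(0, 0), ncol = 1), cfg, init = matrix(0))
  expect_equal(as.numeric(fit0$t), c(1, 1))
  # 1D two-point instance against an independent alternating-update oracle
  x <- c(0, 10)
  oracle <- bf_pcm_1d(x, gamma = 1, eta = 2, b_init = 2)
  fit2 <- pcm_fit(matrix(x, ncol = 1),
                  cluster_config(C = 1, eta = 2, gamma = 1, eps = 1e-14,
                                 max_iter = 1000),
                  init = matrix(2))
  expect_equal(as.numeric(fit2$centers), oracle$b, tolerance = 1e-6)
  expect_equal(as.numeric(fit2$t), oracle$t, tolerance = 1e-6)
})

test_that("FPCM constraints hold and a small instance matches its oracle", {
  # symmetric two-point, two-cluster input: identity assignment
  X <- matrix(c(0, 10), ncol = 1)
  fit <- fpcm_fit(X, cluster_config(C = 2, eta = 2, eps = 1e-12),
                  init = matrix(c(1, 9), ncol = 1))
  expect_equal(diag(fit$u), c(1, 1), tolerance = 1e-6)
  expect_equal(colSums(fit$t), c(1, 1), tolerance = 1e-12)
  # 4-point 1D instance vs brute-force fixed point
  x <- c(0, 1, 7, 9)
  oracle <- bf_fpcm_1d(x, C = 2, m = 2, eta = 2, b_init = c(0.9, 8.2))
  fit2 <- fpcm_fit(matrix(x, ncol = 1),
                   cluster_config(C = 2, m = 2, eta = 2, eps = 1e-14,
                                  max_iter = 2000),
                   init = matrix(c(0.9, 8.2), ncol = 1))
  expect_equal(as.numeric(fit2$centers), oracle$b, tolerance = 1e-5)
  expect_equal(fit2$u, oracle$u, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("gamma estimation follows the weighted-spread formula", {
  # uniform memberships, two symmetric points at distance 1 -> gamma = 1
  X <- matrix(c(-1, 1), ncol = 1)
  u <- matrix(1, 2, 1)
  g <- estimate_gamma(X, u, matrix(0), cluster_config(C = 1))
  expect_equal(as.numeric(g), 1)
  # scaling X by s scales gamma by s^2
  g2 <- estimate_gamma(3 * X, u, matrix(0), cluster_config(C = 1))
  expect_equal(as.numeric(g2), 9)
  # all points at the centroid is degenerate
  expect_warning(estimate_gamma(matrix(c(0, 0), ncol = 1), u, matrix(0),
                                cluster_config(C = 1)), "degenerate")
})

test_that("BCFCM objective reduces to FCM and matches hand expansion", {
  set.seed(2)
  img <- image_volume(matrix(runif(16), 4, 4))
  x <- as.vector(img$data)
  u <- matrix(runif(32), 16, 2); u <- u / rowSums(u)
  B <- matrix(c(0.3, 0.7), ncol = 1)
  cfg0 <- cluster_config(C = 2, alpha = 0)
  J <- bcfcm_objective(img, u, B, beta = numeric(16), cfg0)
  expect_equal(J, sum(u^2 * fuzzyfuse:::dist2_matrix(matrix(x), B)))
  # all points at a single centroid, beta = 0 -> J = 0
  img1 <- image_volume(matrix(0.4, 3, 3))
  expect_equal(bcfcm_objective(img1, matrix(1, 9, 1), matrix(0.4),
                               numeric(9), cluster_config(C = 1, alpha = 0.5)),
               0)
  # 2x2 image, C = 1, hand-set U and beta: term-by-term expansion
  img2 <- image_volume(matrix(c(1, 2, 3, 4), 2, 2))
  beta <- c(0.1, -0.2, 0.3, 0)
  uu <- matrix(c(0.9, 0.8, 0.7, 0.6), 4, 1)
  b1 <- 2.2
  cfg1 <- cluster_config(C = 1, alpha = 0.6, m = 2)
  nb <- fuzzyfuse:::build_neighbors(c(2L, 2L), NULL)
  y <- c(1, 2, 3, 4) - beta
  w <- (y - b1)^2
  J_hand <- sum(uu^2 * w) +
    (0.6 / nb$R) * sum(uu^2 * sapply(seq_len(4), function(j) {
      sum(w[nb$idx[j, ]])
    }))
  expect_equal(bcfcm_objective(img2, uu, matrix(b1), beta, cfg1), J_hand)
  # alpha > 0 demands image structure
  expect_error(bcfcm_objective(1:5, matrix(1, 5, 1), matrix(1), numeric(5),
                               cluster_config(C = 1, alpha = 0.5)),
               "image-structured")
})

test_that("BCFCM with alpha = 0 and frozen bias reproduces FCM exactly", {
  set.seed(6)
  img <- image_volume(matrix(runif(64), 8, 8))
  X <- matrix(as.vector(img$data), ncol = 1)
  init <- matrix(c(0.25, 0.75), ncol = 1)
  cfg <- cluster_config(C = 2, alpha = 0, eps = 1e-12, max_iter = 100)
  bc <- bcfcm_fit(img, cfg, init = init, bias = FALSE)
  fc <- fcm_fit(X, cfg, init = init)
  expect_equal(bc$u, fc$u, tolerance = 1e-10)
  expect_equal(as.numeric(bc$centers), as.numeric(fc$centers), tolerance = 1e-10)
  expect_true(all(bc$beta == 0))
  # beta_post is the one-shot estimate x - sum(u^m b)/sum(u^m)
  um <- bc$u^2
  expect_equal(bc$beta_post,
               as.vector(X) - as.numeric(um %*% bc$centers) / rowSums(um))
})

test_that("single-cluster BCFCM voxel-field identity: beta = x - b", {
  img <- image_volume(matrix(c(1, 2, 3, 4, 5, 6), 2, 3))
  cfg <- cluster_config(C = 1, alpha = 0, eps = 1e-12, max_iter = 5)
  fit <- bcfcm_fit(img, cfg, init = matrix(3.5), bias_model = "voxel")
  # with C = 1, u == 1 and Eq-style update gives beta_j = x_j - b exactly
  expect_equal(fit$beta, as.vector(img$data) - as.numeric(fit$centers))
})

test_that("BCFCM recovers a smooth bias field on spatially rough tissue", {
  # stripes give the tissue structure high spatial frequency, so the smooth
  # polynomial field is identifiable
  set.seed(9)
  n <- 24
  stripes <- matrix(rep(c(0.2, 0.5, 0.8), each = 2, length.out = n), n, n)
  xg <- matrix(rep(seq(-1, 1, length.out = n), n), n, n)
  truebias <- 0.15 * (0.8 * xg + 0.5 * t(xg) + 0.6 * xg * t(xg))
  img <- image_volume(stripes + truebias + matrix(rnorm(n * n, 0, 0.02), n, n))
  fit <- bcfcm_fit(img, cluster_config(C = 3, alpha = 0.3, eps = 1e-8,
                                       max_iter = 300, seed = 1),
                   bias_degree = 3)
  expect_gt(cor(fit$beta, as.vector(truebias)), 0.9)
  expect_lt(max(abs(sort(as.numeric(fit$centers)) - c(0.2, 0.5, 0.8))), 0.05)
})

test_that("PFCM membership/typicality updates match direct evaluation", {
  # 1D x = 1, centroids {0, 3}, m = 2 -> u_1 = 0.8
  u <- fuzzyfuse:::fcm_memberships(
    fuzzyfuse:::dist2_matrix(matrix(1), matrix(c(0, 3), ncol = 1)), m = 2)
  expect_equal(u[1, 1], 0.8)
  # equidistant point gets uniform memberships
  u3 <- fuzzyfuse:::fcm_memberships(matrix(c(4, 4, 4), 1, 3), m = 2)
  expect_equal(as.numeric(u3), rep(1 / 3, 3))
  # b * d2 / gamma = 1, eta = 2 -> t = 0.5
  cfg <- cluster_config(C = 1, eta = 2, b = 1, gamma = 4, eps = 1e-12,
                        max_iter = 1)
  fit <- pfcm_fit(matrix(c(-2, 2), ncol = 1), cfg, init = list(centers = matrix(0)))
  expect_equal(as.numeric(fit$t), c(0.5, 0.5))
})

test_that("PFCM objective matches brute-force summation on a tiny instance", {
  X <- matrix(c(0, 1, 3), ncol = 1)
  u <- matrix(c(0.8, 0.5, 0.1, 0.2, 0.5, 0.9), 3, 2)
  tt <- matrix(c(0.7, 0.4, 0.2, 0.3, 0.5, 0.8), 3, 2)
  B <- matrix(c(0.5, 2.5), ncol = 1)
  gamma <- c(0.6, 1.2)
  cfg <- cluster_config(C = 2, m = 2, eta = 3, a = 1.5, b = 2)
  J_hand <- 0
  for (i in 1:2) for (j in 1:3) {
    J_hand <- J_hand + (1.5 * u[j, i]^2 + 2 * tt[j, i]^3) * (X[j] - B[i])^2
  }
  J_hand <- J_hand + sum(gamma * colSums((1 - tt)^3))
  expect_equal(pfcm_objective(X, u, tt, B, gamma, cfg), J_hand)
  # t == 1 with all points on the centroid -> J = 0
  expect_equal(pfcm_objective(matrix(c(2, 2)), matrix(1, 2, 1),
                              matrix(1, 2, 1), matrix(2), 1,
                              cluster_config(C = 1)),
               0)
})

test_that("PFCM with vanishing possibilistic weight reproduces FCM memberships", {
  set.seed(8)
  X <- matrix(c(rnorm(30, 0, 0.5), rnorm(30, 5, 0.5)), ncol = 1)
  init <- matrix(c(0.5, 4.5), ncol = 1)
  cfg_f <- cluster_config(C = 2, eps = 1e-12, max_iter = 400)
  fc <- fcm_fit(X, cfg_f, init = init)
  cfg_p <- cluster_config(C = 2, b = 1e-12, gamma = c(1, 1), eps = 1e-12,
                          max_iter = 400)
  pf <- pfcm_fit(X, cfg_p, init = list(centers = init))
  expect_lt(max(abs(pf$u - fc$u)), 1e-6)
})

test_that("PFCM rejects non-positive gamma and requires an init", {
  X <- matrix(rnorm(10), ncol = 1)
  expect_error(pfcm_fit(X, cluster_config(C = 2, gamma = c(1, -1)),
                        init = list(centers = matrix(c(0, 1)))),
               "gamma")
  expect_error(pfcm_fit(X, cluster_config(C = 2)), "init")
})

test_that("objective traces are non-increasing for all iterative kernels", {
  ph <- generate_phantom(phantom_spec(shape = c(20, 20), snr_noise = 0.1,
                                      seed = 4))
  img <- normalize_intensity(ph$anat)
  X <- img$data[ph$anat$mask]
  for (sd in 1:3) {
    cfg <- cluster_config(C = 3, eps = 1e-9, max_iter = 120, seed = sd)
    expect_true(all(diff(fcm_fit(X, cfg)$objective) <= 1e-9))
    expect_true(all(diff(suppressWarnings(bcfcm_fit(img, cfg))$objective) <= 1e-9))
    f0 <- fcm_fit(X, cfg)
    pf <- pfcm_fit(X, cfg, init = list(centers = f0$centers, u = f0$u))
    expect_true(all(diff(pf$objective) <= 1e-9))
    expect_true(all(diff(suppressWarnings(pcm_fit(X, cfg))$objective) <= 1e-9))
    expect_true(all(diff(suppressWarnings(fpcm_fit(X, cfg))$objective) <= 1e-9))
  }
})

test_that("permuting observations permutes the outputs consistently", {
  set.seed(10)
  X <- matrix(rnorm(40), ncol = 1)
  perm <- sample(40)
  init <- matrix(c(-1, 1), ncol = 1)
  cfg <- cluster_config(C = 2, eps = 1e-12)
  a <- fcm_fit(X, cfg, init = init)
  b <- fcm_fit(X[perm, , drop = FALSE], cfg, init = init)
  expect_equal(a$u[perm, ], b$u, tolerance = 1e-12)
  expect_equal(a$centers, b$centers, tolerance = 1e-12)
})

test_that("PFCM recovers true tissue means on a noiseless phantom", {
  ph <- generate_phantom(phantom_spec(shape = c(32, 32), snr_noise = 0,
                                      bias_amplitude = 0, pv_width = 0,
                                      seed = 1))
  X <- ph$anat$data[ph$anat$mask]
  # a sane init: evenly spread over the observed intensity range
  init0 <- matrix(min(X) + c(1, 3, 5) / 6 * diff(range(X)), ncol = 1)
  f0 <- fcm_fit(X, cluster_config(C = 3), init = init0)
  pf <- pfcm_fit(X, cluster_config(C = 3), init = list(centers = f0$centers,
                                                       u = f0$u))
  got <- sort(as.numeric(pf$centers))
  truem <- sort(unname(ph$spec$tissue_means_anat))
  expect_lt(max(abs(got - truem)), 0.02 * diff(range(truem)))
})
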