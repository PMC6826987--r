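#' Genetic algorithm configuration
#'
#' Parameters of the GA that refines BCFCM-produced centroid sets before the
#' PFCM stage. Defaults are the settings used for the package's own
#' experiments: a population of 10 chromosomes, 20 generations, crossover
#' probability 0.8 and per-gene mutation probability 0.01.
#'
#' @param pop_size population size (number of chromosomes).
#' @param generations number of generations (stopping criterion).
#' @param p_crossover crossover probability (>= 0.5 recommended).
#' @param p_mutation per-gene mutation probability.
#' @param mutation_sd_frac mutation noise s.d. as a fraction of the feature
#'   range.
#' @param weights optional per-observation weights for the fitness function
#'   (default 1).
#' @param elitism number of best chromosomes copied unchanged each
#'   generation.
#' @param seed RNG seed; fixes the whole evolution.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 10L, generations = 20L,
                      p_crossover = 0.8, p_mutation = 0.01,
                      mutation_sd_frac = 0.05, weights = NULL,
                      elitism = 1L, seed = NULL) {
  stopifnot_scalar(p_crossover, "p_crossover", lower = 0, upper = 1)
  stopifnot_scalar(p_mutation, "p_mutation", lower = 0, upper = 1)
  if (pop_size < 1L) stop("`pop_size` must be >= 1")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 mutation_sd_frac = mutation_sd_frac,
                 weights = weights, elitism = as.integer(elitism),
                 seed = seed),
            class = "ga_config")
}

#' Chromosome fitness: weighted dispersion about gravity centres
#'
#' Assigns every observation to its nearest candidate centre, computes each
#' cluster's (unweighted) gravity centre, and returns the weighted sum of
#' squared distances of the observations to their cluster's gravity centre,
#' \eqn{w = \sum_l \sum_{x_i \in C_l} p_i d^2(x_i, g_l)}. Lower is better.
#' An empty cluster contributes 0 and is flagged via the `"n_empty"`
#' attribute.
#'
#' @param X feature matrix, vector or [image_volume()].
#' @param centers candidate centroid set (C x d).
#' @param weights per-observation weights `p_i` (default 1).
#' @return Scalar fitness with attribute `n_empty`.
#' @export
ga_fitness <- function(X, centers, weights = NULL) {
  X <- as_feature_matrix(X)
  B <- as_center_matrix(centers, ncol(X))
  p <- weights %||% rep(1, nrow(X))
  D2 <- dist2_matrix(X, B)
  assign <- max.col(-D2, ties.method = "first")
  w <- 0
  n_empty <- 0L
  for (l in seq_len(nrow(B))) {
    in_l <- assign == l
    if (!any(in_l)) {
      n_empty <- n_empty + 1L
      next
    }
    g <- colMeans(X[in_l, , drop = FALSE])
    diff <- X[in_l, , drop = FALSE] - matrix(g, sum(in_l), ncol(X), byrow = TRUE)
    w <- w + sum(p[in_l] * rowSums(diff * diff))
  }
  structure(w, n_empty = n_empty)
}

new_chromosome <- function(centers, X, weights) {
  f <- ga_fitness(X, centers, weights)
  list(centers = centers, fitness = as.numeric(f),
       n_empty = attr(f, "n_empty"))
}

#' Initialise a GA population from repeated BCFCM runs
#'
#' Each chromosome is the centroid set of one [bcfcm_fit()] (or, for
#' non-image data, [fcm_fit()]) run started from a distinct derived seed;
#' fitness is attached immediately.
#'
#' @param img image (or feature matrix for `method = "fcm"`).
#' @param cfg a [cluster_config()].
#' @param ga a [ga_config()]; `pop_size` runs are performed, seeded from
#'   `ga$seed`.
#' @param method `"bcfcm"` (image data) or `"fcm"`.
#' @return List of `pop_size` chromosomes (lists with `centers`, `fitness`,
#'   `n_empty`).
#' @export
ga_init_population <- function(img, cfg = cluster_config(), ga = ga_config(),
                               method = c("bcfcm", "fcm")) {
  method <- match.arg(method)
  X <- as_feature_matrix(img)
  lapply(seq_len(ga$pop_size), function(k) {
    cfg_k <- cfg
    cfg_k$seed <- derive_seed(ga$seed %||% 0L, k)
    fit <- if (method == "bcfcm") bcfcm_fit(img, cfg_k) else fcm_fit(X, cfg_k)
    new_chromosome(as_center_matrix(fit$centers, ncol(X)), X, ga$weights)
  })
}

#' Evolve a population of centroid sets
#'
#' Runs `generations` rounds of fitness-proportional selection (on
#' `1/(1+w)`), one-point crossover at centre boundaries with probability
#' `p_crossover`, and per-gene Gaussian mutation with probability
#' `p_mutation`, with elitism. Chromosomes flagged with empty clusters have
#' one centre re-seeded from a random data point during mutation. The best
#' fitness is monotone non-increasing across generations and the whole run
#' is deterministic under a fixed seed.
#'
#' @param population chromosome list from [ga_init_population()].
#' @param X feature matrix, vector or [image_volume()].
#' @param ga a [ga_config()].
#' @param m fuzzifier used to derive the fuzzy partition of the winner.
#' @return List: `best` (winning chromosome), `u` (fuzzy partition induced by
#'   its centres), `fitness_trace` (best-so-far per generation),
#'   `population` (final generation).
#' @export
ga_evolve <- function(population, X, ga = ga_config(), m = 2) {
  if (length(population) == 0L) stop("empty population")
  X <- as_feature_matrix(X)
  d <- ncol(X)
  C <- nrow(as_center_matrix(population[[1L]]$centers, d))
  rng <- apply(X, 2L, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  mut_sd <- ga$mutation_sd_frac * rng

  pop <- population
  best_trace <- numeric(0)

  with_seed(ga$seed, {
    for (gen in seq_len(ga$generations)) {
      fit <- vapply(pop, function(ch) ch$fitness, 0)
      ord <- order(fit)
      elite <- pop[ord[seq_len(min(ga$elitism, length(pop)))]]
      best_trace <- c(best_trace, fit[ord[1L]])
      n_off <- length(pop) - length(elite)
      if (n_off > 0L) {
        sel_p <- 1 / (1 + fit)
        sel_p <- sel_p / sum(sel_p)
        offspring <- vector("list", n_off)
        k <- 1L
        while (k <= n_off) {
          parents <- sample.int(length(pop), 2L, replace = TRUE, prob = sel_p)
          c1 <- as_center_matrix(pop[[parents[1L]]]$centers, d)
          c2 <- as_center_matrix(pop[[parents[2L]]]$centers, d)
          if (C > 1L && stats::runif(1) < ga$p_crossover) {
            cut <- sample.int(C - 1L, 1L)
            ch1 <- rbind(c1[seq_len(cut), , drop = FALSE],
                         c2[-seq_len(cut), , drop = FALSE])
            ch2 <- rbind(c2[seq_len(cut), , drop = FALSE],
                         c1[-seq_len(cut), , drop = FALSE])
          } else {
            ch1 <- c1; ch2 <- c2
          }
          for (child in list(ch1, ch2)) {
            if (k > n_off) break
            # per-gene Gaussian mutation
            mut <- matrix(stats::runif(length(child)) < ga$p_mutation,
                          nrow(child), ncol(child))
            if (any(mut)) {
              noise <- matrix(stats::rnorm(length(child)), nrow(child), ncol(child))
              noise <- sweep(noise, 2L, mut_sd, "*")
              child[mut] <- child[mut] + noise[mut]
            }
            ch <- new_chromosome(child, X, ga$weights)
            # empty-cluster repair: re-seed one centre from a random data point
            if (ch$n_empty > 0L) {
              child[sample.int(C, 1L), ] <- X[sample.int(nrow(X), 1L), ]
              ch <- new_chromosome(child, X, ga$weights)
            }
            offspring[[k]] <- ch
            k <- k + 1L
          }
        }
        pop <- c(elite, offspring)
      } else {
        pop <- elite
      }
    }
  })
  fit <- vapply(pop, function(ch) ch$fitness, 0)
  best <- pop[[which.min(fit)]]
  # the merit function measures dispersion about the gravity centres of the
  # winner's assignment, so those centres minimise it for that assignment:
  # finish with one such polish step (never increases the fitness)
  Bb <- as_center_matrix(best$centers, d)
  assign <- max.col(-dist2_matrix(X, Bb), ties.method = "first")
  Bg <- Bb
  for (l in seq_len(nrow(Bb))) {
    if (any(assign == l)) Bg[l, ] <- colMeans(X[assign == l, , drop = FALSE])
  }
  polished <- new_chromosome(Bg, X, ga$weights)
  if (polished$fitness <= best$fitness) best <- polished
  best_trace <- c(best_trace, best$fitness)
  u <- fcm_memberships(dist2_matrix(X, as_center_matrix(best$centers, d)), m)
  list(best = best, u = u, centers = as_center_matrix(best$centers, d),
       fitness_trace = best_trace, population = pop)
}
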