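# Distance-preservation correlations, superposition RMSD, MMD, EMD and the
# replicate benchmark.

test_that("isometric and anti-ordered embeddings hit the correlation bounds", {
  set.seed(61)
  X <- matrix(rnorm(20 * 8), 20, 8)
  R <- qr.Q(qr(matrix(rnorm(64), 8, 8)))      # random orthogonal map
  expect_equal(distance_preservation(X, X %*% R, "spearman"), 1)
  expect_equal(distance_preservation(X, X %*% R, "pearson"), 1,
               tolerance = 1e-12)
  # three points whose pair distances reverse order between the spaces
  high <- cbind(c(0, 1, 3))
  low <- cbind(c(0, 3, 1))
  expect_equal(distance_preservation(high, low, "spearman"), -1)
  expect_equal(distance_preservation(high, low, "pearson"), -1,
               tolerance = 1e-12)
})

test_that("rank formula matches the all-pairs correlation oracle", {
  set.seed(62)
  X <- matrix(rnorm(15 * 10), 15, 10)
  Y <- matrix(rnorm(15 * 2), 15, 2)
  dh <- as.vector(dist(X)); dl <- as.vector(dist(Y))
  expect_lt(abs(distance_preservation(X, Y, "spearman") -
                  cor(dh, dl, method = "spearman")), 1e-12)
})

test_that("pearson path matches the direct covariance oracle", {
  set.seed(63)
  X <- matrix(rnorm(12 * 6), 12, 6)
  Y <- matrix(rnorm(12 * 2), 12, 2)
  dh <- as.vector(dist(X)); dl <- as.vector(dist(Y))
  expect_lt(abs(distance_preservation(X, Y, "pearson") - cor(dh, dl)), 1e-12)
  # formula unit test on an exact negative linear relation
  x <- c(1, 2, 5, 9)
  expect_equal(latentmd:::pearson_cor(x, -2 * x + 3), -1)
})

test_that("correlations are invariant to joint frame permutations", {
  set.seed(64)
  X <- matrix(rnorm(10 * 5), 10, 5)
  Y <- matrix(rnorm(10 * 2), 10, 2)
  perm <- sample(10)
  for (m in c("spearman", "pearson"))
    expect_equal(distance_preservation(X, Y, m),
                 distance_preservation(X[perm, ], Y[perm, ], m),
                 tolerance = 1e-12)
  expect_error(distance_preservation(X[1:2, ], Y[1:2, ]), "at least 3")
  expect_error(distance_preservation(matrix(1, 5, 2), Y[1:5, ]), "constant")
})

test_that("pair subsampling is seeded and respects max_pairs", {
  set.seed(65)
  X <- matrix(rnorm(60 * 4), 60, 4)
  Y <- X[, 1:2]
  a <- distance_preservation(X, Y, "spearman", max_pairs = 200, seed = 3)
  b <- distance_preservation(X, Y, "spearman", max_pairs = 200, seed = 3)
  expect_identical(a, b)
})

test_that("superposition RMSD is zero under rigid motion and symmetric", {
  set.seed(66)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(superposition_rmsd(A, A), 0)
  moved <- sweep(A %*% rotation_z(37), 2, c(4, -2, 7), `+`)
  expect_lt(superposition_rmsd(moved, A), 1e-9)
  B <- A + matrix(rnorm(30, sd = 0.3), 10, 3)
  expect_lt(abs(superposition_rmsd(A, B) - superposition_rmsd(B, A)), 1e-9)
  expect_error(superposition_rmsd(A, A[1:5, ]), "mismatch")
})

test_that("kabsch minimum matches a brute-force rotation-grid oracle", {
  set.seed(67)
  P <- matrix(rnorm(12, sd = 1), 4, 3)
  Q <- matrix(rnorm(12, sd = 1), 4, 3)
  fitted <- superposition_rmsd(P, Q)
  # translation is analytic (centroids); scan ZYZ Euler rotations at 3 deg
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  step <- 3 * pi / 180
  al <- seq(0, 2 * pi - step, by = step)
  be <- seq(0, pi, by = step)
  ga <- seq(0, 2 * pi - step, by = step)
  grid_min <- Inf
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1),
                           3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)),
                           3, 3)
  cs <- cos(ga); sn <- sin(ga)
  for (a in al) {
    Ra <- rz(a)
    for (b in be) {
      PR <- Pc %*% (Ra %*% ry(b))
      # right-multiplying by rz(g) mixes only the first two columns
      ss <- colSums((outer(PR[, 1], cs) + outer(PR[, 2], sn) - Qc[, 1])^2) +
        colSums((outer(PR[, 2], cs) - outer(PR[, 1], sn) - Qc[, 2])^2) +
        sum((PR[, 3] - Qc[, 3])^2)
      grid_min <- min(grid_min, sqrt(min(ss) / 4))
    }
  }
  max_radius <- max(sqrt(rowSums(Pc^2)))
  expect_lte(fitted, grid_min + 1e-9)          # kabsch is the true minimum
  expect_lt(grid_min - fitted, step * max_radius * 2)  # grid resolution
})

test_that("MMD vanishes on identical samples and separates shifted ones", {
  set.seed(68)
  x <- rnorm(200)
  expect_lt(mmd(x, x, biased = TRUE), 1e-12)
  expect_lte(mmd(x, x), 1e-6)   # unbiased, clamped at zero
  y_same <- rnorm(200)
  y_far <- rnorm(200) + 3
  expect_gt(mmd(x, y_far), mmd(x, y_same))
  expect_equal(mmd(x, y_far), mmd(y_far, x))   # symmetry
  expect_error(mmd(numeric(0), x), "non-empty")
})

test_that("null-distributed MMD stays below its permutation quantile", {
  n <- 100
  n_seeds <- 30
  below <- logical(n_seeds)
  ests <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(700 + s)
    x <- rnorm(n); y <- rnorm(n)
    est <- mmd(x, y)
    pooled <- c(x, y)
    perms <- replicate(99, {
      idx <- sample(2 * n, n)
      mmd(pooled[idx], pooled[-idx])
    })
    below[s] <- est <= quantile(perms, 0.95)
    ests[s] <- est
  }
  expect_lt(mean(ests), 0.2)       # near zero under the null
  expect_gte(mean(below), 0.8)     # nominal rate 0.95; 3-sigma slack
})

test_that("EMD has its analytic values and translation property", {
  expect_equal(emd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(emd(0, 1), 1)                       # point masses
  set.seed(69)
  x <- rnorm(57)
  expect_equal(emd(x, x + 2.5), 2.5)
  expect_equal(emd(x, x - 0.75), 0.75)
  # triangle inequality on random triples
  for (i in 1:5) {
    a <- rnorm(40); b <- rnorm(35, 1); c <- rexp(50)
    expect_lte(emd(a, c), emd(a, b) + emd(b, c) + 1e-12)
  }
  expect_error(emd(numeric(0), 1), "non-empty")
})

test_that("an overtrained model memorizes a tiny frame set", {
  sim <- two_state_trajectory(4, n_atoms = 20, noise_sigma = 0.5,
                              switch_prob = 0.5, seed = 71)
  fm <- featurize(sim$ensemble)
  fit <- traj_vae(fm, kind = "ae", encoder_sizes = c(40, 20), epochs = 8000,
                  batch_size = 4, learning_rate = 5e-3, seed = 2)
  prof <- decoder_rmsd_profile(fit)
  expect_length(prof$per_frame, 4)
  expect_lt(prof$mean, 0.1 * 0.5)   # a tenth of the injected noise scale
})

test_that("training beats the untrained initialization on the same data", {
  fx <- toy_fit_fixture()
  untrained <- traj_vae(fx$fm, epochs = 0, seed = 7, split = fx$split)
  expect_lt(decoder_rmsd_profile(fx$fit)$mean,
            decoder_rmsd_profile(untrained)$mean)
})

test_that("the replicate benchmark reports every metric and reproduces", {
  sim <- two_state_trajectory(64, n_atoms = 12, seed = 72)
  fm <- featurize(align_to_first(sim$ensemble))
  split <- stride_split(64, 4)
  specs <- list(small_vae = list(kind = "vae", encoder_sizes = c(12L, 6L),
                                 epochs = 25))
  tab <- benchmark_models(specs, fm, split, n_replicates = 1, seed = 10)
  expect_equal(nrow(tab), 1L)
  expect_true(all(is.finite(unlist(tab[, c("spearman", "pearson",
                                           "mean_rmsd", "mmd", "emd")]))))
  expect_true(all(abs(tab$spearman) <= 1 & abs(tab$pearson) <= 1))
  tab2 <- benchmark_models(specs, fm, split, n_replicates = 1, seed = 10)
  expect_equal(tab, tab2)
  expect_s3_class(attr(tab, "summary"), "data.frame")

  # an untrained spec must not beat its trained twin on decode RMSD
  specs2 <- list(trained = list(encoder_sizes = c(12L, 6L), epochs = 25),
                 frozen = list(encoder_sizes = c(12L, 6L), epochs = 0))
  tab3 <- benchmark_models(specs2, fm, split, n_replicates = 1, seed = 10)
  expect_lt(tab3$mean_rmsd[tab3$model == "trained"],
            tab3$mean_rmsd[tab3$model == "frozen"])
})
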