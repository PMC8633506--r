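# Hourglass AE/VAE: architecture construction, the ELBO pieces, gradient
# correctness, training behaviour, determinism and persistence.

test_that("hourglass sizes interpolate geometrically and validate", {
  s <- hourglass_sizes(150, 4)
  expect_length(s, 4)
  expect_true(all(diff(s) < 0))
  expect_true(all(s < 150) && all(s > 2))
  expect_error(traj_vae(matrix(runif(40), 10, 4), latent_dim = 0),
               "latent_dim")
  expect_error(traj_vae(matrix(runif(40), 10, 4),
                        encoder_sizes = c(2, 3)), "decreasing")
  expect_error(traj_vae(matrix(runif(40), 10, 4),
                        encoder_sizes = c(8, 3)), "narrower")
})

test_that("same spec and seed give identical initial weights", {
  X <- matrix(runif(200), 20, 10)
  a <- traj_vae(X, encoder_sizes = c(6, 4), epochs = 0, seed = 5)
  b <- traj_vae(X, encoder_sizes = c(6, 4), epochs = 0, seed = 5)
  expect_identical(a$params, b$params)
  expect_equal(nrow(a$history), 0L)
})

test_that("the KL term matches its closed form", {
  # q = N(0, 1): KL is exactly zero
  expect_equal(latentmd:::kl_gaussian(matrix(0, 3, 2), matrix(0, 3, 2)),
               rep(0, 3))
  # KL(N(mu, 1) || N(0, 1)) = mu^2 / 2 per latent dimension
  mu <- matrix(c(1.5, -0.7, 2, 0.3), 2, 2)
  expect_equal(latentmd:::kl_gaussian(mu, matrix(0, 2, 2)),
               rowSums(mu^2) / 2)
  # general diagonal Gaussian against a numeric reference
  expect_equal(latentmd:::kl_gaussian(matrix(1, 1, 1), matrix(log(4), 1, 1)),
               0.5 * (1 + 4 - 1 - log(4)))
})

test_that("backpropagated gradients match finite differences", {
  set.seed(21)
  X <- matrix(runif(5 * 6), 5, 6)
  fit <- traj_vae(X, encoder_sizes = c(4, 3), epochs = 0, seed = 2,
                  kl_weight = 0.7)
  pr <- fit$params
  eps_mat <- matrix(rnorm(5 * 2), 5, 2)
  loss_of <- function(p) {
    bp <- latentmd:::vae_backprop(p, X, 2, TRUE, 0.7, eps_mat)
    (bp$recon_sum + 0.7 * bp$kl_sum) / nrow(X)
  }
  bp <- latentmd:::vae_backprop(pr, X, 2, TRUE, 0.7, eps_mat)
  h <- 1e-6
  for (nm in c("e1", "mu", "lv", "d2", "out")) {
    W <- pr[[nm]]$W
    for (k in sample(length(W), 3)) {
      pp <- pr; pp[[nm]]$W[k] <- W[k] + h
      pm <- pr; pm[[nm]]$W[k] <- W[k] - h
      num <- (loss_of(pp) - loss_of(pm)) / (2 * h)
      expect_equal(bp$grads[[nm]]$W[k], num, tolerance = 1e-4)
    }
  }
})

test_that("recorded losses decompose and trend downward", {
  fx <- toy_fit_fixture()
  h <- fx$fit$history
  expect_equal(nrow(h), fx$fit$epochs)
  expect_true(all(is.finite(unlist(h))))
  expect_lt(max(abs(h$total - (h$recon + fx$fit$kl_weight * h$kl))), 1e-6)
  expect_lt(mean(tail(h$total, 10)), mean(head(h$total, 10)))
})

test_that("a zero-KL VAE trains to the same reconstruction level as an AE", {
  sim <- two_state_trajectory(200, n_atoms = 20, seed = 31)
  fm <- featurize(align_to_first(sim$ensemble))
  vae0 <- traj_vae(fm, kind = "vae", kl_weight = 0, epochs = 40, seed = 1)
  ae <- traj_vae(fm, kind = "ae", epochs = 40, seed = 1)
  r_vae <- tail(vae0$history$recon, 1)
  r_ae <- tail(ae$history$recon, 1)
  expect_lt(abs(r_vae - r_ae), 0.5 * r_ae)
  expect_equal(tail(ae$history$kl, 1), 0)
})

test_that("encoding and decoding are deterministic posterior means", {
  fx <- toy_fit_fixture()
  X <- fx$fm$values[c(1, 1, 5), ]
  Z <- encode(fx$fit, X)
  expect_equal(Z[1, ], Z[2, ])           # identical frames, identical codes
  expect_identical(encode(fx$fit, X), Z) # repeated call, identical result
  z <- Z[1, , drop = FALSE]
  expect_identical(decode(fx$fit, z), decode(fx$fit, z))
  expect_error(decode(fx$fit, matrix(0, 1, 5)), "latent point dimension")
  expect_error(encode(fx$fit, X[, 1:10]), "does not match")
})

test_that("the latent space separates the two metastable states", {
  fx <- toy_fit_fixture()
  Z <- encode(fx$fit)
  lab <- fx$sim$labels
  d <- data.frame(z1 = Z[, 1], z2 = Z[, 2], y = factor(lab))
  g <- suppressWarnings(glm(y ~ z1 + z2, data = d[fx$split$train, ],
                            family = binomial))
  p <- predict(g, d[fx$split$test, ], type = "response")
  acc <- mean((p > 0.5) == (d$y[fx$split$test] == 1))
  expect_gte(acc, 0.95)
  # centroid separation exceeds 3x the mean within-state spread
  s0 <- Z[lab == 0, ]; s1 <- Z[lab == 1, ]
  sep <- sqrt(sum((colMeans(s0) - colMeans(s1))^2))
  spread <- mean(c(sqrt(rowSums(sweep(s0, 2, colMeans(s0))^2)),
                   sqrt(rowSums(sweep(s1, 2, colMeans(s1))^2))))
  expect_gt(sep, 3 * spread)
})

test_that("encode-decode round trips are consistent on the fixture", {
  fx <- toy_fit_fixture()
  Z <- encode(fx$fit)
  z2 <- encode(fx$fit, decode(fx$fit, Z))
  # re-encoded decodes stay in the same latent neighbourhood, per state
  lab <- fx$sim$labels
  sep <- sqrt(sum((colMeans(Z[lab == 0, ]) - colMeans(Z[lab == 1, ]))^2))
  expect_lt(median(sqrt(rowSums((z2 - Z)^2))), 0.25 * sep)
})

test_that("all five reference architectures build and train briefly", {
  sim <- two_state_trajectory(64, n_atoms = 1660, noise_sigma = 0.5,
                              seed = 41)
  fm <- featurize(sim$ensemble)
  expect_equal(ncol(fm$values), 4980L)
  archs <- list(c(128L), c(512L, 32L), c(1024L, 128L, 16L),
                c(1024L, 256L, 64L, 16L), c(2048L, 512L, 128L, 32L, 8L))
  for (a in archs) {
    fit <- traj_vae(fm$values, kind = "vae", encoder_sizes = a,
                    latent_dim = 2, epochs = 2, seed = 1)
    expect_equal(fit$encoder_sizes, a)
    expect_equal(fit$decoder_sizes, rev(a))
    expect_true(all(is.finite(fit$history$total)))
  }
})

test_that("deeper models reconstruct the near-noiseless toy at least as well", {
  sim <- two_state_trajectory(200, n_atoms = 20, noise_sigma = 0.01,
                              switch_prob = 0.1, seed = 51)
  fm <- featurize(sim$ensemble)
  deep <- traj_vae(fm, encoder_sizes = c(40, 24, 12, 6), epochs = 60,
                   seed = 3)
  shallow <- traj_vae(fm, encoder_sizes = c(12L), epochs = 60, seed = 3)
  expect_lte(tail(deep$history$recon, 1), tail(shallow$history$recon, 1))
})

test_that("model persistence round-trips weights, history and scaler", {
  fx <- toy_fit_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  save_vae(fx$fit, path)
  back <- load_vae(path)
  expect_equal(nrow(back$history), nrow(fx$fit$history))
  expect_equal(back$encoder_sizes, fx$fit$encoder_sizes)
  X <- fx$fm$values[1:10, ]
  expect_lt(max(abs(encode(back, X) - encode(fx$fit, X))), 1e-6)
  expect_lt(max(abs(back$scaler$min - fx$fit$scaler$min)), 1e-12)

  trunc_path <- withr::local_tempfile(fileext = ".json")
  full <- readLines(path)
  writeLines(substr(paste(full, collapse = ""), 1, 500), trunc_path)
  expect_error(load_vae(trunc_path), "cannot read|not a latentmd")
})

test_that("fitting is reproducible end to end for a fixed seed", {
  X <- matrix(runif(300), 30, 10)
  a <- traj_vae(X, encoder_sizes = c(6, 4), epochs = 15, seed = 9,
                batch_size = 8)
  b <- traj_vae(X, encoder_sizes = c(6, 4), epochs = 15, seed = 9,
                batch_size = 8)
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
})

test_that("standard S3 methods behave", {
  fx <- toy_fit_fixture()
  expect_output(print(fx$fit), "VAE: 150")
  s <- summary(fx$fit)
  expect_output(print(s), "hidden layers")
  expect_named(coef(fx$fit)[["mu"]], c("W", "b"))
  r <- residuals(fx$fit)
  expect_length(r, 600)
  expect_true(all(r >= 0))
  gen <- simulate(fx$fit, nsim = 3, seed = 1)
  expect_s3_class(gen, "traj_ensemble")
  expect_equal(dim(gen$xyz), c(3L, 50L, 3L))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  plot(fx$fit, "history")
  plot(fx$fit, "latent", labels = fx$sim$labels)
  grDevices::dev.off()
  expect_true(file.exists(path))
})
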