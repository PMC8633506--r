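# Encoder/decoder fidelity metrics: Kabsch superposition RMSD,
# distance-preservation correlations between the feature space and the
# latent space, kernel maximum mean discrepancy and 1-D earth mover's
# distance on RMSD-proxy distributions, and the replicate benchmark table.

## Kabsch least-squares rigid fit of P (moving) onto Q (reference), both
## n x 3 in row-vector convention: P %*% R + t approximates Q.  The SVD
## determinant correction excludes reflections.
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, t = as.numeric(cq - cp %*% R))
}

#' Superposition RMSD between two structures
#'
#' Root-mean-square atomic deviation minimized over all proper rigid
#' transformations (rotation + translation, no reflection) of `structure`
#' onto `reference`:
#' `RMSD = sqrt( sum_i || r0_i - U r_i ||^2 / N )` with `U` the best-fit
#' transformation.
#'
#' @param structure,reference `n_atoms x 3` coordinate matrices (or
#'   single-frame [traj_ensemble()] objects) with equal atom counts,
#'   `n_atoms >= 3`.
#' @return Non-negative RMSD in Angstrom.
#' @examples
#' a <- matrix(rnorm(30), 10)
#' superposition_rmsd(a, a)   # 0
#' @export
superposition_rmsd <- function(structure, reference) {
  P <- as_frame_matrix(structure)
  Q <- as_frame_matrix(reference)
  if (!identical(dim(P), dim(Q)))
    stop("atom count mismatch: ", nrow(P), " vs ", nrow(Q))
  if (nrow(P) < 3L) stop("at least 3 atoms are required")
  k <- kabsch(P, Q)
  moved <- sweep(P %*% k$R, 2L, k$t, `+`)
  sqrt(sum((moved - Q)^2) / nrow(P))
}

as_frame_matrix <- function(x) {
  if (inherits(x, "traj_ensemble")) {
    if (n_frames(x) != 1L)
      stop("expected a single-frame structure, got ", n_frames(x), " frames")
    return(frame_coords(x, 1L))
  }
  m <- as.matrix(x)
  if (ncol(m) != 3L) stop("coordinates must be an n_atoms x 3 matrix")
  m
}

## Euclidean distances for a set of (i, j) index pairs among rows of X
pair_distances <- function(X, pairs) {
  sqrt(rowSums((X[pairs[, 1L], , drop = FALSE] -
                  X[pairs[, 2L], , drop = FALSE])^2))
}

## all i<j pairs, or a seeded uniform subsample of max_pairs of them
choose_pairs <- function(n, max_pairs, seed) {
  total <- n * (n - 1) / 2
  if (total <= max_pairs) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    return(cbind(idx[, "row"], idx[, "col"]))
  }
  if (!is.null(seed)) set.seed(seed)
  i <- sample.int(n, max_pairs, replace = TRUE)
  j <- sample.int(n - 1L, max_pairs, replace = TRUE)
  j <- j + (j >= i)
  cbind(pmin(i, j), pmax(i, j))
}

#' Distance preservation between feature space and latent space
#'
#' How well inter-frame Euclidean distances in the high-dimensional feature
#' space are preserved in the latent embedding: the same frame pairs are
#' measured in both spaces and correlated.  `method = "spearman"` uses the
#' rank formula `rho = 1 - 6 * sum(d_i^2) / (n (n^2 - 1))` on the paired
#' ranks when they are tie-free, and Pearson-of-average-ranks when ties are
#' present (the shortcut formula is biased under ties);
#' `method = "pearson"` is the plain product-moment correlation of the two
#' distance lists.
#'
#' All `choose(n, 2)` pairs are used when that is at most `max_pairs`,
#' otherwise a seeded uniform subsample of `max_pairs` pairs.
#'
#' @param high_dim Frames-by-features matrix or `feature_matrix`.
#' @param low_dim Frames-by-latent matrix (e.g. from [encode()]).
#' @param method `"spearman"` or `"pearson"`.
#' @param max_pairs Maximum number of frame pairs (default 100,000).
#' @param seed Seed for the pair subsample.
#' @return Correlation in `[-1, 1]`.
#' @export
distance_preservation <- function(high_dim, low_dim,
                                  method = c("spearman", "pearson"),
                                  max_pairs = 1e5, seed = 1) {
  method <- match.arg(method)
  X <- if (inherits(high_dim, "feature_matrix")) high_dim$values else
    as.matrix(high_dim)
  Y <- as.matrix(low_dim)
  if (nrow(X) != nrow(Y))
    stop("frame counts differ: ", nrow(X), " vs ", nrow(Y))
  if (nrow(X) < 3L) stop("at least 3 frames are required")
  pairs <- choose_pairs(nrow(X), max_pairs, seed)
  dh <- pair_distances(X, pairs)
  dl <- pair_distances(Y, pairs)
  if (stats::sd(dh) == 0 || stats::sd(dl) == 0)
    stop("distances are constant in one space; correlation undefined")
  if (method == "pearson") return(pearson_cor(dh, dl))
  rh <- rank(dh); rl <- rank(dl)
  if (anyDuplicated(dh) || anyDuplicated(dl)) return(pearson_cor(rh, rl))
  n <- length(dh)
  1 - 6 * sum((rh - rl)^2) / (n * (n^2 - 1))
}

pearson_cor <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

#' Per-frame decode-reconstruction RMSD profile
#'
#' For every frame: encode, decode, invert both original and reconstruction
#' to Angstrom with the model scaler, and measure the superposition RMSD.
#'
#' @param model A fitted [traj_vae()] carrying a scaler.
#' @param x Features to evaluate (`feature_matrix` or matrix); defaults to
#'   the training data.
#' @return List with `per_frame` (RMSD vector, Angstrom) and `mean`.
#' @export
decoder_rmsd_profile <- function(model, x = NULL) {
  stopifnot(inherits(model, "traj_vae"))
  if (is.null(model$scaler))
    stop("the model carries no scaler; fit it on a feature_matrix")
  per_frame <- residuals(model, newdata = x)
  list(per_frame = per_frame, mean = mean(per_frame))
}

#' Maximum mean discrepancy between two samples
#'
#' Kernel two-sample statistic with the Gaussian kernel
#' `k(a, b) = exp(-(a - b)^2 / (2 h^2))`.  By default the unbiased estimator
#' of the squared MMD is used, clamped at zero, and its square root
#' returned; `h` is the median pairwise distance of the pooled sample
#' (median heuristic) unless given.
#'
#' @param sample_p,sample_q Non-empty numeric vectors (here typically
#'   RMSD-to-reference values standing proxy for structures).
#' @param bandwidth `"median"` or a positive number.
#' @param biased Use the biased (V-statistic) estimator instead?
#' @return Non-negative MMD estimate.
#' @export
mmd <- function(sample_p, sample_q, bandwidth = "median", biased = FALSE) {
  x <- as.numeric(sample_p); y <- as.numeric(sample_q)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (identical(bandwidth, "median")) {
    pooled <- c(x, y)
    dists <- abs(outer(pooled, pooled, `-`))
    h <- stats::median(dists[upper.tri(dists)])
    if (!is.finite(h) || h <= 0) h <- 1  # degenerate pooled sample
  } else {
    h <- as.numeric(bandwidth)
    if (h <= 0) stop("'bandwidth' must be positive")
  }
  k <- function(a, b) exp(-outer(a, b, `-`)^2 / (2 * h^2))
  Kxx <- k(x, x); Kyy <- k(y, y); Kxy <- k(x, y)
  n <- length(x); m <- length(y)
  if (biased) {
    mmd2 <- mean(Kxx) + mean(Kyy) - 2 * mean(Kxy)
  } else {
    if (n < 2L || m < 2L)
      stop("the unbiased estimator needs at least 2 points per sample")
    mmd2 <- (sum(Kxx) - n) / (n * (n - 1)) +
      (sum(Kyy) - m) / (m * (m - 1)) - 2 * mean(Kxy)
  }
  sqrt(max(mmd2, 0))
}

#' Earth mover's distance between two 1-D samples
#'
#' First Wasserstein distance between the empirical distributions,
#' computed exactly as the integral of the absolute difference of the two
#' empirical CDFs.
#'
#' @param sample_p,sample_q Non-empty numeric vectors.
#' @return Non-negative distance in the units of the inputs.
#' @examples
#' emd(1:10, 1:10 + 2.5)   # exactly 2.5
#' @export
emd <- function(sample_p, sample_q) {
  x <- as.numeric(sample_p); y <- as.numeric(sample_q)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  v <- sort(c(x, y))
  if (length(v) == 1L) return(0)
  Fx <- stats::ecdf(x)(v[-length(v)])
  Fy <- stats::ecdf(y)(v[-length(v)])
  sum(abs(Fx - Fy) * diff(v))
}

#' Benchmark model architectures with replicate training
#'
#' Trains each architecture `n_replicates` times with distinct seeds,
#' evaluates on the test partition, and tabulates per-replicate metrics:
#' Spearman and Pearson distance preservation (encoder), mean decode RMSD in
#' Angstrom (decoder), and MMD / EMD between the RMSD-to-reference
#' distributions of the test frames and of their decodes (the RMSD-proxy
#' convention; the reference is the first training frame unless given).
#'
#' @param specs Named list of architecture specs; each spec is a list of
#'   arguments for [traj_vae()] (e.g. `kind`, `encoder_sizes`, `epochs`).
#' @param x A `feature_matrix` (a scaler is required for the RMSD metrics).
#' @param split A [stride_split()] result.
#' @param n_replicates Independent trainings per spec (default 3).
#' @param seed Base seed; replicate r of spec s trains with
#'   `seed + 100 * s + r`.
#' @param reference Optional `n_atoms x 3` reference structure for the RMSD
#'   proxy.
#' @return Data frame with one row per (model, replicate):
#'   `model`, `replicate`, `spearman`, `pearson`, `mean_rmsd`, `mmd`, `emd`.
#'   A failed replicate yields a row of `NA`s and a warning, never a silent
#'   drop.  Per-model means are attached as attribute `"summary"`.
#' @export
benchmark_models <- function(specs, x, split, n_replicates = 3, seed = 1,
                             reference = NULL) {
  stopifnot(inherits(x, "feature_matrix"), length(specs) >= 1L)
  if (is.null(names(specs)))
    names(specs) <- paste0("model", seq_along(specs))
  Xtest <- x$values[split$test, , drop = FALSE]
  if (is.null(reference))
    reference <- frame_coords(
      defeaturize(x$values[split$train[1L], , drop = FALSE], x$scaler,
                  x$atoms), 1L)
  rows <- list()
  for (s in seq_along(specs)) {
    for (r in seq_len(n_replicates)) {
      res <- tryCatch({
        args <- c(list(x = x, split = split,
                       seed = seed + 100L * s + r), specs[[s]])
        fit <- do.call(traj_vae, args)
        Z <- encode(fit, Xtest)
        Y <- decode(fit, Z)
        orig <- defeaturize(Xtest, x$scaler, as_ensemble = FALSE)
        reco <- defeaturize(Y, x$scaler, as_ensemble = FALSE)
        per_frame <- vapply(seq_len(nrow(Xtest)), function(i)
          superposition_rmsd(unflatten_frames(reco[i, , drop = FALSE])[1, , ],
                             unflatten_frames(orig[i, , drop = FALSE])[1, , ]),
          numeric(1))
        rmsd_orig <- vapply(seq_len(nrow(Xtest)), function(i)
          superposition_rmsd(unflatten_frames(orig[i, , drop = FALSE])[1, , ],
                             reference), numeric(1))
        rmsd_reco <- vapply(seq_len(nrow(Xtest)), function(i)
          superposition_rmsd(unflatten_frames(reco[i, , drop = FALSE])[1, , ],
                             reference), numeric(1))
        data.frame(model = names(specs)[s], replicate = r,
                   spearman = distance_preservation(Xtest, Z, "spearman"),
                   pearson = distance_preservation(Xtest, Z, "pearson"),
                   mean_rmsd = mean(per_frame),
                   mmd = mmd(rmsd_orig, rmsd_reco),
                   emd = emd(rmsd_orig, rmsd_reco))
      }, error = function(e) {
        warning("replicate ", r, " of '", names(specs)[s], "' failed: ",
                conditionMessage(e))
        data.frame(model = names(specs)[s], replicate = r, spearman = NA_real_,
                   pearson = NA_real_, mean_rmsd = NA_real_, mmd = NA_real_,
                   emd = NA_real_)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  tab <- do.call(rbind, rows)
  means <- stats::aggregate(tab[, c("spearman", "pearson", "mean_rmsd",
                                    "mmd", "emd")],
                            by = list(model = tab$model), FUN = mean)
  attr(tab, "summary") <- means
  tab
}
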