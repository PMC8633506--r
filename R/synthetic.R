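# Synthetic two-metastable-state trajectories with known ground truth.
# Frames are drawn around one of two reference conformations with isotropic
# Gaussian positional noise; the active state follows a two-state Markov
# chain.  There is no force field and no dynamics integration: the generator
# exists so the whole featurize -> train -> evaluate -> sample -> timescales
# pipeline can run end to end with exact ground truth.

#' Simulate a discrete Markov chain
#'
#' Realizes a two-state (or n-state) Markov chain from a row-stochastic
#' transition matrix, started in the first state.  States are returned as
#' 0-based integers so that a two-state chain yields labels in `{0, 1}`.
#'
#' @param n_steps Integer, length of the chain (>= 1).
#' @param transition_matrix Square row-stochastic matrix; rows must sum to 1
#'   within `1e-12` and all entries must lie in `[0, 1]`.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of length `n_steps` with values in
#'   `0:(nrow(transition_matrix) - 1)`.
#' @examples
#' simulate_markov_chain(10, matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
#'                       seed = 1)
#' @export
simulate_markov_chain <- function(n_steps, transition_matrix, seed = NULL) {
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1)
    stop("'n_steps' must be a positive integer")
  n_steps <- as.integer(n_steps)
  P <- as.matrix(transition_matrix)
  if (nrow(P) != ncol(P))
    stop("'transition_matrix' must be square")
  if (any(P < 0) || any(P > 1))
    stop("'transition_matrix' entries must lie in [0, 1]")
  if (any(abs(rowSums(P) - 1) > 1e-12))
    stop("'transition_matrix' rows must sum to 1 (within 1e-12)")
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(P)
  cum <- t(apply(P, 1L, cumsum))
  states <- integer(n_steps)
  s <- 1L
  states[1L] <- 0L
  if (n_steps > 1L) {
    u <- stats::runif(n_steps - 1L)
    for (t in 2:n_steps) {
      s <- which(u[t - 1L] <= cum[s, ])[1L]
      states[t] <- s - 1L
    }
  }
  states
}

#' Reference conformations for the toy two-state system
#'
#' Builds two pseudo-C-alpha chain conformations: a straight chain and the
#' same chain bent at its midpoint.  The bend angle is solved numerically so
#' that the minimal (superposed) RMSD between the two conformations equals
#' `separation`, mimicking a protein with an open and a closed state whose
#' interconversion a 2-D latent space must resolve.
#'
#' @param n_atoms Number of pseudo-atoms (default 50).
#' @param separation Target superposition RMSD between the two states, in
#'   Angstrom (default 5).
#' @param spacing Distance between consecutive pseudo-atoms in Angstrom
#'   (default 3.8, the canonical C-alpha -- C-alpha distance).
#' @return List with matrices `closed` and `open`, each `n_atoms x 3`.
#' @export
toy_state_centers <- function(n_atoms = 50, separation = 5, spacing = 3.8) {
  if (n_atoms < 4) stop("'n_atoms' must be at least 4")
  if (separation <= 0) stop("'separation' must be positive")
  straight <- cbind((seq_len(n_atoms) - 1) * spacing, 0, 0)
  bend <- function(theta) {
    xyz <- straight
    pivot <- straight[ceiling(n_atoms / 2), ]
    idx <- seq(ceiling(n_atoms / 2) + 1L, n_atoms)
    R <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3)
    xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, pivot) %*% R,
                        2, pivot, `+`)
    xyz
  }
  f <- function(theta) superposition_rmsd(bend(theta), straight) - separation
  if (f(pi * 0.9) < 0)
    stop("'separation' unreachable for this chain; reduce it or add atoms")
  theta <- stats::uniroot(f, c(1e-6, pi * 0.9), tol = 1e-10)$root
  list(closed = straight, open = bend(theta))
}

## uniform random rotation from SO(3) via a normalized Gaussian quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Generate a synthetic two-state trajectory
#'
#' Draws `n_frames` conformations around two reference structures.  The
#' active state follows a symmetric two-state Markov chain with per-step
#' switching probability `switch_prob`, started in state 0; each coordinate
#' receives independent Gaussian noise of standard deviation `noise_sigma`.
#' With `rigid_motion = TRUE` every frame is additionally rotated by an
#' independent uniform random rotation and translated uniformly within a
#' cube of half-width `box` Angstrom, emulating the arbitrary global pose of
#' raw MD frames; alignment (see [align_to_first()]) removes this motion
#' exactly.
#'
#' @param n_frames Number of frames (>= 2).
#' @param n_atoms Number of pseudo-atoms; ignored when `state_centers` is
#'   supplied.
#' @param state_centers Optional list of two `n_atoms x 3` matrices (states 0
#'   and 1); defaults to [toy_state_centers()].
#' @param noise_sigma Positive per-coordinate Gaussian noise SD in Angstrom.
#' @param switch_prob Per-step probability of switching state, in `[0, 1]`.
#' @param rigid_motion Apply a random rotation + translation per frame?
#' @param box Half-width (Angstrom) of the uniform translation cube used
#'   when `rigid_motion = TRUE`.
#' @param seed Optional integer seed; a single seeded RNG stream drives the
#'   chain, the noise and the rigid motions.
#' @return List with elements `ensemble` (a [traj_ensemble()]), `labels`
#'   (integer 0/1 per frame), `centers` (the two reference structures) and,
#'   when `rigid_motion = TRUE`, `xyz_raw` (coordinates before the rigid
#'   motion was applied).
#' @export
two_state_trajectory <- function(n_frames, n_atoms = 50, state_centers = NULL,
                                 noise_sigma = 0.5, switch_prob = 0.05,
                                 rigid_motion = FALSE, box = 10, seed = NULL) {
  if (!is.numeric(n_frames) || n_frames < 2)
    stop("'n_frames' must be an integer >= 2")
  if (!is.numeric(noise_sigma) || noise_sigma <= 0)
    stop("'noise_sigma' must be positive")
  if (switch_prob < 0 || switch_prob > 1)
    stop("'switch_prob' must lie in [0, 1]")
  n_frames <- as.integer(n_frames)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state_centers)) state_centers <- toy_state_centers(n_atoms)
  if (length(state_centers) != 2L)
    stop("'state_centers' must contain exactly two conformations")
  c0 <- as.matrix(state_centers[[1L]])
  c1 <- as.matrix(state_centers[[2L]])
  if (!identical(dim(c0), dim(c1)) || ncol(c0) != 3L)
    stop("state centers must be matching n_atoms x 3 matrices")
  if (superposition_rmsd(c0, c1) <= 0)
    stop("the two state centers must be distinct structures")
  n_atoms <- nrow(c0)

  P <- matrix(c(1 - switch_prob, switch_prob,
                switch_prob, 1 - switch_prob), 2, 2, byrow = TRUE)
  labels <- simulate_markov_chain(n_frames, P)
  xyz <- array(0, c(n_frames, n_atoms, 3L))
  for (i in seq_len(n_frames)) {
    centre <- if (labels[i] == 0L) c0 else c1
    xyz[i, , ] <- centre + matrix(stats::rnorm(3L * n_atoms, sd = noise_sigma),
                                  n_atoms, 3L)
  }
  out <- list(labels = labels, centers = list(c0, c1))
  if (rigid_motion) {
    out$xyz_raw <- xyz
    moved <- xyz
    for (i in seq_len(n_frames)) {
      R <- random_rotation()
      tr <- stats::runif(3, -box, box)
      moved[i, , ] <- sweep(xyz[i, , ] %*% R, 2, tr, `+`)
    }
    xyz <- moved
  }
  out$ensemble <- traj_ensemble(xyz)
  out[c("ensemble", "labels", "centers",
        if (rigid_motion) "xyz_raw")]
}
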