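# Shared fixtures, built once per test run.  The trained toy model is cached
# because several files probe the same fitted VAE from different angles.

.fixture_cache <- new.env(parent = emptyenv())

## two-state 50-atom toy system with rigid motion, aligned, featurized,
## split 75/25 and fitted with the default 4-hidden-layer VAE
toy_fit_fixture <- function() {
  if (is.null(.fixture_cache$toy)) {
    sim <- two_state_trajectory(600, n_atoms = 50, noise_sigma = 0.5,
                                switch_prob = 0.05, rigid_motion = TRUE,
                                seed = 42)
    traj <- align_to_first(sim$ensemble)
    fm <- featurize(traj)
    split <- stride_split(600, 4)
    fit <- traj_vae(fm, kind = "vae", epochs = 80, seed = 7, split = split)
    .fixture_cache$toy <- list(sim = sim, traj = traj, fm = fm,
                               split = split, fit = fit)
  }
  .fixture_cache$toy
}

## small heterogeneous protein-like atom table: 7 heavy atoms, 3 hydrogens
mixed_atoms <- function() {
  data.frame(eleno = 1:10,
             elety = c("N", "CA", "C", "O", "H", "HA", "CB", "HB", "SG",
                       "OXT"),
             resid = "CYS", chain = "A",
             resno = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 2),
             stringsAsFactors = FALSE)
}

random_ensemble <- function(n_frames, n_atoms, seed = 1, atoms = NULL) {
  set.seed(seed)
  traj_ensemble(array(rnorm(n_frames * n_atoms * 3), c(n_frames, n_atoms, 3)),
                atoms = atoms)
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}
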