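# Latent-space exploration: domain-angle collective variables, interpolated
# candidate points between metastable-state centroids, decoding latent
# points to PDB seed structures, and the plot-ready latent map table.

#' Define a domain angle from two vectors of residue ranges
#'
#' A domain angle is the angle between two vectors, each running from the
#' center of mass of a "tail" residue set to the center of mass of a "head"
#' residue set — the classic construction for hinge angles such as the
#' CORE--LID and CORE--NMP angles of adenylate kinase.
#'
#' @param name Angle label.
#' @param v1,v2 Each a list with integer vectors `tail` and `head` of residue
#'   numbers (build ranges with `seq()` or `90:99`); within a vector the two
#'   sets must be non-empty and disjoint.
#' @return Object of class `angle_definition`.
#' @examples
#' angle_definition("CORE-NMP", v1 = list(tail = 90:99, head = 35:55),
#'                              v2 = list(tail = 90:99, head = 115:125))
#' @export
angle_definition <- function(name, v1, v2) {
  for (v in list(v1, v2)) {
    if (!length(v$tail) || !length(v$head))
      stop("tail and head residue sets must be non-empty")
    if (setequal(v$tail, v$head))
      stop("tail and head residue sets coincide in angle '", name, "'")
    if (length(intersect(v$tail, v$head)))
      # shared residues are legitimate in hinge definitions (a vector may
      # point from a hinge region into the domain it belongs to)
      warning("tail and head residue sets share residues in angle '",
              name, "'")
  }
  structure(list(name = name,
                 v1 = list(tail = as.integer(v1$tail),
                           head = as.integer(v1$head)),
                 v2 = list(tail = as.integer(v2$tail),
                           head = as.integer(v2$head))),
            class = "angle_definition")
}

## standard atomic masses for the mass-weighted center option
atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                   P = 30.974)

residue_center <- function(xyz, atoms, resnos, mass_weighted) {
  sel <- atoms$resno %in% resnos
  if (!any(sel)) return(NULL)
  sub <- xyz[sel, , drop = FALSE]
  if (!mass_weighted) return(colMeans(sub))
  w <- atomic_masses[toupper(atoms$element[sel])]
  w[is.na(w)] <- 12  # unknown elements weighted as carbon
  colSums(sub * w) / sum(w)
}

#' Per-frame domain angles
#'
#' For every frame, builds `V = COM(head) - COM(tail)` for each of the two
#' vectors of `adef` and returns the angle
#' `acos(V1 . V2 / (|V1| |V2|))` in degrees, in `[0, 180]`.  Centers of mass
#' are unweighted centroids of the selected atoms by default.
#'
#' @param traj A [traj_ensemble()] whose atom metadata contains all residues
#'   named in `adef`.
#' @param adef An [angle_definition()].
#' @param mass_weighted Weight atoms by standard atomic mass?
#' @return Numeric vector of angles in degrees, one per frame.
#' @export
domain_angles <- function(traj, adef, mass_weighted = FALSE) {
  stopifnot(inherits(traj, "traj_ensemble"),
            inherits(adef, "angle_definition"))
  needed <- unique(c(adef$v1$tail, adef$v1$head, adef$v2$tail, adef$v2$head))
  missing <- setdiff(needed, traj$atoms$resno)
  if (length(missing))
    stop("residues absent from the trajectory: ",
         paste(missing, collapse = ", "))
  out <- numeric(n_frames(traj))
  for (i in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, i)
    V1 <- residue_center(xyz, traj$atoms, adef$v1$head, mass_weighted) -
      residue_center(xyz, traj$atoms, adef$v1$tail, mass_weighted)
    V2 <- residue_center(xyz, traj$atoms, adef$v2$head, mass_weighted) -
      residue_center(xyz, traj$atoms, adef$v2$tail, mass_weighted)
    n1 <- sqrt(sum(V1^2)); n2 <- sqrt(sum(V2^2))
    if (n1 == 0 || n2 == 0)
      stop("zero-length angle vector in frame ", i)
    out[i] <- acos(max(-1, min(1, sum(V1 * V2) / (n1 * n2)))) * 180 / pi
  }
  out
}

#' Read angle definitions from a JSON config
#'
#' The config is a JSON array of objects with fields `name`, `v1_tail`,
#' `v1_head`, `v2_tail`, `v2_head`, each residue set written as a string of
#' comma-separated ranges (`"90:99"` or `"95:101,106:108"`).  An example
#' config with the adenylate-kinase CORE--NMP and CORE--LID angle vectors is
#' shipped as `system.file("extdata", "adk_angles.json", package =
#' "latentmd")`.
#'
#' @param path JSON file.
#' @return List of [angle_definition()] objects, named by angle.
#' @export
read_angle_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  parse_set <- function(s)
    unlist(lapply(strsplit(s, ",")[[1L]], function(r) parse_ranges(trimws(r))))
  out <- lapply(seq_len(nrow(cfg)), function(i)
    angle_definition(cfg$name[i],
                     v1 = list(tail = parse_set(cfg$v1_tail[i]),
                               head = parse_set(cfg$v1_head[i])),
                     v2 = list(tail = parse_set(cfg$v2_tail[i]),
                               head = parse_set(cfg$v2_head[i]))))
  names(out) <- cfg$name
  out
}

#' Candidate latent points between two state regions
#'
#' Deterministic surrogate for picking points "in the middle" of two
#' metastable regions of the latent space: points are placed at equally
#' spaced interpolation parameters `i / (n_points + 1)` along the segment
#' between the centroids of the two labelled frame groups, optionally
#' jittered with seeded Gaussian noise.  With `n_points = 1` and no jitter
#' the result is the exact centroid midpoint.
#'
#' @param embedding Frames-by-latent matrix (e.g. from [encode()]).
#' @param idx_a,idx_b Frame index vectors of the two groups (non-empty).
#' @param n_points Number of candidate points (default 1).
#' @param jitter SD of Gaussian jitter added to each coordinate (default 0).
#' @param seed Optional seed for the jitter.
#' @return `n_points x latent_dim` matrix of latent coordinates.
#' @export
midpoint_candidates <- function(embedding, idx_a, idx_b, n_points = 1,
                                jitter = 0, seed = NULL) {
  Z <- as.matrix(embedding)
  if (!length(idx_a) || !length(idx_b))
    stop("both frame groups must be non-empty")
  ca <- colMeans(Z[idx_a, , drop = FALSE])
  cb <- colMeans(Z[idx_b, , drop = FALSE])
  if (sqrt(sum((ca - cb)^2)) < 1e-12)
    stop("group centroids coincide; the interpolation direction is undefined")
  tpar <- seq_len(n_points) / (n_points + 1)
  pts <- outer(rep(1, n_points), ca) + outer(tpar, cb - ca)
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    pts <- pts + matrix(stats::rnorm(length(pts), sd = jitter), nrow(pts))
  }
  colnames(pts) <- paste0("z", seq_len(ncol(pts)))
  pts
}

#' Decode latent points to PDB seed structures
#'
#' Decodes each latent point, inverts the model scaler to Angstrom, writes
#' the coordinates onto the template's atom records, and saves one
#' single-model PDB per point — restart structures for new MD simulations.
#'
#' @param model A fitted [traj_vae()] carrying a scaler.
#' @param points Latent coordinates, `m x latent_dim` matrix or vector.
#' @param template A [traj_ensemble()] whose first frame supplies the atom
#'   records; `3 * n_atoms` must equal the model input width.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix (default `"seed"`).
#' @return Character vector of the written file paths, invisibly.
#' @export
decode_to_pdb <- function(model, points, template, dir = ".",
                          prefix = "seed") {
  stopifnot(inherits(model, "traj_vae"), inherits(template, "traj_ensemble"))
  if (is.null(model$scaler))
    stop("the model carries no scaler; fit it on a feature_matrix")
  if (3L * n_atoms(template) != model$input_dim)
    stop("template atom count (", n_atoms(template),
         ") does not match the model input width (", model$input_dim, ")")
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  Y <- decode(model, points)
  coords <- defeaturize(Y, model$scaler, as_ensemble = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    tr <- traj_ensemble(unflatten_frames(coords[i, , drop = FALSE]),
                        template$atoms)
    paths[i] <- file.path(dir, sprintf("%s_%d.pdb", prefix, i))
    write_trajectory(tr, paths[i], format = "pdb")
  }
  invisible(paths)
}

#' Plot-ready latent map table
#'
#' Joins the 2-D embedding with per-frame labels and collective-variable
#' values into one tidy table for external plotting.
#'
#' @param embedding Frames-by-latent matrix.
#' @param labels Optional per-frame labels (length = frames).
#' @param angles Optional named list (or data frame) of per-frame CV vectors,
#'   each of length = frames.
#' @return Data frame with columns `frame`, `z1`, `z2`, ..., `label` and one
#'   column per CV, rows in frame order.
#' @export
latent_map_report <- function(embedding, labels = NULL, angles = NULL) {
  Z <- as.matrix(embedding)
  n <- nrow(Z)
  out <- data.frame(frame = seq_len(n))
  for (j in seq_len(ncol(Z))) out[[paste0("z", j)]] <- Z[, j]
  if (!is.null(labels)) {
    if (length(labels) != n)
      stop("'labels' length (", length(labels), ") != frames (", n, ")")
    out$label <- labels
  }
  if (!is.null(angles)) {
    angles <- as.data.frame(angles)
    if (nrow(angles) != n)
      stop("CV length (", nrow(angles), ") != frames (", n, ")")
    out <- cbind(out, angles)
  }
  out
}
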