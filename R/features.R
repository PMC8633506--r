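# MinMax featurization of aligned Cartesian coordinates, its exact inverse,
# the strided train/test split, and the scaler sidecar format.

#' MinMax-featurize a trajectory
#'
#' Flattens an (aligned) trajectory to an `n_frames x (3 * n_atoms)` matrix
#' (columns `x1 y1 z1 x2 ...`) and rescales every column linearly to `[0, 1]`
#' using its own minimum and maximum over frames:
#' `value = (c - min_c) / (max_c - min_c)`.  Columns whose coordinate never
#' changes (`max_c == min_c`) are undefined under that map; they are set to 0
#' and flagged, with a warning.
#'
#' @param traj A [traj_ensemble()], or a numeric frames-by-coordinates matrix.
#' @param scaler Optional scaler (as stored in a previous `featurize()`
#'   result) to apply instead of fitting new column extrema, e.g. to project
#'   held-out frames with the training scaler.
#' @return Object of class `feature_matrix`: list with `values` (the scaled
#'   matrix), `scaler` (data frame `column`, `min`, `max`, `constant`),
#'   `atom_index` (feature column -> atom / axis) and `atoms` (metadata for
#'   inversion back to structures).
#' @seealso [defeaturize()] for the exact inverse map.
#' @export
featurize <- function(traj, scaler = NULL) {
  if (inherits(traj, "traj_ensemble")) {
    values <- flatten_frames(traj$xyz)
    atoms <- traj$atoms
  } else {
    values <- as.matrix(traj)
    atoms <- NULL
  }
  if (!all(is.finite(values))) stop("coordinates contain NaN/Inf values")
  p <- ncol(values)
  if (is.null(scaler)) {
    mins <- apply(values, 2L, min)
    maxs <- apply(values, 2L, max)
    constant <- maxs == mins
    scaler <- data.frame(column = seq_len(p), min = mins, max = maxs,
                         constant = constant)
  } else {
    scaler <- as_scaler(scaler)
    if (nrow(scaler) != p)
      stop("scaler width (", nrow(scaler), ") does not match feature width (",
           p, ")")
  }
  rng <- scaler$max - scaler$min
  scaled <- sweep(values, 2L, scaler$min)
  scaled[, !scaler$constant] <- sweep(scaled[, !scaler$constant, drop = FALSE],
                                      2L, rng[!scaler$constant], `/`)
  if (any(scaler$constant)) {
    scaled[, scaler$constant] <- 0
    warning(sum(scaler$constant),
            " constant feature column(s) mapped to 0 (min == max)")
  }
  atom_index <- if (p %% 3L == 0L)
    data.frame(column = seq_len(p),
               atom = rep(seq_len(p %/% 3L), each = 3L),
               axis = rep(c("x", "y", "z"), p %/% 3L))
  structure(list(values = scaled, scaler = scaler, atom_index = atom_index,
                 atoms = atoms),
            class = "feature_matrix")
}

as_scaler <- function(scaler) {
  if (inherits(scaler, "feature_matrix")) scaler <- scaler$scaler
  scaler <- as.data.frame(scaler)
  stopifnot(all(c("min", "max") %in% names(scaler)))
  if (is.null(scaler$constant)) scaler$constant <- scaler$max == scaler$min
  scaler
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$values), "frames x", ncol(x$values),
      "features (MinMax-scaled)\n")
  if (any(x$scaler$constant))
    cat("  constant columns:", sum(x$scaler$constant), "\n")
  invisible(x)
}

#' Invert MinMax features back to coordinates
#'
#' Applies `coordinate = value * (max_c - min_c) + min_c` per column.  Values
#' outside `[0, 1]` (e.g. decoder outputs beyond the training range) are
#' mapped linearly without clipping.  Constant columns recover their stored
#' coordinate exactly.
#'
#' @param values Numeric matrix (or vector treated as one frame) of scaled
#'   features, or a `feature_matrix`.
#' @param scaler Scaler to invert with; taken from `values` when it is a
#'   `feature_matrix`.
#' @param atoms Optional atom metadata for the returned ensemble.
#' @param as_ensemble Return a [traj_ensemble()] (default) or the raw
#'   frames-by-coordinates matrix.
#' @return A [traj_ensemble()] or coordinate matrix in Angstrom.
#' @export
defeaturize <- function(values, scaler = NULL, atoms = NULL,
                        as_ensemble = TRUE) {
  if (inherits(values, "feature_matrix")) {
    if (is.null(scaler)) scaler <- values$scaler
    if (is.null(atoms)) atoms <- values$atoms
    values <- values$values
  }
  if (is.null(scaler)) stop("a scaler is required to invert features")
  scaler <- as_scaler(scaler)
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  values <- as.matrix(values)
  if (ncol(values) != nrow(scaler))
    stop("value width (", ncol(values), ") does not match scaler length (",
         nrow(scaler), ")")
  coords <- sweep(sweep(values, 2L, scaler$max - scaler$min, `*`),
                  2L, scaler$min, `+`)
  if (!as_ensemble) return(coords)
  traj_ensemble(unflatten_frames(coords), atoms)
}

#' Strided train/test split
#'
#' Every frame whose 1-based index is a multiple of `test_stride` goes to the
#' test set, the rest to the training set; with `test_stride = 4` this is a
#' 75% / 25% split.
#'
#' @param n_frames Total number of frames (>= `test_stride`).
#' @param test_stride Integer >= 2 (default 4).
#' @return Object of class `split_index`: list with integer vectors `train`
#'   and `test`, disjoint and covering `1:n_frames`.
#' @examples
#' stride_split(8)   # test frames 4 and 8
#' @export
stride_split <- function(n_frames, test_stride = 4) {
  if (!is.numeric(test_stride) || test_stride < 2)
    stop("'test_stride' must be an integer >= 2")
  if (n_frames < test_stride)
    stop("'n_frames' must be at least 'test_stride'")
  test_stride <- as.integer(test_stride)
  n_frames <- as.integer(n_frames)
  test <- seq.int(test_stride, n_frames, by = test_stride)
  structure(list(train = setdiff(seq_len(n_frames), test), test = test),
            class = "split_index")
}

#' @export
print.split_index <- function(x, ...) {
  n <- length(x$train) + length(x$test)
  cat(sprintf("Split: %d train / %d test (%.1f%% test)\n",
              length(x$train), length(x$test), 100 * length(x$test) / n))
  invisible(x)
}

#' Persist / restore a feature scaler
#'
#' The scaler is stored as a small JSON sidecar with one record per feature
#' column (`column`, `min`, `max`, `constant`) so that decoded latent points
#' can be inverted to Angstrom coordinates in a later session.
#'
#' @param scaler A scaler data frame or `feature_matrix`.
#' @param path JSON file path.
#' @return `write_scaler()` returns `path` invisibly; `read_scaler()` returns
#'   the scaler data frame.
#' @export
write_scaler <- function(scaler, path) {
  jsonlite::write_json(as_scaler(scaler), path, digits = NA)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  as_scaler(jsonlite::fromJSON(path))
}
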