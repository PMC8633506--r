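# Trajectory container, PDB / flat-matrix I/O, atom selection and alignment.

#' Construct a trajectory ensemble
#'
#' The central container of the package: per-frame Cartesian coordinates of a
#' fixed atom set, plus per-atom metadata in the style of PDB ATOM records.
#'
#' @param xyz Either an `n_frames x n_atoms x 3` array or a single
#'   `n_atoms x 3` matrix (treated as one frame).  Coordinates in Angstrom;
#'   must be finite.
#' @param atoms Optional data frame with one row per atom and columns
#'   `eleno`, `elety` (atom name), `resid` (residue name), `chain`, `resno`
#'   and `element`.  Defaults to generic C-alpha pseudo-atoms.
#' @param frame_ids Optional integer frame identifiers (default `1:n_frames`).
#' @return Object of class `traj_ensemble`.
#' @export
traj_ensemble <- function(xyz, atoms = NULL, frame_ids = NULL) {
  if (is.matrix(xyz)) {
    if (ncol(xyz) != 3L) stop("single-frame 'xyz' must be an n_atoms x 3 matrix")
    xyz <- array(xyz, c(1L, nrow(xyz), 3L))
  }
  if (!is.array(xyz) || length(dim(xyz)) != 3L || dim(xyz)[3L] != 3L)
    stop("'xyz' must be an n_frames x n_atoms x 3 array")
  if (!all(is.finite(xyz)))
    stop("coordinates contain NaN/Inf values")
  n_frames <- dim(xyz)[1L]
  n_atoms <- dim(xyz)[2L]
  if (n_frames < 1L) stop("at least one frame is required")
  if (is.null(atoms)) atoms <- pseudo_ca_atoms(n_atoms)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) != n_atoms)
    stop("'atoms' must have one row per atom (", n_atoms, ")")
  needed <- c("eleno", "elety", "resid", "chain", "resno")
  miss <- setdiff(needed, names(atoms))
  if (length(miss))
    stop("'atoms' is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$element) || all(is.na(atoms$element)))
    atoms$element <- guess_element(atoms$elety)
  if (is.null(frame_ids)) frame_ids <- seq_len(n_frames)
  structure(list(xyz = xyz, atoms = atoms,
                 frame_ids = as.integer(frame_ids)),
            class = "traj_ensemble")
}

pseudo_ca_atoms <- function(n_atoms) {
  data.frame(eleno = seq_len(n_atoms), elety = "CA", resid = "ALA",
             chain = "A", resno = seq_len(n_atoms), element = "C",
             stringsAsFactors = FALSE)
}

## element from an atom name: first alphabetic character that is not a digit;
## names like "1HG1" resolve to H
guess_element <- function(elety) {
  el <- sub("^[0-9' ]*", "", trimws(elety))
  toupper(substr(el, 1L, 1L))
}

#' @export
print.traj_ensemble <- function(x, ...) {
  cat("Trajectory ensemble:", dim(x$xyz)[1L], "frames x",
      dim(x$xyz)[2L], "atoms\n")
  cat("  atom names:", paste(utils::head(unique(x$atoms$elety), 6),
                             collapse = " "),
      if (length(unique(x$atoms$elety)) > 6) "..." else "", "\n")
  cat("  residues:", length(unique(paste(x$atoms$chain, x$atoms$resno))), "\n")
  invisible(x)
}

#' @export
dim.traj_ensemble <- function(x) dim(x$xyz)

n_frames <- function(traj) dim(traj$xyz)[1L]
n_atoms <- function(traj) dim(traj$xyz)[2L]

## one frame as an n_atoms x 3 matrix
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, , ], ncol = 3L)
}

#' Read a trajectory
#'
#' Reads either a multi-model PDB file (parsed with \pkg{bio3d}) or a flat
#' whitespace/comma-delimited coordinate matrix with one frame per row and
#' columns `x1 y1 z1 x2 y2 z2 ...`.  Flat-matrix input yields synthesized
#' generic C-alpha atom metadata.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"pdb"` or `"matrix"`.
#' @return A [traj_ensemble()].
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "matrix"
  if (format == "pdb") {
    check_model_atom_counts(path)
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    nf <- nrow(xyz)
    na <- ncol(xyz) / 3L
    arr <- array(0, c(nf, na, 3L))
    for (i in seq_len(nf)) arr[i, , ] <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
    at <- pdb$atom
    atoms <- data.frame(eleno = at$eleno, elety = at$elety, resid = at$resid,
                        chain = ifelse(is.na(at$chain) | at$chain == "",
                                       "A", at$chain),
                        resno = at$resno,
                        element = if (!is.null(at$elesy) &&
                                      !all(is.na(at$elesy)) &&
                                      !all(trimws(at$elesy) == ""))
                                    trimws(at$elesy)
                                  else guess_element(at$elety),
                        stringsAsFactors = FALSE)
    traj_ensemble(arr, atoms)
  } else {
    m <- as.matrix(utils::read.table(path, header = FALSE,
                                     sep = if (any(grepl(",",
                                       readLines(path, n = 1L)))) "," else ""))
    storage.mode(m) <- "double"
    if (ncol(m) %% 3L != 0L)
      stop("flat coordinate matrix must have a multiple of 3 columns, got ",
           ncol(m))
    na <- ncol(m) %/% 3L
    arr <- array(0, c(nrow(m), na, 3L))
    for (i in seq_len(nrow(m))) arr[i, , ] <- matrix(m[i, ], ncol = 3L,
                                                     byrow = TRUE)
    traj_ensemble(arr)
  }
}

## fail early, with the offending model, when models disagree in atom count
check_model_atom_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) < 2L) return(invisible(TRUE))
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts))
    stop("malformed multi-model PDB: ", length(model_starts), " MODEL but ",
         length(model_ends), " ENDMDL records in ", path)
  counts <- mapply(function(s, e)
    sum(grepl("^(ATOM|HETATM)", lines[s:e])), model_starts, model_ends)
  if (length(unique(counts)) != 1L)
    stop("inconsistent atom counts across models in ", path, ": model ",
         which(counts != counts[1L])[1L], " has ",
         counts[which(counts != counts[1L])[1L]], " atoms, model 1 has ",
         counts[1L])
  invisible(TRUE)
}

#' Write a trajectory
#'
#' Writes a multi-model PDB (fixed-width ATOM records, one MODEL per frame)
#' or a flat coordinate matrix with one frame per row.
#'
#' @param traj A [traj_ensemble()].
#' @param path Output file.
#' @param format `"pdb"` or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "matrix")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "traj_ensemble"))
  if (format == "pdb") {
    con <- file(path, "w")
    on.exit(close(con))
    nf <- n_frames(traj)
    for (i in seq_len(nf)) {
      if (nf > 1L) writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(pdb_atom_lines(frame_coords(traj, i), traj$atoms), con)
      if (nf > 1L) writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    m <- flatten_frames(traj$xyz)
    utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

pdb_atom_lines <- function(xyz, atoms) {
  name <- ifelse(nchar(atoms$elety) <= 3L,
                 formatC(paste0(" ", atoms$elety), width = -4),
                 substr(atoms$elety, 1L, 4L))
  sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$eleno %% 100000L, name, substr(atoms$resid, 1L, 3L),
          substr(atoms$chain, 1L, 1L), atoms$resno %% 10000L,
          xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0, atoms$element)
}

## frames x atoms x 3 array -> frames x (3 atoms) matrix, columns x1 y1 z1 x2 ..
flatten_frames <- function(xyz) {
  nf <- dim(xyz)[1L]; na <- dim(xyz)[2L]
  m <- matrix(0, nf, 3L * na)
  for (ax in 1:3) m[, seq(ax, 3L * na, by = 3L)] <- xyz[, , ax]
  m
}

unflatten_frames <- function(m, n_atoms = ncol(m) %/% 3L) {
  m <- as.matrix(m)
  arr <- array(0, c(nrow(m), n_atoms, 3L))
  for (ax in 1:3) arr[, , ax] <- m[, seq(ax, 3L * n_atoms, by = 3L)]
  arr
}

#' Select atoms from a trajectory
#'
#' Supported selection strings are conjunctions (joined with `" and "`) of:
#' `"all"`, `"name <N1> <N2> ..."`, `"chain <C1> ..."`,
#' `"resno <a>:<b>"` (or a list of numbers), `"element <E>"`, `"noh"` /
#' `"not element H"`, and any clause prefixed by `"not "`.
#'
#' @param traj A [traj_ensemble()].
#' @param selection Selection string, or a logical/integer atom index vector.
#' @return The sub-ensemble of matching atoms (order preserved).
#' @examples
#' tr <- two_state_trajectory(4, n_atoms = 10, seed = 1)$ensemble
#' select_atoms(tr, "name CA")
#' @export
select_atoms <- function(traj, selection) {
  stopifnot(inherits(traj, "traj_ensemble"))
  mask <- selection_mask(traj$atoms, selection)
  if (!any(mask)) stop("selection matches no atoms: cannot featurize zero atoms")
  traj_ensemble(traj$xyz[, mask, , drop = FALSE],
                traj$atoms[mask, , drop = FALSE], traj$frame_ids)
}

selection_mask <- function(atoms, selection) {
  if (is.logical(selection)) {
    if (length(selection) != nrow(atoms))
      stop("logical selection has wrong length")
    return(selection)
  }
  if (is.numeric(selection)) {
    mask <- rep(FALSE, nrow(atoms)); mask[selection] <- TRUE
    return(mask)
  }
  if (!is.character(selection) || length(selection) != 1L)
    stop("'selection' must be a string or an index vector")
  clauses <- strsplit(trimws(selection), "\\s+and\\s+")[[1L]]
  mask <- rep(TRUE, nrow(atoms))
  for (cl in clauses) mask <- mask & clause_mask(atoms, trimws(cl))
  mask
}

clause_mask <- function(atoms, cl) {
  if (grepl("^not\\s+", cl))
    return(!clause_mask(atoms, sub("^not\\s+", "", cl)))
  if (cl == "all") return(rep(TRUE, nrow(atoms)))
  if (cl == "noh") return(clause_mask(atoms, "not element H"))
  toks <- strsplit(cl, "\\s+")[[1L]]
  key <- toks[1L]; args <- toks[-1L]
  if (!length(args)) stop("selection clause needs arguments: '", cl, "'")
  switch(key,
    name = trimws(atoms$elety) %in% args,
    chain = trimws(atoms$chain) %in% args,
    element = toupper(trimws(atoms$element)) %in% toupper(args),
    resno = atoms$resno %in% parse_ranges(args),
    resid = trimws(atoms$resid) %in% args,
    stop("unsupported selection clause: '", cl, "'")
  )
}

## "90:99" / "90-99" / "90 91 92" -> integer vector
parse_ranges <- function(args) {
  out <- integer(0)
  for (a in args) {
    if (grepl("[:-]", a)) {
      ab <- as.integer(strsplit(a, "[:-]")[[1L]])
      out <- c(out, seq(ab[1L], ab[2L]))
    } else out <- c(out, as.integer(a))
  }
  out
}

#' Align all frames to the first frame
#'
#' Rigid-body superposition (Kabsch least-squares fit, rotations only — no
#' reflection) of every frame onto frame 1.  The rotation and translation are
#' determined on the `fit_selection` atoms and applied to all atoms, so
#' internal geometry is untouched.
#'
#' @param traj A [traj_ensemble()].
#' @param fit_selection Selection (see [select_atoms()]) used for the fit;
#'   needs at least 3 non-collinear atoms.
#' @return The aligned [traj_ensemble()]; frame 1 is returned unchanged.
#' @export
align_to_first <- function(traj, fit_selection = "all") {
  stopifnot(inherits(traj, "traj_ensemble"))
  mask <- selection_mask(traj$atoms, fit_selection)
  if (sum(mask) < 3L)
    stop("alignment needs at least 3 fit atoms, got ", sum(mask))
  ref <- frame_coords(traj, 1L)[mask, , drop = FALSE]
  sv <- svd(scale(ref, scale = FALSE))$d
  if (sv[2L] < 1e-8 * max(sv[1L], 1))
    stop("fit atoms in the reference frame are (near-)collinear; ",
         "the rotation is not determined")
  xyz <- traj$xyz
  for (i in seq_len(n_frames(traj))[-1L]) {
    fr <- frame_coords(traj, i)
    k <- kabsch(fr[mask, , drop = FALSE], ref)
    xyz[i, , ] <- sweep(fr %*% k$R, 2, k$t, `+`)
  }
  traj_ensemble(xyz, traj$atoms, traj$frame_ids)
}
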