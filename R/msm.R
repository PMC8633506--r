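# Markov state model analysis of collective-variable trajectories:
# k-means discretization, lagged transition counting that never crosses
# trajectory-segment joins, non-reversible maximum-likelihood transition
# matrices on the largest connected set, implied relaxation timescales
# t_i(tau) = -tau / ln(lambda_i), and bootstrap confidence intervals.

#' Construct a discrete trajectory
#'
#' Wraps per-frame cluster assignments with the segment structure needed so
#' that transition counting never pairs frames across the joins of
#' concatenated trajectories.
#'
#' @param assignments Integer vector of cluster indices in `1:n_clusters`.
#' @param n_clusters Number of clusters (default `max(assignments)`).
#' @param segments Integer vector of segment lengths summing to
#'   `length(assignments)` (default: one segment).
#' @param centers Optional `n_clusters x d` cluster-center matrix.
#' @return Object of class `discrete_traj`.
#' @export
discrete_trajectory <- function(assignments, n_clusters = max(assignments),
                                segments = length(assignments),
                                centers = NULL) {
  assignments <- as.integer(assignments)
  if (any(assignments < 1L) || any(assignments > n_clusters))
    stop("assignments must lie in 1:n_clusters")
  if (sum(segments) != length(assignments))
    stop("'segments' must partition the frame sequence (sum = ",
         length(assignments), ")")
  structure(list(assignments = assignments,
                 n_clusters = as.integer(n_clusters),
                 segments = as.integer(segments), centers = centers),
            class = "discrete_traj")
}

#' @export
print.discrete_traj <- function(x, ...) {
  cat("Discrete trajectory:", length(x$assignments), "frames,",
      x$n_clusters, "clusters,", length(x$segments), "segment(s)\n")
  invisible(x)
}

## k-means++ seeding (Arthur & Vassilvitskii): each new center drawn with
## probability proportional to the squared distance to the nearest chosen one
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in seq_len(k)[-1L]) {
    p <- d2 / sum(d2)
    centers[j, ] <- X[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

#' Discretize collective variables by k-means
#'
#' Seeded k-means (k-means++ initialization, several restarts, Lloyd
#' iterations via [stats::kmeans()]) on the CV points; every frame is
#' assigned to its nearest center.
#'
#' @param cvs Frames-by-dimensions numeric matrix (a vector is treated as
#'   one-dimensional).
#' @param n_clusters Number of clusters (<= number of frames).
#' @param seed Integer seed (default 1).
#' @param nstart Independent k-means++ restarts, best inertia kept
#'   (default 10).
#' @param segments Segment lengths for concatenated trajectories (default:
#'   one segment).
#' @return A [discrete_trajectory()] with centers attached.
#' @export
discretize_kmeans <- function(cvs, n_clusters, seed = 1, nstart = 10,
                              segments = NULL) {
  X <- as.matrix(cvs)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n_clusters > n)
    stop("'n_clusters' (", n_clusters, ") exceeds the number of frames (",
         n, ")")
  if (is.null(segments)) segments <- n
  set.seed(seed)
  if (n_clusters == n)   # every frame its own cluster
    return(discrete_trajectory(seq_len(n), n_clusters, segments,
                               centers = X))
  best <- NULL
  for (r in seq_len(nstart)) {
    init <- kmeanspp_centers(X, n_clusters)
    km <- suppressWarnings(
      stats::kmeans(X, centers = init, iter.max = 100L))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  discrete_trajectory(best$cluster, n_clusters, segments,
                      centers = best$centers)
}

#' Count lagged transitions
#'
#' `C[i, j]` is the number of frame pairs `(t, t + lag)` assigned to
#' clusters `(i, j)`.  Windows never cross segment boundaries.  `"sliding"`
#' counts every admissible `t`; `"strided"` advances `t` by `lag`, so each
#' frame enters at most one pair.
#'
#' @param dtraj A [discrete_trajectory()].
#' @param lag Positive integer lag time in frames; at least one segment must
#'   be longer than `lag`.
#' @param mode `"sliding"` (default) or `"strided"`.
#' @return `n_clusters x n_clusters` integer count matrix.
#' @export
count_transitions <- function(dtraj, lag, mode = c("sliding", "strided")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dtraj, "discrete_traj"))
  if (lag < 1L) stop("'lag' must be at least 1")
  k <- dtraj$n_clusters
  C <- matrix(0L, k, k)
  offset <- 0L
  any_window <- FALSE
  for (len in dtraj$segments) {
    s <- dtraj$assignments[offset + seq_len(len)]
    offset <- offset + len
    if (len <= lag) next
    any_window <- TRUE
    starts <- if (mode == "sliding") seq_len(len - lag) else
      seq(1L, len - lag, by = lag)
    a <- s[starts]; b <- s[starts + lag]
    C <- C + unclass(table(factor(a, levels = seq_len(k)),
                           factor(b, levels = seq_len(k))))
  }
  if (!any_window)
    stop("lag ", lag, " is not shorter than any trajectory segment")
  storage.mode(C) <- "integer"
  dimnames(C) <- NULL
  C
}

#' Maximum-likelihood transition matrix
#'
#' Restricts the count matrix to its largest strongly connected component
#' (states outside it are reported as trimmed) and row-normalizes:
#' `T[i, j] = C[i, j] / sum_j C[i, j]` — the non-reversible maximum
#' likelihood estimator.
#'
#' @param counts Non-negative square count matrix.
#' @return List with `T` (row-stochastic matrix over the active set),
#'   `active` (indices of retained states) and `trimmed` (dropped states).
#' @export
transition_matrix <- function(counts) {
  C <- as.matrix(counts)
  if (nrow(C) != ncol(C) || any(C < 0))
    stop("'counts' must be a square non-negative matrix")
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  ## among the strongly connected components keep the one with most states;
  ## states never visited (zero row and column) form singleton components
  sizes <- tabulate(comp$membership, comp$no)
  keep <- which(comp$membership == which.max(sizes))
  visited <- which(rowSums(C) + colSums(C) > 0)
  keep <- intersect(keep, visited)
  if (!length(keep)) stop("no connected set with observed transitions")
  Csub <- C[keep, keep, drop = FALSE]
  rs <- rowSums(Csub)
  if (any(rs == 0)) stop("a retained state has no outgoing counts")
  list(T = Csub / rs, active = keep,
       trimmed = setdiff(seq_len(nrow(C)), keep))
}

## eigenvalues of a stochastic matrix sorted by decreasing magnitude;
## complex parts beyond tolerance are flagged with a warning
sorted_eigenvalues <- function(T) {
  ev <- eigen(T, only.values = TRUE)$values
  if (any(abs(Im(ev)) > 1e-8))
    warning("complex eigenvalues detected (max |Im| = ",
            format(max(abs(Im(ev)))), "); using real parts")
  Re(ev)[order(-abs(ev))]
}

#' Implied timescales from a transition matrix
#'
#' `t_i(tau) = -tau / ln(lambda_i)` for the i-th largest-magnitude
#' eigenvalue below one of the transition matrix estimated at lag `tau`.
#' Eigenvalues outside `(0, 1)` have no defined relaxation time and yield
#' `NA` with a warning rather than being dropped.
#'
#' @param T Row-stochastic matrix.
#' @param lag Lag time (frames) at which `T` was estimated.
#' @param n_timescales Number of timescales (default 1: the slowest,
#'   from the second eigenvalue).
#' @return Numeric vector of length `n_timescales`, in frame units.
#' @export
timescales_from_matrix <- function(T, lag = 1, n_timescales = 1) {
  ev <- sorted_eigenvalues(T)[-1L]          # drop the stationary eigenvalue
  ev <- ev[seq_len(min(n_timescales, length(ev)))]
  out <- rep(NA_real_, n_timescales)
  ok <- !is.na(ev) & ev > 0 & ev < 1
  out[which(ok)] <- -lag / log(ev[ok])
  if (any(!ok))
    warning(sum(!ok), " eigenvalue(s) outside (0, 1); timescales set to NA")
  out
}

#' Implied timescale table across lag times
#'
#' Estimates a transition matrix at every requested lag and extracts the top
#' implied timescales.  Lag-independence of the timescales indicates
#' Markovian behaviour of the discretized dynamics.
#'
#' @param dtraj A [discrete_trajectory()].
#' @param lags Vector of positive integer lag times (frames).
#' @param n_timescales Timescales per lag (default 1).
#' @param mode Counting mode, see [count_transitions()].
#' @param frame_time Optional physical time per frame; timescales are
#'   multiplied by it (default 1: frame units).
#' @return Data frame with columns `lag`, `t1`, ..., `t<n_timescales>`.
#' @export
implied_timescales <- function(dtraj, lags, n_timescales = 1,
                               mode = "sliding", frame_time = 1) {
  rows <- lapply(lags, function(lag) {
    tm <- transition_matrix(count_transitions(dtraj, lag, mode))
    ts <- timescales_from_matrix(tm$T, lag, n_timescales) * frame_time
    as.data.frame(c(list(lag = lag), stats::setNames(as.list(ts),
                                                     paste0("t", seq_along(ts)))))
  })
  do.call(rbind, rows)
}

#' Bootstrap confidence intervals for implied timescales
#'
#' Block bootstrap over trajectory segments: segments are resampled with
#' replacement, transitions recounted and the timescales re-estimated.  With
#' fewer than two segments a transition-pair bootstrap is used instead (the
#' counted pairs at the given lag are resampled multinomially), with a
#' warning.
#'
#' @param dtraj A [discrete_trajectory()].
#' @param lag Lag time (frames).
#' @param n_timescales Number of timescales (default 1).
#' @param n_boot Bootstrap replicates, at least 50 (default 100).
#' @param seed Integer seed (default 1).
#' @param level Confidence level (default 0.95).
#' @return Data frame with one row per timescale: `timescale` (index),
#'   `estimate`, `lower`, `upper` (percentile interval).
#' @export
bootstrap_timescale_ci <- function(dtraj, lag, n_timescales = 1,
                                   n_boot = 100, seed = 1, level = 0.95) {
  stopifnot(inherits(dtraj, "discrete_traj"))
  if (n_boot < 50) stop("'n_boot' must be at least 50")
  set.seed(seed)
  point <- timescales_from_matrix(
    transition_matrix(count_transitions(dtraj, lag))$T, lag, n_timescales)
  nseg <- length(dtraj$segments)
  boots <- matrix(NA_real_, n_boot, n_timescales)
  if (nseg >= 2L) {
    seg_list <- split(dtraj$assignments,
                      rep(seq_len(nseg), dtraj$segments))
    for (b in seq_len(n_boot)) {
      pick <- sample.int(nseg, nseg, replace = TRUE)
      dt <- discrete_trajectory(unlist(seg_list[pick]), dtraj$n_clusters,
                                segments = dtraj$segments[pick])
      boots[b, ] <- tryCatch(timescales_from_matrix(
        transition_matrix(count_transitions(dt, lag))$T, lag, n_timescales),
        error = function(e) rep(NA_real_, n_timescales))
    }
  } else {
    warning("only one trajectory segment: falling back to a ",
            "transition-pair bootstrap")
    C <- count_transitions(dtraj, lag)
    N <- sum(C)
    p <- as.vector(C) / N
    for (b in seq_len(n_boot)) {
      Cb <- matrix(stats::rmultinom(1L, N, p), nrow(C), ncol(C))
      boots[b, ] <- tryCatch(timescales_from_matrix(
        transition_matrix(Cb)$T, lag, n_timescales),
        error = function(e) rep(NA_real_, n_timescales))
    }
  }
  alpha <- (1 - level) / 2
  data.frame(timescale = seq_len(n_timescales), estimate = point,
             lower = apply(boots, 2L, stats::quantile, probs = alpha,
                           na.rm = TRUE),
             upper = apply(boots, 2L, stats::quantile, probs = 1 - alpha,
                           na.rm = TRUE))
}
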