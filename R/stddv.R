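#' Distance-variability (STDDV) matrix
#'
#' For every pair of selected atoms, the standard deviation of their
#' Euclidean distance time series over a frame window:
#' \deqn{D_{ij} = \sqrt{\frac{N_f}{N_f - 1}\,\langle (d_{ij} - \langle
#' d_{ij}\rangle)^2 \rangle}}
#' i.e. the Bessel-corrected sample standard deviation of
#' \eqn{d_{ij}(t) = \lVert x_i(t) - x_j(t) \rVert} over the \eqn{N_f}
#' frames of the window. STDDV is the package's proxy for "motional
#' distance": pairs inside a rigid body have \eqn{D_{ij} = 0} no matter
#' how far the body travels. The computation is two-pass (exact mean,
#' then squared deviations) for numerical robustness.
#'
#' Distances are invariant under per-frame rigid transforms, so the
#' result is identical before and after [fit_trajectory()].
#'
#' @param traj an [srd_trajectory()].
#' @param atom_indices atoms to include (1-based); default all atoms. For
#'   the clustering pipeline, pass [select_calpha()].
#' @param frame_range half-open frame window `c(start, end)` (1-based
#'   start, frames `start .. end-1`); default the whole trajectory
#'   (whole-trajectory mode, \eqn{N_f = N_t}).
#' @return symmetric matrix (nm) with zero diagonal; attributes
#'   `frame_range` and `atom_indices`.
#' @export
stddv_matrix <- function(traj, atom_indices = NULL, frame_range = NULL) {
  sel <- atom_indices %||% seq_len(n_atoms(traj))
  if (any(sel < 1 | sel > n_atoms(traj)))
    abort_usage("atom_indices out of range")
  frame_range <- frame_range %||% c(1L, n_frames(traj) + 1L)
  f0 <- frame_range[1]; f1 <- frame_range[2]
  if (f0 < 1 || f1 > n_frames(traj) + 1 || f1 <= f0)
    abort_usage("invalid frame_range")
  frames <- seq.int(f0, f1 - 1)
  nf <- length(frames)
  if (nf < 2) abort_usage("STDDV needs at least 2 frames")

  n <- length(sel)
  npair <- n * (n - 1) / 2
  s1 <- numeric(npair)
  for (f in frames)
    s1 <- s1 + stats::dist(traj$coords[f, sel, , drop = TRUE])
  m <- s1 / nf
  s2 <- numeric(npair)
  for (f in frames) {
    dv <- stats::dist(traj$coords[f, sel, , drop = TRUE]) - m
    s2 <- s2 + dv * dv
  }
  sdv <- sqrt(as.numeric(s2) / (nf - 1))

  D <- matrix(0, n, n)
  D[lower.tri(D)] <- sdv
  D <- D + t(D)
  attr(D, "frame_range") <- c(f0, f1)
  attr(D, "atom_indices") <- sel
  D
}

#' Segmentation scheme: N_t = N_s * N_f
#'
#' Partitions `n_t` frames into `n_s` equal contiguous segments of
#' `n_f = n_t / n_s` frames. The division must be exact (trim the
#' trajectory first otherwise) and each segment must hold at least two
#' frames so a variance estimate exists.
#'
#' @param n_t total frame count.
#' @param n_s number of segments.
#' @return list with `n_t`, `n_s`, `n_f`, class `srd_segmentation`.
#' @export
segmentation_scheme <- function(n_t, n_s) {
  n_t <- as.integer(n_t); n_s <- as.integer(n_s)
  if (n_s < 1 || n_t < 2) abort_usage("need n_s >= 1 and n_t >= 2")
  if (n_t %% n_s != 0)
    abort_usage("n_t (", n_t, ") is not divisible by n_s (", n_s,
                "); trim the trajectory first")
  n_f <- n_t %/% n_s
  if (n_f < 2) abort_usage("segments must contain at least 2 frames")
  structure(list(n_t = n_t, n_s = n_s, n_f = n_f), class = "srd_segmentation")
}

#' Half-open frame ranges of a segmentation
#' @param scheme an [segmentation_scheme()].
#' @return data frame with columns `start` and `end` (half-open, 1-based),
#'   one row per segment; contiguous, disjoint and exhaustive.
#' @export
segment_ranges <- function(scheme) {
  starts <- seq.int(1L, scheme$n_t, by = scheme$n_f)
  data.frame(start = starts, end = starts + scheme$n_f)
}

#' Per-segment STDDV matrices
#' @param traj an [srd_trajectory()].
#' @param atom_indices atoms to include; default all.
#' @param scheme an [segmentation_scheme()] over `n_frames(traj)`.
#' @return list of STDDV matrices, one per segment.
#' @export
segment_stddv <- function(traj, atom_indices = NULL, scheme) {
  if (scheme$n_t != n_frames(traj))
    abort_usage("scheme$n_t does not match the trajectory frame count")
  rg <- segment_ranges(scheme)
  lapply(seq_len(nrow(rg)), function(s)
    stddv_matrix(traj, atom_indices, c(rg$start[s], rg$end[s])))
}
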