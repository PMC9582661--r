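#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' between `mobile %*% t(R) + t` (rows are atoms) and `reference`, via SVD
#' of the cross-covariance with a reflection guard (the sign of the
#' smallest singular vector is flipped when needed so that `det(R) = +1`:
#' only physical rigid motions are returned). Weights are uniform.
#'
#' @param mobile n x 3 coordinate matrix, nm.
#' @param reference n x 3 coordinate matrix, nm.
#' @return list with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (post-fit, nm).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    abort_usage("mobile and reference must be equal-sized n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) abort_numeric("superposition needs at least 3 atoms")
  if (any(!is.finite(mobile)) || any(!is.finite(reference)))
    abort_numeric("non-finite coordinates in superposition")

  mc <- colMeans(mobile); rc <- colMeans(reference)
  M <- sweep(mobile, 2, mc); Rf <- sweep(reference, 2, rc)

  sm <- svd(M)$d
  if (sm[2] <= 1e-9 * max(sm[1], 1e-30))
    abort_numeric("degenerate (collinear) geometry: superposition undefined")

  sv <- svd(crossprod(M, Rf)) # t(M) %*% Rf, 3 x 3
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rc - as.vector(R %*% mc)

  fitted <- mobile %*% t(R) + rep(tr, each = n)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param X n x 3 matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector.
#' @return transformed n x 3 matrix.
#' @export
apply_rigid_transform <- function(X, rotation, translation) {
  X %*% t(rotation) + rep(translation, each = nrow(X))
}

#' Fit every frame of a trajectory onto a reference frame
#'
#' For each frame, the rigid transform is computed on the fit selection
#' only (typically backbone atoms within strands and helices, see
#' [fit_selection()]) and then applied to all atoms, so that the
#' per-frame RMSD over the fit selection is minimal. Note that pairwise
#' intra-frame distances -- and hence every STDDV matrix -- are invariant
#' under this operation; fitting matters only for coordinate-space
#' displays and downstream per-atom analyses.
#'
#' @param traj an [srd_trajectory()].
#' @param fit_sel atom indices defining the fit; defaults to all atoms.
#' @param ref_frame reference frame (1-based).
#' @return the fitted trajectory, with the per-frame RMSD over the fit
#'   selection in attribute `"rmsd"`.
#' @export
fit_trajectory <- function(traj, fit_sel = NULL, ref_frame = 1) {
  nf <- n_frames(traj)
  if (ref_frame < 1 || ref_frame > nf)
    abort_usage("ref_frame out of range")
  fit_sel <- fit_sel %||% seq_len(n_atoms(traj))
  if (any(fit_sel < 1 | fit_sel > n_atoms(traj)))
    abort_usage("fit_sel contains out-of-range atom indices")

  ref <- traj$coords[ref_frame, fit_sel, , drop = TRUE]
  out <- traj
  rmsd <- numeric(nf)
  for (f in seq_len(nf)) {
    fit <- kabsch_superpose(traj$coords[f, fit_sel, , drop = TRUE], ref)
    out$coords[f, , ] <- apply_rigid_transform(
      traj$coords[f, , , drop = TRUE], fit$rotation, fit$translation)
    rmsd[f] <- fit$rmsd
  }
  attr(out, "rmsd") <- rmsd
  attr(out, "ref_frame") <- ref_frame
  out
}
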