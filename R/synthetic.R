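# Synthetic trajectories with planted semi-rigid domains: the package's
# validation bed. Each domain is a rigid cloud of atoms performing a slow
# rigid-body random walk; fast per-atom Gaussian jitter is superimposed,
# and designated "loop" atoms may switch their governing domain mid-run
# (a metastable-state caricature). No physics is modelled -- only the
# statistical structure the clustering method exploits.

#' Specification of a planted-domain trajectory
#'
#' @param n_domains number of rigid domains.
#' @param atoms_per_domain atoms per domain (drawn uniformly in a 1 nm
#'   sphere around well-separated centres >= 4 nm apart).
#' @param domain_motion_amplitude per-frame scale of the slow collective
#'   rigid-body random walk, nm: each frame every domain translates by a
#'   Gaussian step of this standard deviation per axis and rotates about
#'   its centroid by a Gaussian angle of the same numeric magnitude in
#'   radians. Displacements accumulate, so the motion is slow and
#'   large-amplitude.
#' @param atom_jitter_sigma per-frame i.i.d. Gaussian jitter per atom per
#'   coordinate, nm (fast small-amplitude oscillation).
#' @param n_frames number of frames (>= 2).
#' @param dt_frame frame spacing, ps.
#' @param switch_spec optional list of switches, each a list with fields
#'   `atoms` (indices), `frame` (1-based switch frame), `from` and `to`
#'   (domain indices): the atoms ride with domain `from` before `frame`
#'   and with domain `to` from it onwards. An atom may appear in at most
#'   one switch.
#' @param seed integer seed; the whole trajectory is a deterministic
#'   function of it.
#' @return validated spec of class `srd_planted_spec`.
#' @export
planted_spec <- function(n_domains = 3, atoms_per_domain = 30,
                         domain_motion_amplitude = 0.3,
                         atom_jitter_sigma = 0.02,
                         n_frames = 2500, dt_frame = 20,
                         switch_spec = NULL, seed = 1L) {
  if (n_domains < 1 || atoms_per_domain < 1)
    abort_usage("need at least one domain and one atom per domain")
  if (domain_motion_amplitude < 0 || atom_jitter_sigma < 0)
    abort_usage("amplitudes must be >= 0")
  if (n_frames < 2) abort_usage("n_frames must be >= 2")
  if (dt_frame <= 0) abort_usage("dt_frame must be > 0")
  n_atoms <- n_domains * atoms_per_domain
  if (!is.null(switch_spec)) {
    all_atoms <- integer(0)
    for (sw in switch_spec) {
      if (!all(c("atoms", "frame", "from", "to") %in% names(sw)))
        abort_usage("each switch needs fields atoms, frame, from, to")
      if (sw$frame < 2 || sw$frame > n_frames)
        abort_usage("switch frame out of range")
      if (sw$from < 1 || sw$from > n_domains || sw$to < 1 || sw$to > n_domains)
        abort_usage("switch domain index out of range")
      if (any(sw$atoms < 1 | sw$atoms > n_atoms))
        abort_usage("switch atom index out of range")
      if (any(sw$atoms %in% all_atoms))
        abort_usage("overlapping switch definitions: an atom may switch once")
      all_atoms <- c(all_atoms, sw$atoms)
    }
  }
  structure(
    list(n_domains = as.integer(n_domains),
         atoms_per_domain = as.integer(atoms_per_domain),
         domain_motion_amplitude = domain_motion_amplitude,
         atom_jitter_sigma = atom_jitter_sigma,
         n_frames = as.integer(n_frames), dt_frame = dt_frame,
         switch_spec = switch_spec, seed = as.integer(seed)),
    class = "srd_planted_spec"
  )
}

rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate a planted-domain trajectory
#'
#' See [planted_spec()] for the motion model. With zero jitter, distances
#' within a domain are constant over the whole run (exact rigid bodies),
#' so within-domain STDDV entries vanish at any motion amplitude -- the
#' separation the clustering method exploits. One "residue" is emitted per
#' atom (atom name `CA`), so the full trajectory is the C-alpha selection.
#'
#' @param spec an [planted_spec()].
#' @return list with `trajectory` (an [srd_trajectory()]) and `truth`
#'   (class `srd_planted_truth`: `true_label` = planted domain per atom,
#'   plus the switch annotations).
#' @export
generate_planted_trajectory <- function(spec) {
  nd <- spec$n_domains
  apd <- spec$atoms_per_domain
  n <- nd * apd
  nf <- spec$n_frames
  amp <- spec$domain_motion_amplitude

  with_seed(spec$seed, {
    centers <- cbind(4.5 * (seq_len(nd) - 1), 0, 0)

    # uniform in the unit sphere around each centre
    templates <- lapply(seq_len(nd), function(d) {
      u <- matrix(stats::rnorm(apd * 3), apd, 3)
      u <- u / sqrt(rowSums(u^2))
      r <- stats::runif(apd)^(1 / 3)
      u * r + rep(centers[d, ], each = apd)
    })

    domain_of <- rep(seq_len(nd), each = apd)

    # governing domain per atom per frame
    governs <- matrix(rep(domain_of, each = nf), nf, n)
    for (sw in spec$switch_spec %||% list()) {
      governs[seq_len(sw$frame - 1), sw$atoms] <- sw$from
      governs[seq.int(sw$frame, nf), sw$atoms] <- sw$to
    }

    # rigid-body state per domain, evolved frame by frame
    rots <- lapply(seq_len(nd), function(d) diag(3))
    trans <- lapply(seq_len(nd), function(d) c(0, 0, 0))

    # per-atom template coordinates (absolute); switched atoms get
    # re-anchored into their target domain's frame at the switch time
    tmpl <- do.call(rbind, templates)
    coords <- array(NA_real_, dim = c(nf, n, 3))

    place <- function(d, X) {
      # map absolute template coords through domain d's current transform
      rel <- sweep(X, 2, centers[d, ])
      sweep(rel %*% t(rots[[d]]), 2, centers[d, ] + trans[[d]], "+")
    }
    unplace <- function(d, X) {
      rel <- sweep(X, 2, centers[d, ] + trans[[d]])
      sweep(rel %*% rots[[d]], 2, centers[d, ], "+")
    }

    for (f in seq_len(nf)) {
      if (f > 1 && amp > 0) {
        for (d in seq_len(nd)) {
          axis <- stats::rnorm(3)
          rots[[d]] <- rotation_about_axis(axis, stats::rnorm(1, 0, amp)) %*%
            rots[[d]]
          trans[[d]] <- trans[[d]] + stats::rnorm(3, 0, amp)
        }
      }
      if (f > 1) {
        # re-anchor atoms whose governing domain changes at this frame
        changed <- which(governs[f, ] != governs[f - 1, ])
        for (i in changed) {
          pos <- place(governs[f - 1, i], tmpl[i, , drop = FALSE])
          tmpl[i, ] <- unplace(governs[f, i], pos)
        }
      }
      for (d in seq_len(nd)) {
        idx <- which(governs[f, ] == d)
        if (length(idx))
          coords[f, idx, ] <- place(d, tmpl[idx, , drop = FALSE])
      }
    }

    if (spec$atom_jitter_sigma > 0)
      coords <- coords + stats::rnorm(length(coords), 0, spec$atom_jitter_sigma)

    atoms <- data.frame(
      atom_index = seq_len(n), atom_name = "CA",
      residue_number = seq_len(n), residue_id = seq_len(n),
      chain_id = LETTERS[(domain_of - 1) %% 26 + 1],
      residue_name = "ALA", stringsAsFactors = FALSE
    )
    traj <- srd_trajectory(coords, spec$dt_frame, atoms)

    truth <- structure(
      list(true_label = domain_of, switches = spec$switch_spec),
      class = "srd_planted_truth"
    )
    list(trajectory = traj, truth = truth)
  })
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement corrected for chance: 1 for identical
#' partitions (up to relabeling), approximately 0 for independent ones.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    abort_usage("label vectors differ in length")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1) # both partitions degenerate & equal
  (sum_ij - expected) / (max_index - expected)
}
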