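# Fixture builders and independent oracles used across the suite.

# Random symmetric non-negative matrix with zero diagonal.
rand_D <- function(n, scale = 1) {
  M <- matrix(stats::runif(n * n, 0, scale), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M
}

# Random per-segment labeling matrix (n_s x n_atoms).
rand_seglab <- function(n_s, n, k) {
  matrix(sample.int(k, n_s * n, replace = TRUE), n_s, n)
}

# Random trajectory with i.i.d. Gaussian coordinates.
rand_traj <- function(n_frames, n_atoms, sd = 1, dt = 20, names = "CA") {
  coords <- array(stats::rnorm(n_frames * n_atoms * 3, sd = sd),
                  dim = c(n_frames, n_atoms, 3))
  atoms <- data.frame(atom_index = seq_len(n_atoms),
                      atom_name = rep_len(names, n_atoms),
                      residue_number = seq_len(n_atoms),
                      residue_id = seq_len(n_atoms),
                      chain_id = "A", residue_name = "ALA",
                      stringsAsFactors = FALSE)
  srd_trajectory(coords, dt, atoms)
}

# Random proper rotation matrix.
rand_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Horn's quaternion method: minimal RMSD of mobile onto reference,
# independent of the SVD route used by kabsch_superpose().
quaternion_rmsd <- function(mobile, reference) {
  n <- nrow(mobile)
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(A, B)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lambda) / n
  sqrt(max(msd, 0))
}

# Brute-force pair-counting adjusted Rand index.
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  s_ab <- 0; s_a <- 0; s_b <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      ta <- a[i] == a[j]; tb <- b[i] == b[j]
      if (ta && tb) s_ab <- s_ab + 1
      if (ta) s_a <- s_a + 1
      if (tb) s_b <- s_b + 1
    }
  }
  total <- n * (n - 1) / 2
  expected <- s_a * s_b / total
  max_index <- (s_a + s_b) / 2
  if (max_index == expected) return(1)
  (s_ab - expected) / (max_index - expected)
}

# All permutations of 1..n (for the factorial assignment oracle).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Factorial brute-force linear assignment.
brute_force_lap <- function(cost) {
  n <- nrow(cost)
  best <- Inf; best_perm <- NULL
  for (p in all_perms(n)) {
    v <- sum(cost[cbind(seq_len(n), p)])
    if (v < best) { best <- v; best_perm <- p }
  }
  list(cost = best, assignment = best_perm)
}

# Minimal Tcl syntax checker: balanced braces/brackets and closed quotes,
# honouring backslash escapes.
tcl_syntax_ok <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth_brace <- 0; depth_bracket <- 0
  in_quote <- FALSE; escape <- FALSE
  for (ch in chars) {
    if (escape) { escape <- FALSE; next }
    if (ch == "\\") { escape <- TRUE; next }
    if (in_quote) {
      if (ch == '"') in_quote <- FALSE
      next
    }
    if (ch == '"') in_quote <- TRUE
    else if (ch == "{") depth_brace <- depth_brace + 1
    else if (ch == "}") { depth_brace <- depth_brace - 1; if (depth_brace < 0) return(FALSE) }
    else if (ch == "[") depth_bracket <- depth_bracket + 1
    else if (ch == "]") { depth_bracket <- depth_bracket - 1; if (depth_bracket < 0) return(FALSE) }
  }
  depth_brace == 0 && depth_bracket == 0 && !in_quote && !escape
}

# Apply an independent rigid transform to every frame of a trajectory.
rigid_perturb_traj <- function(traj) {
  out <- traj
  for (f in seq_len(n_frames(traj))) {
    R <- rand_rotation()
    tvec <- stats::rnorm(3, sd = 5)
    out$coords[f, , ] <- traj$coords[f, , , drop = TRUE] %*% t(R) +
      rep(tvec, each = n_atoms(traj))
  }
  out
}

path_ss_fixtures <- function() {
  c(system.file("extdata", "ss_4zqk_pdl1.tsv", package = "semirigid"),
    system.file("extdata", "ss_4zqk_pd1.tsv", package = "semirigid"))
}
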