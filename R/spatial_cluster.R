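# Crisp decomposition of atoms into k clusters minimising the within-cluster
# sum of distance variabilities, q = tr(c' D c). Memberships are {0,1}
# (each atom in exactly one cluster), which permits fast single-atom-move
# search; empty clusters are allowed and carry no penalty.

#' Clustering target function q = tr(c' D c)
#'
#' Sum of all within-cluster STDDV entries, counting both ordered pairs
#' `(i, j)` and `(j, i)`; the diagonal is zero, so singletons contribute
#' nothing.
#'
#' @param D symmetric non-negative matrix with zero diagonal.
#' @param labels integer cluster label per atom (1-based).
#' @return the target value `q`.
#' @export
target_q <- function(D, labels) {
  check_dissimilarity(D, "D")
  if (length(labels) != nrow(D))
    abort_usage("labels length does not match D")
  q <- 0
  for (idx in split(seq_along(labels), labels))
    q <- q + sum(D[idx, idx])
  q
}

# n x k matrix S with S[i, m] = sum of D[i, j] over atoms j in cluster m.
cluster_row_sums <- function(D, labels, k) {
  n <- nrow(D)
  ind <- matrix(0, n, k)
  ind[cbind(seq_len(n), labels)] <- 1
  D %*% ind
}

#' Exact target change of a single-atom move
#'
#' Returns `q(after) - q(before)` for moving `atom` into `new_cluster`,
#' computed incrementally as `2 * (S[atom, new] - S[atom, old])` where `S`
#' holds per-atom sums of `D` over each cluster. Exact with respect to
#' full recomputation (the diagonal of `D` is zero, so the atom's own term
#' cancels).
#'
#' @param D symmetric matrix with zero diagonal.
#' @param labels current labeling.
#' @param atom atom index (1-based).
#' @param new_cluster target cluster in `1..k`, different from the current
#'   label.
#' @param k number of clusters (default `max(labels)`).
#' @param cluster_sums optional precomputed `cluster_row_sums(D, labels, k)`.
#' @return the change in `q`.
#' @export
delta_q_move <- function(D, labels, atom, new_cluster, k = max(labels),
                         cluster_sums = NULL) {
  n <- nrow(D)
  if (atom < 1 || atom > n) abort_usage("invalid atom index")
  if (new_cluster < 1 || new_cluster > k) abort_usage("invalid target cluster")
  old <- labels[atom]
  if (new_cluster == old) abort_usage("new_cluster equals the current label")
  S <- cluster_sums %||% cluster_row_sums(D, labels, k)
  2 * (S[atom, new_cluster] - S[atom, old])
}

# One restart of the local search: uniform random start, greedy random
# single-atom moves (accept iff delta q < 0) until `stall` consecutive
# rejections, then exhaustive single-atom sweeps to a verified local
# optimum (no single move improves q).
local_search_once <- function(D, k, stall) {
  n <- nrow(D)
  labels <- sample.int(k, n, replace = TRUE)
  S <- cluster_row_sums(D, labels, k)

  rejects <- 0L
  block <- max(4L * stall, 64L)
  while (rejects < stall) {
    ats <- sample.int(n, block, replace = TRUE)
    cls <- sample.int(k, block, replace = TRUE)
    for (b in seq_len(block)) {
      i <- ats[b]; m <- cls[b]; old <- labels[i]
      if (m == old) next
      if (S[i, m] < S[i, old]) {
        labels[i] <- m
        di <- D[, i]
        S[, old] <- S[, old] - di
        S[, m] <- S[, m] + di
        rejects <- 0L
      } else {
        rejects <- rejects + 1L
        if (rejects >= stall) break
      }
    }
  }

  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      old <- labels[i]
      m <- which.min(S[i, ])
      if (S[i, m] < S[i, old]) {
        labels[i] <- m
        di <- D[, i]
        S[, old] <- S[, old] - di
        S[, m] <- S[, m] + di
        improved <- TRUE
      }
    }
    if (!improved) break
  }

  list(labels = labels, q = sum(S[cbind(seq_len(n), labels)]))
}

#' Crisp clustering by randomised single-atom-move search
#'
#' Runs `n_trials` independent restarts of a two-phase local search
#' (random single-atom moves until a stall, then exhaustive sweeps to a
#' single-move local optimum) and keeps the best target value; among equal
#' values the first found wins, so the result is fully determined by
#' `seed`. Clusters may end up empty -- the target carries no occupancy
#' penalty -- and `k` is only an upper bound on the number of non-empty
#' clusters.
#'
#' @param D symmetric STDDV (or any dissimilarity) matrix, zero diagonal.
#' @param k maximum number of clusters (`1 <= k <= nrow(D)`).
#' @param n_trials number of independent restarts.
#' @param seed integer seed; every run with the same seed is bit-identical.
#' @param stall random-phase stopping rule: consecutive rejected moves
#'   before switching to exhaustive sweeps. Default `50 * nrow(D)`.
#' @return object of class `srd_labeling`: list with `labels`, `k`, `q`,
#'   `n_nonempty`, `n_trials`, `seed`.
#' @export
optimize_labels <- function(D, k, n_trials = 100, seed = 1L, stall = NULL) {
  check_dissimilarity(D, "D")
  n <- nrow(D)
  if (k < 1) abort_usage("k must be >= 1")
  if (k > n) abort_usage("k (", k, ") exceeds the number of atoms (", n, ")")
  if (n_trials < 1) abort_usage("n_trials must be >= 1")
  stall <- as.integer(stall %||% (50L * n))

  if (k == 1) {
    best <- list(labels = rep(1L, n), q = sum(D))
  } else {
    best <- with_seed(seed, {
      b <- NULL
      for (trial in seq_len(n_trials)) {
        res <- local_search_once(D, k, stall)
        if (is.null(b) || res$q < b$q) b <- res
      }
      b
    })
  }
  structure(
    list(labels = as.integer(best$labels), k = as.integer(k), q = best$q,
         n_nonempty = length(unique(best$labels)),
         n_trials = as.integer(n_trials), seed = as.integer(seed)),
    class = "srd_labeling"
  )
}

#' @export
print.srd_labeling <- function(x, ...) {
  cat(sprintf("<srd_labeling> %d atoms, k = %d (%d non-empty), q = %.6g\n",
              length(x$labels), x$k, x$n_nonempty, x$q))
  invisible(x)
}

#' Exact optimum by set-partition enumeration (test oracle)
#'
#' Enumerates every partition of the atoms into at most `k` unlabeled
#' non-empty blocks (restricted growth strings) and returns the global
#' minimum of the target. Only feasible for tiny instances; guarded at
#' 12 atoms.
#'
#' @inheritParams optimize_labels
#' @return an `srd_labeling` holding the global optimum.
#' @export
brute_force_labels <- function(D, k) {
  check_dissimilarity(D, "D")
  n <- nrow(D)
  if (n > 12) abort_usage("instance too large for brute force (n > 12)")
  if (k < 1 || k > n) abort_usage("need 1 <= k <= n")

  best_q <- Inf
  best_labels <- rep(1L, n)
  labels <- integer(n)
  recurse <- function(i, maxlab) {
    if (i > n) {
      q <- target_q(D, labels[seq_len(n)])
      if (q < best_q) {
        best_q <<- q
        best_labels <<- labels[seq_len(n)]
      }
      return(invisible(NULL))
    }
    for (m in seq_len(min(maxlab + 1L, k))) {
      labels[i] <<- m
      recurse(i + 1L, max(maxlab, m))
    }
  }
  if (n == 1) {
    best_q <- 0; best_labels <- 1L
  } else {
    labels[1] <- 1L
    recurse(2L, 1L)
  }
  structure(
    list(labels = as.integer(best_labels), k = as.integer(k), q = best_q,
         n_nonempty = length(unique(best_labels)),
         n_trials = NA_integer_, seed = NA_integer_),
    class = "srd_labeling"
  )
}

#' Cluster every trajectory segment
#'
#' Computes the per-segment STDDV matrix over the given atoms and runs
#' [optimize_labels()] on each; the per-segment seeds are derived
#' deterministically from `seed` and the segment index, so segments are
#' independent of execution order.
#'
#' @param traj an [srd_trajectory()].
#' @param atom_indices atoms to cluster (typically [select_calpha()]).
#' @param scheme an [segmentation_scheme()].
#' @param k number of spatial clusters per segment.
#' @param n_trials restarts per segment.
#' @param seed master seed.
#' @return object of class `srd_seglab`: list with `labels` (an
#'   `n_s x n_atoms` integer matrix), `k`, `q` (per-segment optima) and
#'   `atom_indices`.
#' @export
cluster_segments <- function(traj, atom_indices = NULL, scheme, k,
                             n_trials = 100, seed = 1L) {
  atom_indices <- atom_indices %||% seq_len(n_atoms(traj))
  mats <- segment_stddv(traj, atom_indices, scheme)
  n <- length(atom_indices)
  labels <- matrix(NA_integer_, scheme$n_s, n)
  qs <- numeric(scheme$n_s)
  for (s in seq_len(scheme$n_s)) {
    lab <- optimize_labels(mats[[s]], k, n_trials = n_trials,
                           seed = derive_seed(seed, s))
    labels[s, ] <- lab$labels
    qs[s] <- lab$q
  }
  structure(list(labels = labels, k = as.integer(k), q = qs,
                 atom_indices = atom_indices),
            class = "srd_seglab")
}
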