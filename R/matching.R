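# Cross-trajectory group matching: symmetric-difference losses, optimal
# label assignment (Hungarian algorithm), disparity and stable kernels.

#' Symmetric-difference loss between two atom sets
#'
#' `|(A U B) \\ (A n B)|`: 0 for identical sets, `|A| + |B|` for disjoint
#' ones, otherwise the number of atoms in exactly one of the two sets.
#'
#' @param set_a,set_b vectors of atom indices.
#' @return integer loss.
#' @export
symmetric_difference_loss <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  length(union(set_a, set_b)) - length(intersect(set_a, set_b))
}

partition_groups <- function(partition) {
  ng <- attr(partition, "n_groups") %||% max(partition)
  lapply(seq_len(ng), function(m) which(unclass(partition) == m))
}

#' Pairwise loss matrix between two group partitions
#'
#' Entry `(i, j)` is the symmetric-difference loss between group `i` of
#' the reference partition and group `j` of the other. Comparison requires
#' both partitions to have the same number of groups.
#'
#' @param partition_a,partition_b `srd_partition` objects (or integer
#'   label vectors) over the same atoms.
#' @return integer `N_G x N_G` matrix.
#' @export
loss_matrix <- function(partition_a, partition_b) {
  if (length(partition_a) != length(partition_b))
    abort_usage("partitions cover different numbers of atoms")
  ga <- partition_groups(partition_a)
  gb <- partition_groups(partition_b)
  if (length(ga) != length(gb))
    abort_usage("partitions have different group counts (",
                length(ga), " vs ", length(gb), ")")
  ng <- length(ga)
  L <- matrix(0L, ng, ng)
  for (i in seq_len(ng))
    for (j in seq_len(ng))
      L[i, j] <- symmetric_difference_loss(ga[[i]], gb[[j]])
  L
}

# O(n^3) Hungarian algorithm (potentials + shortest augmenting paths).
# Returns one optimal assignment and its cost; all arithmetic on integer-
# valued doubles stays exact.
hungarian_solve <- function(cost) {
  n <- nrow(cost)
  if (n == 0) return(list(assignment = integer(0), cost = 0))
  u <- numeric(n)
  v <- numeric(n + 1)
  p <- integer(n + 1) # p[j] = row matched to column j (0 = free); j = n+1 virtual
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j]] <- j
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}

#' Optimal group-label assignment (Hungarian algorithm)
#'
#' Finds the bijection of columns (groups of the compared trajectory) onto
#' rows (groups of the reference) minimising the total loss; the total is
#' the clustering disparity between the two trajectories. Among equally
#' optimal bijections the lexicographically smallest permutation is
#' returned, so results are deterministic across platforms.
#'
#' @param loss square matrix, e.g. from [loss_matrix()].
#' @return object of class `srd_match`: list with `assignment`
#'   (`assignment[i]` = column matched to row `i`), `pair_losses`,
#'   `total_disparity` and `loss_matrix`.
#' @export
match_pairs <- function(loss) {
  if (!is_square_matrix(loss)) abort_usage("loss matrix must be square")
  if (any(!is.finite(loss))) abort_numeric("loss matrix has non-finite entries")
  n <- nrow(loss)
  best <- hungarian_solve(loss)$cost

  # Fix rows one by one to the smallest column that still admits an
  # optimal completion: yields the lexicographically smallest optimum.
  avail <- seq_len(n)
  perm <- integer(n)
  fixed <- 0
  for (i in seq_len(n)) {
    rest_rows <- if (i < n) seq.int(i + 1L, n) else integer(0)
    for (j in avail) {
      rest <- if (length(rest_rows) == 0) 0 else
        hungarian_solve(loss[rest_rows, setdiff(avail, j), drop = FALSE])$cost
      if (abs(fixed + loss[i, j] + rest - best) < 1e-9) {
        perm[i] <- j
        fixed <- fixed + loss[i, j]
        avail <- setdiff(avail, j)
        break
      }
    }
  }
  structure(
    list(assignment = perm,
         pair_losses = loss[cbind(seq_len(n), perm)],
         total_disparity = best,
         loss_matrix = loss),
    class = "srd_match"
  )
}

#' @export
print.srd_match <- function(x, ...) {
  cat(sprintf("<srd_match> %d groups, total disparity = %g\n",
              length(x$assignment), x$total_disparity))
  cat("  assignment:", paste(seq_along(x$assignment), x$assignment,
                             sep = "->", collapse = " "), "\n")
  invisible(x)
}

#' Relabel a partition onto the reference numbering
#'
#' After [match_pairs()], group `assignment[i]` of the compared partition
#' is renamed `i` so that equal indices denote corresponding groups.
#'
#' @param partition the compared `srd_partition`.
#' @param match the `srd_match` from comparing the reference against it.
#' @return relabeled `srd_partition`.
#' @export
relabel_partition <- function(partition, match) {
  inv <- integer(length(match$assignment))
  inv[match$assignment] <- seq_along(match$assignment)
  out <- inv[unclass(partition)]
  sizes <- as.integer(table(factor(out, levels = seq_along(inv))))
  structure(out, n_groups = length(inv), sizes = sizes,
            method = attr(partition, "method"), class = "srd_partition")
}

#' Match several partitions onto a reference
#'
#' Each non-reference partition is matched pairwise to the reference and
#' relabeled onto its group numbering.
#'
#' @param reference an `srd_partition`.
#' @param others list of `srd_partition`s with the same group count.
#' @return list with `matches` (one `srd_match` per other) and
#'   `partitions` (reference first, others relabeled).
#' @export
match_partitions <- function(reference, others) {
  matches <- lapply(others, function(p) match_pairs(loss_matrix(reference, p)))
  relabeled <- mapply(relabel_partition, others, matches, SIMPLIFY = FALSE)
  list(matches = matches, partitions = c(list(reference), relabeled))
}

#' Stable kernels of matched partitions
#'
#' For each group index `m`, the intersection of group `m`'s atom set over
#' all (already relabeled) partitions. Kernels are pairwise disjoint;
#' atoms outside every kernel changed groups in at least one trajectory.
#'
#' @param partitions list of relabeled `srd_partition`s sharing a group
#'   count (e.g. `match_partitions(...)$partitions`).
#' @return object of class `srd_kernels`: list with `kernels` (list of
#'   atom index vectors), `coverage` (fraction of atoms inside a kernel)
#'   and `n_atoms`.
#' @export
stable_kernels <- function(partitions) {
  ng <- unique(vapply(partitions, function(p)
    attr(p, "n_groups") %||% max(p), 1L))
  if (length(ng) != 1)
    abort_usage("partitions have different group counts")
  n <- unique(lengths(partitions))
  if (length(n) != 1)
    abort_usage("partitions cover different numbers of atoms")
  kernels <- lapply(seq_len(ng), function(m) {
    Reduce(intersect, lapply(partitions, function(p) which(unclass(p) == m)))
  })
  structure(list(kernels = kernels,
                 coverage = sum(lengths(kernels)) / n,
                 n_atoms = n),
            class = "srd_kernels")
}

#' @export
print.srd_kernels <- function(x, ...) {
  cat(sprintf("<srd_kernels> %d kernels over %d atoms, coverage %.3f\n",
              length(x$kernels), x$n_atoms, x$coverage))
  cat("  sizes:", paste(lengths(x$kernels), collapse = " "), "\n")
  invisible(x)
}

#' Multi-trajectory disparity
#'
#' After matching all partitions onto the reference, the number of atoms
#' *not* assigned to the same group index in every trajectory. An atom
#' counts as disparate if it changes groups between any pair, so this
#' equals `n_atoms - sum(kernel sizes)`.
#'
#' @param reference an `srd_partition`.
#' @param others list of `srd_partition`s with the same group count.
#' @return integer disparity count.
#' @export
disparity_multi <- function(reference, others) {
  mp <- match_partitions(reference, others)
  ker <- stable_kernels(mp$partitions)
  as.integer(ker$n_atoms - sum(lengths(ker$kernels)))
}
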