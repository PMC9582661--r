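# Time-wise consensus over per-segment clusterings and agglomerative
# grouping of the resulting dissimilarity.

#' Time-wise consensus dissimilarity and similarity
#'
#' For atoms i, j the dissimilarity is the fraction of segments in which
#' they were *not* assigned to the same spatial cluster:
#' \deqn{\Delta_{ij} = \frac{1}{N_s} \#\{s : \mathrm{label}_i(s) \neq
#' \mathrm{label}_j(s)\}}
#' and the similarity (consensus) is \eqn{C_{ij} = 1 - \Delta_{ij}}.
#' Cluster identity is irrelevant -- only co-membership within each
#' segment counts, so per-segment labels never need to be matched. Each
#' per-segment term is the indicator of a partition-induced pseudo-metric,
#' hence the averaged Delta satisfies the triangle inequality.
#'
#' @param seg_labels an `srd_seglab` from [cluster_segments()], or a plain
#'   `n_s x n_atoms` integer matrix of per-segment labels.
#' @return object of class `srd_consensus`: list with `delta`,
#'   `similarity` (both `n x n`, entries in `[0, 1]`, `delta * n_s`
#'   integral) and `n_s`.
#' @export
dissimilarity_matrix <- function(seg_labels) {
  L <- if (inherits(seg_labels, "srd_seglab")) seg_labels$labels else seg_labels
  if (!is.matrix(L) || nrow(L) < 1)
    abort_usage("seg_labels must be an n_s x n_atoms matrix with n_s >= 1")
  ns <- nrow(L)
  n <- ncol(L)
  disagree <- matrix(0, n, n)
  for (s in seq_len(ns)) {
    l <- L[s, ]
    disagree <- disagree + (outer(l, l, "!="))
  }
  delta <- disagree / ns # exact: integer count over N_s
  structure(list(delta = delta, similarity = 1 - delta, n_s = ns),
            class = "srd_consensus")
}

#' @export
print.srd_consensus <- function(x, ...) {
  cat(sprintf("<srd_consensus> %d atoms, N_s = %d, mean delta = %.4f\n",
              nrow(x$delta), x$n_s, mean(x$delta[upper.tri(x$delta)])))
  invisible(x)
}

#' Agglomerative hierarchical clustering of a dissimilarity matrix
#'
#' Standard bottom-up agglomeration with "average" (UPGMA) or "complete"
#' linkage, both of which are monotone (merge heights never decrease) and
#' valid for non-Euclidean dissimilarities such as the consensus Delta.
#' Implemented in-package so that ties are broken deterministically: among
#' equal-height candidate merges, the pair with the lexicographically
#' smallest (cluster slot, cluster slot) indices is joined.
#'
#' @param delta symmetric dissimilarity matrix, zero diagonal.
#' @param method linkage: `"average"` or `"complete"`.
#' @return object of class `srd_dendrogram`: list with `merge` (the
#'   `stats::hclust` coding: negative entries are singletons, positive
#'   entries earlier merge steps), `height`, `method`, `n`.
#' @export
agglomerate <- function(delta, method = c("average", "complete")) {
  method <- match.arg(method)
  check_dissimilarity(delta, "delta")
  n <- nrow(delta)
  if (n < 2) abort_usage("agglomeration needs at least 2 atoms")

  d <- delta
  alive <- rep(TRUE, n)
  sizes <- rep(1L, n)
  code <- -seq_len(n) # hclust coding of the cluster currently in each slot
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    slots <- which(alive)
    sub <- d[slots, slots, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    h <- min(sub)
    cand <- which(sub == h, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- slots[cand[1, 1]]
    j <- slots[cand[1, 2]]

    other <- setdiff(slots, c(i, j))
    if (length(other)) {
      d[i, other] <- switch(method,
        average  = (sizes[i] * d[i, other] + sizes[j] * d[j, other]) /
                   (sizes[i] + sizes[j]),
        complete = pmax(d[i, other], d[j, other]))
      d[other, i] <- d[i, other]
    }
    merge[step, ] <- c(code[i], code[j])
    height[step] <- h
    sizes[i] <- sizes[i] + sizes[j]
    alive[j] <- FALSE
    code[i] <- step
  }
  structure(list(merge = merge, height = height, method = method, n = n),
            class = "srd_dendrogram")
}

#' @export
print.srd_dendrogram <- function(x, ...) {
  cat(sprintf("<srd_dendrogram> %d leaves, %s linkage, heights %.4g .. %.4g\n",
              x$n, x$method, min(x$height), max(x$height)))
  invisible(x)
}

# Member atom indices of the cluster created at each merge step.
merge_members <- function(dend) {
  members <- vector("list", nrow(dend$merge))
  get_mem <- function(codev) {
    unlist(lapply(codev, function(cd) if (cd < 0) -cd else members[[cd]]))
  }
  for (s in seq_len(nrow(dend$merge)))
    members[[s]] <- get_mem(dend$merge[s, ])
  members
}

#' Cut a dendrogram into a fixed number of groups
#'
#' Applies the first `n - n_groups` merges and reads off the remaining
#' clusters, i.e. cuts just below the `(n_groups - 1)`-th merge from the
#' top. Groups are renumbered in order of descending size; ties are broken
#' by the smallest contained atom index.
#'
#' @param dend an [agglomerate()] result.
#' @param n_groups desired number of groups, `1 <= n_groups <= n`.
#' @return object of class `srd_partition`: integer vector of group labels
#'   (one per atom) with attributes `n_groups`, `sizes`, `method`.
#' @export
cut_groups <- function(dend, n_groups) {
  n <- dend$n
  if (n_groups < 1 || n_groups > n)
    abort_usage("n_groups must be in 1..", n)
  n_merges <- n - n_groups

  labels <- integer(n)
  if (n_merges == 0) {
    labels <- seq_len(n)
  } else {
    members <- merge_members(dend)
    used <- rep(FALSE, n_merges) # merge steps absorbed by a later kept merge
    leaf_used <- rep(FALSE, n)
    for (s in seq_len(n_merges)) {
      for (cd in dend$merge[s, ]) {
        if (cd < 0) leaf_used[-cd] <- TRUE else used[cd] <- TRUE
      }
    }
    g <- 0L
    for (s in seq_len(n_merges)) {
      if (!used[s]) {
        g <- g + 1L
        labels[members[[s]]] <- g
      }
    }
    for (i in which(!leaf_used & labels == 0L)) {
      g <- g + 1L
      labels[i] <- g
    }
  }

  partition_renumber(labels, method = dend$method)
}

# Renumber group labels by descending size; ties by smallest member index.
partition_renumber <- function(labels, method = NULL) {
  grp <- split(seq_along(labels), labels)
  ord <- order(-lengths(grp), vapply(grp, min, 1L))
  out <- integer(length(labels))
  for (newg in seq_along(ord)) out[grp[[ord[newg]]]] <- newg
  structure(out,
            n_groups = length(grp),
            sizes = as.integer(lengths(grp)[ord]),
            method = method,
            class = "srd_partition")
}

#' @export
print.srd_partition <- function(x, ...) {
  cat(sprintf("<srd_partition> %d atoms in %d groups; sizes: %s\n",
              length(x), attr(x, "n_groups"),
              paste(attr(x, "sizes"), collapse = " ")))
  invisible(x)
}

#' Dissimilarity level of a dendrogram cut
#'
#' The median of the two merge heights straddling the cut that yields
#' `n_groups` groups (the last height crossed while retracing the tree
#' from the root, and the next one below) -- for two values, the midpoint.
#'
#' @inheritParams cut_groups
#' @return the cut-point dissimilarity (scalar).
#' @export
cut_point_value <- function(dend, n_groups) {
  n <- dend$n
  if (n_groups <= 1 || n_groups >= n)
    abort_usage("cut_point_value is defined for 1 < n_groups < n")
  h <- sort(dend$height)
  (h[n - n_groups] + h[n - n_groups + 1]) / 2
}

#' Consensus edges below a dissimilarity threshold
#'
#' All unordered atom pairs whose consensus dissimilarity does not exceed
#' `delta_th` -- the line list behind circular consensus plots. Edge sets
#' are nested in `delta_th`.
#'
#' @param delta dissimilarity matrix.
#' @param delta_th threshold in `[0, 1]`.
#' @return data frame with columns `i`, `j` (`i < j`) and `delta`.
#' @export
circular_edges <- function(delta, delta_th) {
  check_dissimilarity(delta, "delta")
  if (delta_th < 0 || delta_th > 1)
    abort_usage("delta_th must lie in [0, 1]")
  hit <- which(upper.tri(delta) & delta <= delta_th, arr.ind = TRUE)
  out <- data.frame(i = hit[, 1], j = hit[, 2],
                    delta = delta[hit])
  out[order(out$i, out$j), , drop = FALSE]
}
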