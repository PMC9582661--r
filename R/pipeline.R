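# End-to-end orchestration: trim, fit, segment, cluster, consensus,
# agglomerate, cut, cross-trajectory match, kernels.

#' Pipeline configuration
#'
#' Defaults are the production parameters of the method: discard the first
#' 100 ns, 500 segments, k = 7 spatial clusters, 100000 restarts per
#' segment, average linkage, 24 groups. Tests and desk-scale runs override
#' `n_trials` and sizes.
#'
#' @param discard_time initial time span to drop, ps.
#' @param n_segments number of time-wise segments N_s.
#' @param k spatial clusters per segment.
#' @param n_trials restarts per segment clustering.
#' @param linkage `"average"` or `"complete"`.
#' @param n_groups groups N_G for the agglomerative cut.
#' @param delta_th thresholds for consensus edge export.
#' @param seed master seed; all randomness derives from it.
#' @param whole also run whole-trajectory STDDV clustering (N_f = N_t).
#' @return list of class `srd_config`.
#' @export
pipeline_config <- function(discard_time = 1e5, n_segments = 500, k = 7,
                            n_trials = 100000, linkage = "average",
                            n_groups = 24, delta_th = c(0.04, 0.1),
                            seed = 1L, whole = FALSE) {
  linkage <- match.arg(linkage, c("average", "complete"))
  structure(list(discard_time = discard_time, n_segments = as.integer(n_segments),
                 k = as.integer(k), n_trials = as.integer(n_trials),
                 linkage = linkage, n_groups = as.integer(n_groups),
                 delta_th = delta_th, seed = as.integer(seed),
                 whole = isTRUE(whole)),
            class = "srd_config")
}

#' Run the full semi-rigid-domain pipeline
#'
#' Per trajectory: discard the initial `discard_time`, optionally fit all
#' frames onto the first over the backbone-in-secondary-structure
#' selection (display convenience -- STDDV is fitting-invariant), select
#' C-alpha atoms, partition the frames into `n_segments` equal segments
#' (trailing remainder frames are dropped), cluster each segment's STDDV
#' matrix into `k` crisp clusters, build the consensus
#' dissimilarity/similarity, agglomerate and cut into `n_groups` groups.
#' With several trajectories, groups are matched onto the first trajectory
#' (the reference) via the Hungarian assignment and stable kernels are
#' extracted. Deterministic given `config$seed`.
#'
#' @param trajectories list of [srd_trajectory()] objects sharing an
#'   identical C-alpha atom list.
#' @param config an [pipeline_config()].
#' @param sstable optional `srd_sstable`; when given, frames are fitted on
#'   backbone atoms within strands and helices before analysis.
#' @return object of class `srd_results`: per-trajectory list `per_traj`
#'   (with `seg_labels`, `consensus`, `dendrogram`, `partition`,
#'   `cut_point`, `edges`, optionally `whole_labeling`), cross-trajectory
#'   `matches`, `partitions` (relabeled), `kernels`,
#'   `disparity` (pairwise vs reference) and `disparity_multi`, plus a
#'   `manifest` recording the configuration and derived seeds.
#' @export
run_pipeline <- function(trajectories, config = pipeline_config(),
                         sstable = NULL) {
  if (inherits(trajectories, "srd_trajectory"))
    trajectories <- list(trajectories)
  if (length(trajectories) < 1) abort_usage("need at least one trajectory")

  ca_sig <- lapply(trajectories, function(tr) {
    ca <- select_calpha(tr)
    tr$atoms$residue_number[ca]
  })
  for (t in seq_along(ca_sig))
    if (!identical(ca_sig[[t]], ca_sig[[1]]))
      abort_usage("trajectories differ in their C-alpha atom lists")

  per_traj <- vector("list", length(trajectories))
  for (t in seq_along(trajectories)) {
    tr <- trajectories[[t]]
    if (config$discard_time > 0)
      tr <- trim_frames(tr, config$discard_time)
    if (!is.null(sstable))
      tr <- fit_trajectory(tr, fit_selection(tr, sstable), ref_frame = 1)
    ca <- select_calpha(tr)

    nf_seg <- n_frames(tr) %/% config$n_segments
    if (nf_seg < 2)
      abort_usage("too few frames (", n_frames(tr), ") for ",
                  config$n_segments, " segments of >= 2 frames")
    nt <- nf_seg * config$n_segments
    if (nt < n_frames(tr)) { # drop the trailing remainder
      tr2 <- tr
      tr2$coords <- tr$coords[seq_len(nt), , , drop = FALSE]
      tr <- tr2
    }
    scheme <- segmentation_scheme(nt, config$n_segments)

    seg <- cluster_segments(tr, ca, scheme, k = config$k,
                            n_trials = config$n_trials,
                            seed = derive_seed(config$seed, t))
    cons <- dissimilarity_matrix(seg)
    dend <- agglomerate(cons$delta, method = config$linkage)
    part <- cut_groups(dend, config$n_groups)
    cutp <- if (config$n_groups > 1 && config$n_groups < length(ca))
      cut_point_value(dend, config$n_groups) else NA_real_
    edges <- lapply(config$delta_th, function(th)
      circular_edges(cons$delta, th))
    names(edges) <- as.character(config$delta_th)

    whole <- NULL
    if (config$whole) {
      Dw <- stddv_matrix(tr, ca)
      whole <- optimize_labels(Dw, config$k, n_trials = config$n_trials,
                               seed = derive_seed(config$seed, t, 999983L))
    }
    per_traj[[t]] <- list(
      residue_numbers = ca_sig[[1]], scheme = scheme, seg_labels = seg,
      consensus = cons, dendrogram = dend, partition = part,
      cut_point = cutp, edges = edges, whole_labeling = whole)
  }

  matches <- NULL; partitions <- NULL; kernels <- NULL
  disparity <- NULL; dmulti <- NULL
  if (length(trajectories) >= 2) {
    ref <- per_traj[[1]]$partition
    others <- lapply(per_traj[-1], `[[`, "partition")
    mp <- match_partitions(ref, others)
    matches <- mp$matches
    partitions <- mp$partitions
    kernels <- stable_kernels(partitions)
    disparity <- vapply(matches, `[[`, numeric(1), "total_disparity")
    dmulti <- disparity_multi(ref, others)
  } else {
    warning("single trajectory: cross-trajectory matching and kernels skipped")
  }

  manifest <- list(
    config = unclass(config),
    n_trajectories = length(trajectories),
    segment_seeds = vapply(seq_along(trajectories), function(t)
      derive_seed(config$seed, t), 1L),
    package_version = as.character(utils::packageVersion("semirigid"))
  )
  structure(list(per_traj = per_traj, matches = matches,
                 partitions = partitions, kernels = kernels,
                 disparity = disparity, disparity_multi = dmulti,
                 manifest = manifest),
            class = "srd_results")
}

#' @export
print.srd_results <- function(x, ...) {
  cat(sprintf("<srd_results> %d trajectories, k = %d, N_G = %d\n",
              length(x$per_traj), x$manifest$config$k,
              x$manifest$config$n_groups))
  if (!is.null(x$kernels)) {
    cat(sprintf("  pairwise disparity vs reference: %s\n",
                paste(x$disparity, collapse = " ")))
    cat(sprintf("  multi-trajectory disparity: %d; kernel coverage %.3f\n",
                x$disparity_multi, x$kernels$coverage))
  }
  invisible(x)
}

#' Generate a VMD Tcl colouring script for groups or kernels
#'
#' Emits one representation block per non-empty group, selecting its
#' residues by `resid` and assigning a distinct `ColorID`; residues in no
#' group (label 0, e.g. outside every kernel) are collected into a final
#' neutrally coloured block. The script is valid Tcl and can be sourced
#' in VMD with the corresponding structure loaded.
#'
#' @param labels integer group label per atom; 0 = unassigned.
#' @param atom_records atom data frame (the `atoms` of a trajectory);
#'   residue ids are taken from its `residue_id` column.
#' @param representation VMD drawing method for the blocks.
#' @return the Tcl script as a single character string.
#' @export
export_tcl <- function(labels, atom_records,
                       representation = "NewCartoon") {
  if (length(labels) != nrow(atom_records))
    abort_usage("labels must cover all atoms")
  resid_ranges <- function(resids) {
    r <- sort(unique(resids))
    brk <- c(0, which(diff(r) != 1), length(r))
    parts <- vapply(seq_len(length(brk) - 1), function(b) {
      lo <- r[brk[b] + 1]; hi <- r[brk[b + 1]]
      if (lo == hi) as.character(lo) else sprintf("%d to %d", lo, hi)
    }, "")
    paste(parts, collapse = " ")
  }
  # VMD ColorIDs 0..32; skip 8 (white) for groups, reserve it for "none"
  palette <- setdiff(0:32, 8)
  out <- c("# semirigid group colouring for VMD",
           "mol delrep all top")
  block <- function(selection, colorid, comment) {
    c(sprintf("# %s", comment),
      sprintf("mol representation %s", representation),
      sprintf("mol selection {resid %s}", selection),
      sprintf("mol color ColorID %d", colorid),
      "mol addrep top")
  }
  groups <- sort(unique(labels[labels > 0]))
  for (g in groups) {
    resids <- atom_records$residue_id[labels == g]
    out <- c(out, block(resid_ranges(resids),
                        palette[(g - 1) %% length(palette) + 1],
                        sprintf("group %d: %d atoms", g, sum(labels == g))))
  }
  if (any(labels == 0)) {
    resids <- atom_records$residue_id[labels == 0]
    out <- c(out, block(resid_ranges(resids), 8L, "unassigned residues"))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Per-atom kernel membership labels
#'
#' Converts an `srd_kernels` object into a per-atom label vector
#' (0 = outside every kernel), e.g. for [export_tcl()].
#'
#' @param kernels an `srd_kernels`.
#' @return integer vector of length `n_atoms`.
#' @export
kernel_labels <- function(kernels) {
  lab <- integer(kernels$n_atoms)
  for (m in seq_along(kernels$kernels))
    lab[kernels$kernels[[m]]] <- m
  lab
}
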