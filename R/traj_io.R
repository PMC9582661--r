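#' Trajectory container
#'
#' A trajectory is a dense array of Cartesian coordinates (in nanometres)
#' plus per-atom metadata and the time spacing between consecutive frames.
#' All analysis functions in the package operate on this container.
#'
#' @param coords numeric array of dimension `frames x atoms x 3`, in nm.
#' @param dt_frame time between consecutive frames, in ps (> 0).
#' @param atoms data frame with one row per atom and columns `atom_index`
#'   (1-based, contiguous), `atom_name` (e.g. `"N"`, `"CA"`, `"C"`),
#'   `residue_number` (continuous 1-based numbering over the whole complex,
#'   non-decreasing along the atom list), `residue_id` (author/PDB residue
#'   id), `chain_id`, and optionally `residue_name`.
#' @param time0 time of the first frame, ps.
#'
#' @return an object of class `srd_trajectory`.
#' @export
srd_trajectory <- function(coords, dt_frame, atoms, time0 = 0) {
  if (!is.array(coords) || length(dim(coords)) != 3 || dim(coords)[3] != 3)
    abort_usage("coords must be a frames x atoms x 3 array")
  if (any(!is.finite(coords)))
    abort_numeric("coords contains non-finite values")
  if (!is.numeric(dt_frame) || length(dt_frame) != 1 || dt_frame <= 0)
    abort_usage("dt_frame must be a single positive number (ps)")
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  needed <- c("atom_index", "atom_name", "residue_number", "residue_id", "chain_id")
  miss <- setdiff(needed, names(atoms))
  if (length(miss))
    abort_usage("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) != dim(coords)[2])
    abort_usage("atoms has ", nrow(atoms), " rows but coords has ",
                dim(coords)[2], " atoms")
  if (!identical(as.integer(atoms$atom_index), seq_len(nrow(atoms))))
    abort_usage("atom_index must be 1..n_atoms, contiguous")
  if (is.unsorted(atoms$residue_number))
    abort_usage("residue_number must be non-decreasing along the atom list")
  if (is.null(atoms$residue_name)) atoms$residue_name <- "ALA"
  structure(
    list(coords = coords, dt_frame = as.numeric(dt_frame),
         atoms = atoms, time0 = as.numeric(time0)),
    class = "srd_trajectory"
  )
}

#' @export
print.srd_trajectory <- function(x, ...) {
  cat(sprintf(
    "<srd_trajectory> %d frames x %d atoms, dt = %g ps, t0 = %g ps\n",
    n_frames(x), n_atoms(x), x$dt_frame, x$time0))
  cat(sprintf("  residues %d..%d, chains: %s\n",
              min(x$atoms$residue_number), max(x$atoms$residue_number),
              paste(unique(x$atoms$chain_id), collapse = " ")))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj an `srd_trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

frame_times <- function(traj) traj$time0 + (seq_len(n_frames(traj)) - 1) * traj$dt_frame

# ---------------------------------------------------------------------------
# Multi-model PDB

#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records is read as a single frame. Coordinates are converted from
#' Angstrom to nm. All models must share an identical atom list; alternate
#' locations and insertion codes are rejected. The continuous residue
#' numbering (`residue_number`) is rebuilt from scratch: it increments each
#' time the (chain, residue id) pair changes along the atom list.
#'
#' The frame spacing is not part of the PDB format; files written by
#' [write_multimodel_pdb()] carry it in a `REMARK 250 DT_FRAME_PS` record,
#' which is honoured when present, otherwise `dt_frame` is used.
#'
#' @param path path to a PDB file.
#' @param dt_frame fallback frame spacing in ps when the file carries none.
#' @return an [srd_trajectory()].
#' @export
read_multimodel_pdb <- function(path, dt_frame = 20) {
  if (!file.exists(path)) abort_usage("no such file: ", path)
  lines <- readLines(path, warn = FALSE)

  rem <- grep("^REMARK 250 DT_FRAME_PS", lines, value = TRUE)
  if (length(rem)) {
    dt <- suppressWarnings(as.numeric(sub("^REMARK 250 DT_FRAME_PS *", "", rem[1])))
    if (is.finite(dt) && dt > 0) dt_frame <- dt
  }
  t0 <- 0
  rem0 <- grep("^REMARK 250 TIME0_PS", lines, value = TRUE)
  if (length(rem0)) {
    v <- suppressWarnings(as.numeric(sub("^REMARK 250 TIME0_PS *", "", rem0[1])))
    if (is.finite(v)) t0 <- v
  }

  model_starts <- grep("^MODEL", lines)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  if (!any(is_atom)) abort_usage("empty input: no ATOM records in ", path)

  if (length(model_starts) == 0) {
    frames <- list(which(is_atom))
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      abort_format("unbalanced MODEL/ENDMDL records in ", path)
    frames <- mapply(function(a, b) {
      idx <- seq(a, b)
      idx[is_atom[idx]]
    }, model_starts, model_ends, SIMPLIFY = FALSE)
  }

  counts <- lengths(frames)
  if (any(counts == 0)) abort_format("a MODEL block contains no ATOM records")
  if (length(unique(counts)) != 1)
    abort_format("inconsistent atom counts across models: ",
                 paste(unique(counts), collapse = ", "))
  nat <- counts[1]
  nfr <- length(frames)

  parse_block <- function(idx) {
    rec <- lines[idx]
    altloc <- substr(rec, 17, 17)
    icode <- substr(rec, 27, 27)
    if (any(altloc != " "))
      abort_format("alternate location indicators are not supported")
    if (any(icode != " "))
      abort_format("residue insertion codes are not supported")
    xyz <- cbind(as.numeric(substr(rec, 31, 38)),
                 as.numeric(substr(rec, 39, 46)),
                 as.numeric(substr(rec, 47, 54)))
    if (any(!is.finite(xyz))) abort_format("unparseable coordinates in ATOM record")
    list(
      xyz = xyz / 10, # Angstrom -> nm
      name = trimws(substr(rec, 13, 16)),
      resname = trimws(substr(rec, 18, 20)),
      chain = substr(rec, 22, 22),
      resid = as.integer(substr(rec, 23, 26))
    )
  }

  first <- parse_block(frames[[1]])
  coords <- array(NA_real_, dim = c(nfr, nat, 3))
  coords[1, , ] <- first$xyz
  if (nfr > 1) {
    for (f in 2:nfr) {
      blk <- parse_block(frames[[f]])
      if (!identical(blk$name, first$name) || !identical(blk$resid, first$resid))
        abort_format("atom list differs between models (model ", f, ")")
      coords[f, , ] <- blk$xyz
    }
  }

  key <- paste(first$chain, first$resid)
  resnum <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  atoms <- data.frame(
    atom_index = seq_len(nat),
    atom_name = first$name,
    residue_number = as.integer(resnum),
    residue_id = first$resid,
    chain_id = first$chain,
    residue_name = first$resname,
    stringsAsFactors = FALSE
  )
  srd_trajectory(coords, dt_frame, atoms, time0 = t0)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame; coordinates converted from nm to
#' Angstrom at the format's `%8.3f` precision (0.0001 nm). The frame
#' spacing is stored in a `REMARK 250 DT_FRAME_PS` record so that the file
#' round-trips through [read_multimodel_pdb()].
#'
#' @param traj an [srd_trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  a <- traj$atoms
  pad_name <- function(nm) {
    nm <- ifelse(nchar(nm) <= 3, paste0(" ", nm), nm)
    formatC(nm, width = -4)
  }
  names4 <- pad_name(a$atom_name)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK 250 DT_FRAME_PS %.6f", traj$dt_frame), con)
  writeLines(sprintf("REMARK 250 TIME0_PS %.6f", traj$time0), con)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      a$atom_index %% 100000, names4, a$residue_name, a$chain_id,
      a$residue_id %% 10000, xyz[, 1] * 10, xyz[, 2] * 10, xyz[, 3] * 10,
      1.0, 0.0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Multi-frame GRO

#' Read a multi-frame GRO trajectory
#'
#' Reads a concatenation of GROMACS GRO frames (the text trajectory format
#' `gmx trjconv` emits). Frame times are parsed from the `t=` field of the
#' title lines and define `dt_frame`; if absent, `dt_frame` falls back to
#' the argument. All frames must have identical atom counts.
#'
#' @param path path to a `.gro` file (one or more frames).
#' @param dt_frame fallback frame spacing, ps.
#' @return an [srd_trajectory()].
#' @export
read_gro_trajectory <- function(path, dt_frame = 20) {
  if (!file.exists(path)) abort_usage("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort_usage("empty input: ", path)

  pos <- 1L
  frames <- list()
  titles <- character()
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos])) && pos == length(lines)) break
    if (pos + 1 > length(lines)) abort_format("truncated GRO frame header")
    nat <- suppressWarnings(as.integer(trimws(lines[pos + 1])))
    if (is.na(nat) || nat <= 0) abort_format("bad atom count in GRO frame")
    if (pos + 1 + nat + 1 > length(lines)) abort_format("truncated GRO frame")
    titles <- c(titles, lines[pos])
    frames[[length(frames) + 1L]] <- lines[(pos + 2):(pos + 1 + nat)]
    pos <- pos + nat + 3L # title + count + atoms + box
  }
  if (length(frames) == 0) abort_usage("empty input: no frames in ", path)
  if (length(unique(lengths(frames))) != 1)
    abort_format("inconsistent atom counts across GRO frames")

  parse_frame <- function(rec) {
    cbind(as.numeric(substr(rec, 21, 28)),
          as.numeric(substr(rec, 29, 36)),
          as.numeric(substr(rec, 37, 44)))
  }
  nat <- length(frames[[1]])
  nfr <- length(frames)
  coords <- array(NA_real_, dim = c(nfr, nat, 3))
  for (f in seq_len(nfr)) {
    xyz <- parse_frame(frames[[f]])
    if (any(!is.finite(xyz))) abort_format("unparseable coordinates in GRO frame ", f)
    coords[f, , ] <- xyz
  }

  rec <- frames[[1]]
  resid <- as.integer(substr(rec, 1, 5))
  resname <- trimws(substr(rec, 6, 10))
  name <- trimws(substr(rec, 11, 15))
  key <- resid # GRO has no chain column
  resnum <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  atoms <- data.frame(
    atom_index = seq_len(nat), atom_name = name,
    residue_number = as.integer(resnum), residue_id = resid,
    chain_id = "A", residue_name = resname, stringsAsFactors = FALSE
  )

  tm <- regmatches(titles, regexpr("t= *[-+0-9.eE]+", titles))
  times <- suppressWarnings(as.numeric(sub("t= *", "", tm)))
  t0 <- 0
  if (length(times) == nfr && all(is.finite(times))) {
    t0 <- times[1]
    if (nfr > 1) {
      dts <- diff(times)
      if (any(dts <= 0)) abort_format("non-increasing frame times in GRO file")
      dt_frame <- dts[1]
    }
  }
  srd_trajectory(coords, dt_frame, atoms, time0 = t0)
}

#' Write a trajectory as a multi-frame GRO file
#'
#' @param traj an [srd_trajectory()].
#' @param path output path.
#' @param box box vector lengths, nm (written verbatim on each frame).
#' @return `path`, invisibly.
#' @export
write_gro_trajectory <- function(traj, path, box = c(10, 10, 10)) {
  a <- traj$atoms
  times <- frame_times(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("semirigid trajectory t= %.4f", times[f]), con)
    writeLines(sprintf("%5d", n_atoms(traj)), con)
    xyz <- traj$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$residue_id %% 100000, a$residue_name, a$atom_name,
                       a$atom_index %% 100000, xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Secondary-structure tables

#' Read a per-residue secondary-structure table
#'
#' The table is a TSV with columns `domain`, `res_start`, `res_end`, `kind`
#' (`strand`, `helix` or `loop`); `res_start`/`res_end` refer to the
#' continuous residue numbering of the complex. Several files may be given
#' (e.g. one per chain); entries are concatenated and must then cover a
#' contiguous residue range without overlaps.
#'
#' Tables for the extracellular PD-1/PD-L1 complex of PDB entry 4ZQK are
#' packaged under `inst/extdata` (`ss_4zqk_pdl1.tsv`: residues 1-115,
#' `ss_4zqk_pd1.tsv`: residues 116-240).
#'
#' @param path one or more TSV paths.
#' @return a data frame of class `srd_sstable`.
#' @export
read_ss_table <- function(path) {
  tabs <- lapply(path, function(p) {
    if (!file.exists(p)) abort_usage("no such file: ", p)
    utils::read.delim(p, stringsAsFactors = FALSE)
  })
  ss_table(do.call(rbind, tabs))
}

#' Construct/validate a secondary-structure table
#' @param entries data frame with columns `domain`, `res_start`, `res_end`, `kind`.
#' @return the validated table, ordered by `res_start`, class `srd_sstable`.
#' @export
ss_table <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("domain", "res_start", "res_end", "kind")
  if (!all(need %in% names(entries)))
    abort_format("secondary-structure table needs columns: ",
                 paste(need, collapse = ", "))
  if (!all(entries$kind %in% c("strand", "helix", "loop")))
    abort_format("kind must be one of strand/helix/loop")
  if (any(entries$res_start > entries$res_end))
    abort_format("res_start must be <= res_end")
  entries <- entries[order(entries$res_start), , drop = FALSE]
  if (nrow(entries) > 1) {
    gaps <- entries$res_start[-1] - entries$res_end[-nrow(entries)]
    if (any(gaps != 1))
      abort_format("entries must cover a contiguous residue range without overlap")
  }
  rownames(entries) <- NULL
  class(entries) <- c("srd_sstable", "data.frame")
  entries
}

#' Map residue numbers to secondary-structure kind
#' @param sstable an `srd_sstable`.
#' @param residue_numbers integer vector.
#' @return character vector of kinds (`NA` for residues outside the table).
#' @export
ss_kind <- function(sstable, residue_numbers) {
  kind <- rep(NA_character_, length(residue_numbers))
  for (r in seq_len(nrow(sstable))) {
    hit <- residue_numbers >= sstable$res_start[r] &
      residue_numbers <= sstable$res_end[r]
    kind[hit] <- sstable$kind[r]
  }
  kind
}

# ---------------------------------------------------------------------------
# Frame trimming and atom selection

#' Discard the initial part of a trajectory
#'
#' Removes all frames with time (relative to the first frame) strictly
#' below `discard_time`, the usual equilibration-discard step. The
#' resulting frame count is exactly `floor((T - discard_time) / dt_frame)`
#' where `T` is the total duration `n_frames * dt_frame`.
#'
#' @param traj an [srd_trajectory()].
#' @param discard_time time span to drop from the start, ps.
#' @return the trimmed trajectory (`time0` advanced accordingly).
#' @export
trim_frames <- function(traj, discard_time) {
  if (!is.numeric(discard_time) || length(discard_time) != 1 || discard_time < 0)
    abort_usage("discard_time must be a single non-negative number (ps)")
  if (discard_time == 0) return(traj)
  total <- n_frames(traj) * traj$dt_frame
  if (discard_time >= total)
    abort_usage("discard_time (", discard_time, " ps) >= trajectory duration (",
                total, " ps)")
  rel <- (seq_len(n_frames(traj)) - 1) * traj$dt_frame
  keep <- rel >= discard_time
  out <- traj
  out$coords <- traj$coords[keep, , , drop = FALSE]
  out$time0 <- traj$time0 + min(rel[keep])
  out
}

#' Select atoms by a predicate on the atom table
#'
#' @param traj an [srd_trajectory()].
#' @param predicate a function taking the `atoms` data frame and returning
#'   a logical vector over atoms.
#' @return sorted vector of 1-based atom indices.
#' @export
select_atoms <- function(traj, predicate) {
  keep <- predicate(traj$atoms)
  if (!is.logical(keep) || length(keep) != n_atoms(traj))
    abort_usage("predicate must return one logical per atom")
  idx <- sort(unique(which(keep)))
  if (length(idx) == 0) abort_usage("atom selection is empty")
  idx
}

#' Select all C-alpha atoms
#' @param traj an [srd_trajectory()].
#' @return sorted vector of 1-based atom indices.
#' @export
select_calpha <- function(traj) {
  select_atoms(traj, function(a) a$atom_name == "CA")
}

#' Fit selection: backbone atoms within strands and helices
#'
#' The default reference set for rigid-body fitting: backbone atoms
#' (amide N, C-alpha, carbonyl C) of residues annotated as `strand` or
#' `helix` in the secondary-structure table.
#'
#' @param traj an [srd_trajectory()].
#' @param sstable an `srd_sstable`.
#' @param kinds secondary-structure kinds to keep.
#' @param backbone_names atom names counted as backbone.
#' @return sorted vector of 1-based atom indices.
#' @export
fit_selection <- function(traj, sstable, kinds = c("strand", "helix"),
                          backbone_names = c("N", "CA", "C")) {
  select_atoms(traj, function(a) {
    a$atom_name %in% backbone_names &
      ss_kind(sstable, a$residue_number) %in% kinds
  })
}
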