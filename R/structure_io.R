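# Structures, frames and trajectories ----------------------------------------
#
# A Frame is a data.frame of atoms plus a frame index and a time stamp; a
# Trajectory is an ordered list of Frames sharing one topology. Atom identity
# is (chain_id, residue_seq, atom_name) and must be unique within a frame.

#' Default residue names recognized as water
#'
#' PDB dialects differ; TIP3 is the CHARMM name, SOL the GROMACS one.
#' @export
WATER_RESIDUE_NAMES <- c("HOH", "TIP3", "WAT", "SOL")

#' Construct a frame from an atom table
#'
#' @param atoms data.frame with columns `serial`, `atom_name`, `element`,
#'   `residue_name`, `residue_seq`, `chain_id`, `x`, `y`, `z`. Columns
#'   `is_hydrogen` and `is_water` are derived if absent.
#' @param frame_index integer index of this frame within its trajectory.
#' @param time_ps simulation time in picoseconds (>= 0).
#' @param water_names residue names treated as water.
#' @return object of class `iface_frame`.
#' @export
iface_frame <- function(atoms, frame_index = 1L, time_ps = 0,
                        water_names = WATER_RESIDUE_NAMES) {
  required <- c("serial", "atom_name", "element", "residue_name",
                "residue_seq", "chain_id", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$residue_seq <- as.integer(atoms$residue_seq)
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (is.null(atoms$is_hydrogen))
    atoms$is_hydrogen <- infer_hydrogen(atoms$atom_name, atoms$element)
  if (is.null(atoms$is_water))
    atoms$is_water <- atoms$residue_name %in% water_names
  key <- atom_key(atoms)
  if (anyDuplicated(key))
    stop("duplicate atom identity (chain, residue_seq, atom_name): ",
         key[duplicated(key)][1])
  if (time_ps < 0) stop("time_ps must be >= 0")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, frame_index = as.integer(frame_index),
                 time_ps = as.numeric(time_ps)),
            class = "iface_frame")
}

#' @export
print.iface_frame <- function(x, ...) {
  cat(sprintf("<iface_frame> %d atoms, %d chains (%s), t = %g ps\n",
              nrow(x$atoms), length(unique(x$atoms$chain_id)),
              paste(sort(unique(x$atoms$chain_id)), collapse = ","),
              x$time_ps))
  invisible(x)
}

#' Construct a trajectory from frames
#'
#' All frames must share atom count and atom identity ordering; times must be
#' non-decreasing.
#'
#' @param frames list of `iface_frame` objects (at least one).
#' @param replica_label label such as "Equ1".
#' @return object of class `iface_trajectory`.
#' @export
iface_trajectory <- function(frames, replica_label = "Equ1") {
  if (!length(frames)) stop("trajectory needs at least one frame")
  ref_key <- atom_key(frames[[1]]$atoms)
  for (i in seq_along(frames)) {
    if (!inherits(frames[[i]], "iface_frame"))
      stop("frame ", i, " is not an iface_frame")
    if (!identical(atom_key(frames[[i]]$atoms), ref_key))
      stop("frame ", i, " topology differs from frame 1")
    frames[[i]]$frame_index <- i
  }
  times <- vapply(frames, function(f) f$time_ps, numeric(1))
  if (is.unsorted(times)) stop("frame times must be non-decreasing")
  structure(list(frames = frames, replica_label = replica_label),
            class = "iface_trajectory")
}

#' @export
print.iface_trajectory <- function(x, ...) {
  cat(sprintf("<iface_trajectory> %s: %d frames x %d atoms\n",
              x$replica_label, length(x$frames), nrow(x$frames[[1]]$atoms)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `iface_trajectory`.
#' @export
n_frames <- function(traj) length(traj$frames)

atom_key <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_seq, atoms$atom_name, sep = "|")
}

infer_hydrogen <- function(atom_name, element) {
  el <- toupper(trimws(element))
  has_el <- !is.na(el) & nzchar(el)
  out <- logical(length(atom_name))
  out[has_el] <- el[has_el] == "H"
  # no element column: first alphabetic character of the atom name decides
  nm <- toupper(gsub("[^A-Z]", "", toupper(atom_name[!has_el])))
  out[!has_el] <- substr(nm, 1, 1) == "H"
  out
}

infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Z]", "", toupper(atom_name)))
  two <- substr(nm, 1, 2)
  el <- substr(nm, 1, 1)
  el[two %in% c("CL", "NA", "MG", "ZN", "FE", "BR")] <-
    two[two %in% c("CL", "NA", "MG", "ZN", "FE", "BR")]
  el
}

#' Coordinate matrix of a frame
#' @param frame an `iface_frame`.
#' @param idx optional integer row indices.
#' @return numeric n x 3 matrix.
#' @export
frame_coords <- function(frame, idx = NULL) {
  a <- frame$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  cbind(x = a$x, y = a$y, z = a$z)
}

set_frame_coords <- function(frame, idx, xyz) {
  frame$atoms$x[idx] <- xyz[, 1]
  frame$atoms$y[idx] <- xyz[, 2]
  frame$atoms$z[idx] <- xyz[, 3]
  frame
}

# Selections ------------------------------------------------------------------

#' Inclusive residue range on one chain
#'
#' Residue numbering is author (PDB) numbering; both ends are inclusive.
#' Omitting `start`/`end` selects the whole chain.
#'
#' @param chain_id chain identifier.
#' @param start,end first and last residue number (inclusive).
#' @export
residue_range <- function(chain_id, start = -Inf, end = Inf) {
  if (start > end) stop("residue_range: start > end")
  structure(list(chain_id = as.character(chain_id),
                 start = start, end = end),
            class = "iface_residue_range")
}

#' Atom selection specification
#'
#' @param ranges a single `residue_range` or list of them.
#' @param atom_class one of "all", "heavy", "hydrogen", "water_oxygen".
#' @param name_patterns optional glob patterns matched against atom names.
#' @export
selection_spec <- function(ranges,
                           atom_class = c("all", "heavy", "hydrogen",
                                          "water_oxygen"),
                           name_patterns = NULL) {
  atom_class <- match.arg(atom_class)
  if (inherits(ranges, "iface_residue_range")) ranges <- list(ranges)
  if (!length(ranges) || !all(vapply(ranges, inherits, logical(1),
                                     "iface_residue_range")))
    stop("ranges must be residue_range objects")
  structure(list(ranges = ranges, atom_class = atom_class,
                 name_patterns = name_patterns),
            class = "iface_selection")
}

#' Shorthand: select whole chains
#' @param ... chain identifiers.
#' @param atom_class passed to [selection_spec()].
#' @export
chain_selection <- function(..., atom_class = "all") {
  selection_spec(lapply(c(...), residue_range), atom_class = atom_class)
}

#' Resolve a selection to atom row indices
#'
#' Order-stable: returned indices are increasing, so the subset preserves the
#' frame's atom order. Unknown chain ids are an error; an empty result for a
#' known chain is not.
#'
#' @param frame an `iface_frame`.
#' @param spec an `iface_selection`.
#' @return integer vector of row indices into `frame$atoms`.
#' @export
select_atom_indices <- function(frame, spec) {
  a <- frame$atoms
  chains <- unique(vapply(spec$ranges, function(r) r$chain_id, character(1)))
  unknown <- setdiff(chains, unique(a$chain_id))
  if (length(unknown))
    stop("selection names unknown chain(s): ", paste(unknown, collapse = ", "))
  keep <- rep(FALSE, nrow(a))
  for (r in spec$ranges) {
    keep <- keep | (a$chain_id == r$chain_id &
                    a$residue_seq >= r$start & a$residue_seq <= r$end)
  }
  keep <- keep & switch(spec$atom_class,
    all          = TRUE,
    heavy        = !a$is_hydrogen,
    hydrogen     = a$is_hydrogen,
    water_oxygen = a$is_water & infer_or_stored_element(a) == "O")
  if (!is.null(spec$name_patterns)) {
    pat <- paste(vapply(spec$name_patterns, utils::glob2rx, character(1)),
                 collapse = "|")
    keep <- keep & grepl(pat, a$atom_name)
  }
  which(keep)
}

infer_or_stored_element <- function(atoms) {
  el <- toupper(trimws(atoms$element))
  miss <- is.na(el) | !nzchar(el)
  el[miss] <- infer_element(atoms$atom_name[miss])
  el
}

#' Resolve a selection to an atom table
#'
#' @inheritParams select_atom_indices
#' @return subset of `frame$atoms`, frame order preserved.
#' @export
select_atoms <- function(frame, spec) {
  frame$atoms[select_atom_indices(frame, spec), , drop = FALSE]
}

#' Subset a frame to a selection (or to explicit indices)
#' @inheritParams select_atom_indices
#' @param idx integer indices, used instead of `spec` when given.
#' @export
subset_frame <- function(frame, spec = NULL, idx = NULL) {
  if (is.null(idx)) idx <- select_atom_indices(frame, spec)
  frame$atoms <- frame$atoms[idx, , drop = FALSE]
  rownames(frame$atoms) <- NULL
  frame
}

#' Count residues of a range present in a frame
#'
#' Counts distinct residue numbers of the chain within `[start, end]`;
#' residues absent from the structure are simply not counted.
#'
#' @param range a `residue_range`.
#' @param frame an `iface_frame`.
#' @return integer count.
#' @export
residue_range_size <- function(range, frame) {
  a <- frame$atoms
  sel <- a$chain_id == range$chain_id &
    a$residue_seq >= range$start & a$residue_seq <= range$end
  length(unique(a$residue_seq[sel]))
}

# PDB reading and writing ------------------------------------------------------

#' Read a (multi-model) PDB file as a trajectory
#'
#' One frame per MODEL block; a file without MODEL records yields a single
#' frame. Author residue numbering is preserved. Alternate locations keep the
#' highest-occupancy record (tie: altloc "A"). Frame times are
#' `(i - 1) * dt_ps`: the PDB format carries no time axis, so frame spacing
#' is caller-supplied data.
#'
#' @param path file path.
#' @param replica_label label stored on the trajectory.
#' @param dt_ps time between successive frames, ps.
#' @param water_names residue names treated as water.
#' @return an `iface_trajectory`.
#' @export
read_structure <- function(path, replica_label = "Equ1", dt_ps = 1,
                           water_names = WATER_RESIDUE_NAMES) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  atom_line <- rec %in% c("ATOM  ", "HETATM")
  if (!any(atom_line)) stop("no ATOM/HETATM records in ", path)

  if (length(model_starts) == 0) {
    blocks <- list(which(atom_line))
  } else {
    model_ends <- which(trimws(rec) == "ENDMDL")
    if (length(model_ends) < length(model_starts))
      model_ends <- c(model_ends, length(lines))
    blocks <- mapply(function(s, e) {
      idx <- s:e
      idx[atom_line[idx]]
    }, model_starts, model_ends[seq_along(model_starts)], SIMPLIFY = FALSE)
    blocks <- Filter(length, blocks)
  }

  frames <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    atoms <- parse_pdb_atoms(lines[blocks[[i]]], blocks[[i]])
    frames[[i]] <- iface_frame(atoms, frame_index = i,
                               time_ps = (i - 1) * dt_ps,
                               water_names = water_names)
  }
  iface_trajectory(frames, replica_label = replica_label)
}

parse_pdb_atoms <- function(lines, line_numbers) {
  ok <- nchar(lines) >= 54
  if (!all(ok))
    stop("malformed ATOM/HETATM line at line ", line_numbers[!ok][1],
         ": shorter than coordinate fields")
  num <- function(from, to, what) {
    s <- trimws(substr(lines, from, to))
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v))
      stop("malformed ATOM/HETATM line at line ",
           line_numbers[is.na(v)][1], ": bad ", what, " field")
    v
  }
  atoms <- data.frame(
    serial       = as.integer(num(7, 11, "serial")),
    atom_name    = trimws(substr(lines, 13, 16)),
    altloc       = substr(lines, 17, 17),
    residue_name = trimws(substr(lines, 18, 20)),
    chain_id     = trimws(substr(lines, 22, 22)),
    residue_seq  = as.integer(num(23, 26, "residue number")),
    x            = num(31, 38, "x"),
    y            = num(39, 46, "y"),
    z            = num(47, 54, "z"),
    occupancy    = {
      s <- trimws(substr(lines, 55, 60))
      v <- suppressWarnings(as.numeric(s))
      v[is.na(v)] <- 1
      v
    },
    element      = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE
  )
  atoms$chain_id[!nzchar(atoms$chain_id)] <- " "
  miss_el <- !nzchar(atoms$element)
  atoms$element[miss_el] <- infer_element(atoms$atom_name[miss_el])
  resolve_altloc(atoms)
}

# Keep one record per (chain, residue, atom): highest occupancy wins,
# ties prefer altloc "A", then file order.
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$residue_seq, atoms$atom_name, sep = "|")
  if (!anyDuplicated(key)) {
    atoms$altloc <- NULL
    return(atoms)
  }
  pref <- order(key, -atoms$occupancy, atoms$altloc != "A",
                seq_len(nrow(atoms)))
  atoms <- atoms[pref, , drop = FALSE]
  key <- key[pref]
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  atoms <- atoms[order(atoms$serial), , drop = FALSE]
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  atoms
}

#' Write a trajectory (or single frame) as PDB
#'
#' Multi-frame trajectories get one MODEL/ENDMDL block per frame; a
#' single-frame trajectory is written without MODEL records. TER records
#' close each chain; coordinates are written at PDB precision (0.001 A).
#'
#' @param traj an `iface_trajectory` or `iface_frame`.
#' @param path output file path.
#' @export
write_structure <- function(traj, path) {
  if (inherits(traj, "iface_frame"))
    traj <- iface_trajectory(list(traj))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  multi <- length(traj$frames) > 1
  for (i in seq_along(traj$frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(format_pdb_atoms(traj$frames[[i]]$atoms), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(NULL)
}

format_pdb_atoms <- function(atoms) {
  nm <- atoms$atom_name
  # PDB column 13 is blank for names whose element code is one character
  nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$serial %% 100000L, nm4, substr(atoms$residue_name, 1, 3),
    atoms$chain_id, atoms$residue_seq, atoms$x, atoms$y, atoms$z,
    1, 0, atoms$element)
  # TER after each chain block
  chain_end <- c(atoms$chain_id[-1] != atoms$chain_id[-nrow(atoms)], TRUE)
  out <- character(0)
  for (i in seq_along(lines)) {
    out <- c(out, lines[i])
    if (chain_end[i] && !atoms$is_water[i]) out <- c(out, "TER")
  }
  out
}

# Atom parameter tables ---------------------------------------------------------

#' Read an atom parameter table
#'
#' Whitespace-separated columns: chain, residue_seq, atom_name, charge_e,
#' epsilon_kcal_mol, rmin_half_A, radius_A. Lines starting with '#' are
#' comments.
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_param_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("chain", "residue_seq", "atom_name",
                                        "charge_e", "epsilon_kcal_mol",
                                        "rmin_half_A", "radius_A"))
  validate_param_table(df)
  df
}

#' Write an atom parameter table
#' @param params data.frame as produced by [read_param_table()].
#' @param path output path.
#' @export
write_param_table <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chain residue_seq atom_name charge_e epsilon_kcal_mol rmin_half_A radius_A",
             con)
  utils::write.table(params, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(NULL)
}

validate_param_table <- function(df) {
  if (any(df$epsilon_kcal_mol < 0)) stop("epsilon must be >= 0")
  if (any(df$radius_A <= 0)) stop("radius must be > 0")
  invisible(df)
}

# Look up per-atom parameters for a set of atoms; error lists missing atoms.
match_params <- function(atoms, params) {
  key_a <- paste(atoms$chain_id, atoms$residue_seq, atoms$atom_name)
  key_p <- paste(params$chain, params$residue_seq, params$atom_name)
  m <- match(key_a, key_p)
  if (anyNA(m))
    stop("no parameters for atom(s): ",
         paste(utils::head(key_a[is.na(m)], 10), collapse = "; "))
  params[m, , drop = FALSE]
}
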