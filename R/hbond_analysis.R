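# Interfacial hydrogen bonds and survival-ratio statistics -------------------
#
# A hydrogen bond exists between a donor heavy atom D (N or O carrying at
# least one hydrogen within a covalent distance) and an acceptor heavy atom
# A (N or O on the other partner) when the D-A distance is below the
# distance cutoff and the angle H-D-A at the donor is below the angle
# cutoff for at least one hydrogen on D. The survival ratio of a bond over
# one replica is the fraction of analyzed frames in which it is detected.

#' Geometric hydrogen-bond criteria
#'
#' @param max_da_distance_A donor-acceptor distance cutoff, Angstrom.
#' @param max_angle_deg cutoff on the H-D-A angle at the donor, degrees.
#'   `angle_convention = "dha"` instead measures the deviation of the
#'   D-H...A angle from linearity.
#' @param angle_convention "hda" (default) or "dha".
#' @export
hbond_geometry <- function(max_da_distance_A = 3.5, max_angle_deg = 30,
                           angle_convention = c("hda", "dha")) {
  if (max_da_distance_A <= 0 || max_angle_deg <= 0)
    stop("cutoffs must be positive")
  structure(list(max_da_distance_A = max_da_distance_A,
                 max_angle_deg = max_angle_deg,
                 angle_convention = match.arg(angle_convention)),
            class = "hbond_geometry")
}

H_COVALENT_CUTOFF_A <- 1.2

#' Detect interfacial hydrogen bonds in one frame
#'
#' Both donor directions are scanned (side A donating to side B and vice
#' versa); a bond key is direction-specific, so the same atom pair in
#' swapped roles is a distinct key. Donors and acceptors are N/O heavy
#' atoms; a heavy atom is donor-capable iff a hydrogen lies within 1.2 A
#' of it in that frame.
#'
#' @param frame an `iface_frame` with explicit hydrogens.
#' @param side_a,side_b disjoint `iface_selection`s, one per binding partner.
#' @param geom an [hbond_geometry()].
#' @return data.frame, one row per bond: donor/acceptor chain, residue_seq,
#'   residue_name, atom name, and a `key` string.
#' @export
detect_hbonds <- function(frame, side_a, side_b, geom = hbond_geometry()) {
  if (!any(frame$atoms$is_hydrogen))
    stop("frame carries no hydrogens; hydrogen-bearing input is required ",
         "(no distance-only fallback is provided)")
  ia <- select_atom_indices(frame, side_a)
  ib <- select_atom_indices(frame, side_b)
  if (length(intersect(ia, ib))) stop("sides overlap")
  bonds <- rbind(detect_directional(frame, ia, ib, geom),
                 detect_directional(frame, ib, ia, geom))
  rownames(bonds) <- NULL
  bonds
}

empty_bond_table <- function() {
  data.frame(don_chain = character(0), don_resseq = integer(0),
             don_resname = character(0), don_atom = character(0),
             acc_chain = character(0), acc_resseq = integer(0),
             acc_resname = character(0), acc_atom = character(0),
             key = character(0), stringsAsFactors = FALSE)
}

detect_directional <- function(frame, don_side, acc_side, geom) {
  at <- frame$atoms
  el <- infer_or_stored_element(at)
  don_idx <- don_side[!at$is_hydrogen[don_side] & el[don_side] %in% c("N", "O")]
  acc_idx <- acc_side[!at$is_hydrogen[acc_side] & el[acc_side] %in% c("N", "O")]
  h_idx <- which(at$is_hydrogen)
  if (!length(don_idx) || !length(acc_idx) || !length(h_idx))
    return(empty_bond_table())

  D <- frame_coords(frame, don_idx)
  A <- frame_coords(frame, acc_idx)
  H <- frame_coords(frame, h_idx)

  # hydrogens covalently attached to each donor
  DH <- cross_dist(D, H)
  has_h <- rowSums(DH < H_COVALENT_CUTOFF_A) > 0
  if (!any(has_h)) return(empty_bond_table())
  don_idx <- don_idx[has_h]
  D <- D[has_h, , drop = FALSE]
  DH <- DH[has_h, , drop = FALSE]

  DA <- cross_dist(D, A)
  cand <- which(DA < geom$max_da_distance_A, arr.ind = TRUE)
  if (!nrow(cand)) return(empty_bond_table())

  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    d <- cand[k, 1]; a <- cand[k, 2]
    hs <- which(DH[d, ] < H_COVALENT_CUTOFF_A)
    dv <- D[d, ]; av <- A[a, ]
    ang <- vapply(hs, function(h) {
      hv <- H[h, ]
      if (geom$angle_convention == "hda")
        vec_angle_deg(hv - dv, av - dv)
      else
        180 - vec_angle_deg(dv - hv, av - hv)
    }, numeric(1))
    keep[k] <- any(ang < geom$max_angle_deg)
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty_bond_table())

  di <- don_idx[cand[, 1]]
  ai <- acc_idx[cand[, 2]]
  out <- data.frame(
    don_chain = at$chain_id[di], don_resseq = at$residue_seq[di],
    don_resname = at$residue_name[di], don_atom = at$atom_name[di],
    acc_chain = at$chain_id[ai], acc_resseq = at$residue_seq[ai],
    acc_resname = at$residue_name[ai], acc_atom = at$atom_name[ai],
    stringsAsFactors = FALSE)
  out$key <- hbond_key(out)
  out[order(out$key), , drop = FALSE]
}

vec_angle_deg <- function(u, v) {
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cs))) * 180 / pi
}

#' Direction-specific hydrogen-bond key strings
#' @param bonds data.frame as returned by [detect_hbonds()].
#' @return character vector, e.g. `"P:ASP29:OD1>H:GLY33:N"`.
#' @export
hbond_key <- function(bonds) {
  sprintf("%s:%s%d:%s>%s:%s%d:%s",
          bonds$don_chain, bonds$don_resname, bonds$don_resseq,
          bonds$don_atom,
          bonds$acc_chain, bonds$acc_resname, bonds$acc_resseq,
          bonds$acc_atom)
}

#' Per-replica hydrogen-bond survival ratios
#'
#' The ratio of a bond key is (frames in which it is detected) / (frames
#' analyzed), computed after discarding the leading equilibration fraction
#' (ceiling rule). Keys never detected are absent from the result.
#'
#' @param traj an `iface_trajectory`.
#' @inheritParams detect_hbonds
#' @param discard_fraction leading fraction of frames dropped before
#'   counting (equilibration), in [0, 1).
#' @return data.frame: key, donor/acceptor identity columns, `ratio`;
#'   attributes `replica_label` and `n_analyzed`.
#' @export
survival_ratio <- function(traj, side_a, side_b, geom = hbond_geometry(),
                           discard_fraction = 0) {
  if (!length(traj$frames)) stop("empty trajectory")
  if (discard_fraction < 0 || discard_fraction >= 1)
    stop("discard_fraction must be in [0, 1)")
  n <- length(traj$frames)
  drop_n <- ceiling(discard_fraction * n)
  frames <- traj$frames[seq_len(n) > drop_n]
  if (!length(frames)) stop("no frames left after equilibration discard")

  tabs <- lapply(frames, detect_hbonds, side_a = side_a, side_b = side_b,
                 geom = geom)
  all_bonds <- do.call(rbind, tabs)
  if (is.null(all_bonds) || !nrow(all_bonds)) {
    out <- empty_bond_table()
    out$ratio <- numeric(0)
  } else {
    counts <- table(all_bonds$key)
    first <- all_bonds[!duplicated(all_bonds$key), , drop = FALSE]
    first$ratio <- as.numeric(counts[first$key]) / length(frames)
    out <- first[order(-first$ratio, first$key), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "replica_label") <- traj$replica_label
  attr(out, "n_analyzed") <- length(frames)
  out
}

#' Summarize survival ratios across replicas
#'
#' Takes one survival table per replica and produces one row per bond key
#' with the per-replica ratios (absent replicas count as 0), their maximum,
#' arithmetic mean, and sample (n-1) standard deviation, plus the antigen
#' loop class of the bond.
#'
#' @param records named list of survival tables (names = replica labels),
#'   as returned by [survival_ratio()], or any data.frame with `key` and
#'   `ratio` columns.
#' @param antigen_chain chain id of the antigen; the bond's antigen-side
#'   residue (donor if on that chain, else acceptor) is classified.
#' @param loop_ranges named list of `c(start, end)` loop ranges passed to
#'   [classify_loop()].
#' @return data.frame: key, identity columns, one column per replica,
#'   max, ave, std, loop_class.
#' @export
summarize_replicas <- function(records, antigen_chain = "P",
                               loop_ranges = default_loop_ranges()) {
  if (is.null(names(records)) || any(!nzchar(names(records))))
    names(records) <- vapply(seq_along(records), function(i) {
      lb <- attr(records[[i]], "replica_label")
      if (is.null(lb)) paste0("Equ", i) else lb
    }, character(1))
  if (length(records) == 1)
    warning("single replica: std reported as 0")

  keys <- unique(unlist(lapply(records, function(r) r$key)))
  if (!length(keys)) {
    out <- empty_bond_table()
    for (lb in names(records)) out[[lb]] <- numeric(0)
    out$max <- out$ave <- out$std <- numeric(0)
    out$loop_class <- character(0)
    return(out)
  }
  id_cols <- do.call(rbind, lapply(records, function(r)
    r[, setdiff(names(r), "ratio"), drop = FALSE]))
  id_cols <- id_cols[!duplicated(id_cols$key), , drop = FALSE]
  out <- id_cols[match(keys, id_cols$key), , drop = FALSE]

  mat <- sapply(records, function(r) {
    v <- r$ratio[match(keys, r$key)]
    v[is.na(v)] <- 0
    v
  })
  mat <- matrix(mat, nrow = length(keys),
                dimnames = list(NULL, names(records)))
  for (lb in colnames(mat)) out[[lb]] <- mat[, lb]
  out$max <- apply(mat, 1, max)
  out$ave <- rowMeans(mat)
  out$std <- if (ncol(mat) > 1) apply(mat, 1, stats::sd) else 0
  out$loop_class <- vapply(seq_len(nrow(out)), function(i) {
    res <- if (out$don_chain[i] == antigen_chain) out$don_resseq[i]
           else if (out$acc_chain[i] == antigen_chain) out$acc_resseq[i]
           else NA_integer_
    if (is.na(res)) "other" else classify_loop(res, loop_ranges)
  }, character(1))
  rownames(out) <- NULL
  attr(out, "replica_labels") <- names(records)
  out
}

#' Default antigen loop classification ranges
#'
#' N-terminal loop 25-33, BC loop 56-64, FG loop 127-135 (author numbering
#' of the PD-1 ectodomain). The FG upper bound 135 is a reading that keeps
#' residues 133/135 in the FG class.
#' @export
default_loop_ranges <- function() {
  list("N-terminal" = c(25, 33), "BC" = c(56, 64), "FG" = c(127, 135))
}

#' Classify an antigen residue by loop
#'
#' @param residue_seq residue number.
#' @param loop_ranges named list of inclusive `c(start, end)` ranges; must
#'   not overlap.
#' @return the range name, or "other".
#' @export
classify_loop <- function(residue_seq, loop_ranges = default_loop_ranges()) {
  rng <- do.call(rbind, loop_ranges)
  o <- order(rng[, 1])
  if (any(rng[o, 2][-nrow(rng)] >= rng[o, 1][-1]))
    stop("loop ranges overlap")
  for (nm in names(loop_ranges)) {
    r <- loop_ranges[[nm]]
    if (residue_seq >= r[1] && residue_seq <= r[2]) return(nm)
  }
  "other"
}

#' Retain bonds above a maximum-survival threshold
#'
#' Keeps rows whose `max` column, rounded to two decimals (the precision of
#' a printed occupancy table), is at or above the threshold. Rows are
#' ordered by loop class (N-terminal, FG, BC, other) and then by
#' descending first-replica ratio, mirroring publication table layout.
#'
#' @param summaries data.frame from [summarize_replicas()].
#' @param threshold retention threshold on the rounded max (default 0.2).
#' @return filtered, re-ordered data.frame.
#' @export
filter_retained <- function(summaries, threshold = 0.2) {
  keep <- round(summaries$max, 2) >= threshold
  out <- summaries[keep, , drop = FALSE]
  if (!nrow(out)) return(out)
  loop_order <- c("N-terminal", "FG", "BC", "other")
  lc <- if (!is.null(out$loop_class))
    match(out$loop_class, loop_order, nomatch = length(loop_order) + 1)
  else rep(1, nrow(out))
  labels <- attr(summaries, "replica_labels")
  first_col <- if (!is.null(labels) && labels[1] %in% names(out))
    out[[labels[1]]] else out$max
  out <- out[order(lc, -first_col), , drop = FALSE]
  rownames(out) <- NULL
  out
}
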