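# Interface metrics: SASA, interaction energy, aligned RMSD, water counts ----

#' Coulomb constant, kcal A / (mol e^2)
#' @export
COULOMB_KCAL <- 332.0636

#' Default element radii for SASA (Angstrom)
#'
#' Standard heavy-atom van der Waals radii; used when no per-atom parameter
#' table is supplied.
#' @export
ELEMENT_RADII_A <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                     H = 1.20)

# Deterministic quasi-uniform unit sphere points (golden-section spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic quadrature: each heavy atom's solvent sphere (vdW radius +
#' probe) is sampled with a golden-section spiral; a point is accessible if
#' it lies outside every other atom's solvent sphere. Only the selected
#' atoms occlude each other - computing a partner "alone" means selecting
#' only that partner. Hydrogens are excluded.
#'
#' @param frame an `iface_frame`.
#' @param selection an `iface_selection`, or NULL for all non-water atoms.
#' @param probe_A probe radius (water), Angstrom.
#' @param n_points quadrature points per atom.
#' @param params optional parameter table with `radius_A` per atom; element
#'   radii from [ELEMENT_RADII_A] are used when NULL. Missing entries are
#'   an error naming the atoms.
#' @return object of class `sasa_result`: `per_atom` (A^2), `total`,
#'   `probe_radius`, `n_sphere_points`.
#' @export
sasa <- function(frame, selection = NULL, probe_A = 1.4, n_points = 960,
                 params = NULL) {
  if (is.null(selection)) {
    idx <- which(!frame$atoms$is_hydrogen & !frame$atoms$is_water)
  } else {
    selection$atom_class <- "heavy"
    idx <- select_atom_indices(frame, selection)
  }
  if (!length(idx)) stop("sasa: empty selection")
  at <- frame$atoms[idx, , drop = FALSE]
  if (is.null(params)) {
    el <- infer_or_stored_element(at)
    r <- unname(ELEMENT_RADII_A[el])
    if (anyNA(r))
      stop("no default radius for element(s): ",
           paste(unique(el[is.na(r)]), collapse = ", "))
  } else {
    r <- match_params(at, params)$radius_A
  }

  X <- frame_coords(frame, idx)
  R <- r + probe_A
  pts <- sphere_points(n_points)
  n <- length(idx)
  per_atom <- numeric(n)
  D <- cross_dist(X, X)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] < R[i] + R & seq_len(n) != i)
    if (!length(nb)) {
      per_atom[i] <- 4 * pi * R[i]^2
      next
    }
    P <- sweep(pts * R[i], 2, X[i, ], "+")
    occluded <- rep(FALSE, n_points)
    for (j in nb) {
      dj2 <- (P[, 1] - X[j, 1])^2 + (P[, 2] - X[j, 2])^2 +
             (P[, 3] - X[j, 3])^2
      occluded <- occluded | dj2 < R[j]^2
      if (all(occluded)) break
    }
    per_atom[i] <- 4 * pi * R[i]^2 * sum(!occluded) / n_points
  }
  structure(list(per_atom = per_atom, total = sum(per_atom),
                 probe_radius = probe_A, n_sphere_points = n_points,
                 atom_idx = idx),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, total %.1f A^2 (probe %.1f, %d pts)\n",
              length(x$per_atom), x$total, x$probe_radius,
              x$n_sphere_points))
  invisible(x)
}

#' Buried solvent-accessible surface area of an interface
#'
#' SASA(side A alone) + SASA(side B alone) - SASA(A and B together); no
#' halving, so the value covers both faces of the interface. Symmetric in
#' its sides and >= 0 up to quadrature noise.
#'
#' @inheritParams sasa
#' @param side_a,side_b disjoint `iface_selection`s.
#' @return buried area in A^2.
#' @export
buried_sasa <- function(frame, side_a, side_b, probe_A = 1.4,
                        n_points = 960, params = NULL) {
  ia <- heavy_indices(frame, side_a)
  ib <- heavy_indices(frame, side_b)
  if (!length(ia) || !length(ib)) stop("buried_sasa: empty side")
  if (length(intersect(ia, ib))) stop("buried_sasa: sides overlap")
  s <- function(i) sasa(subset_frame(frame, idx = i), probe_A = probe_A,
                        n_points = n_points, params = params)$total
  s(ia) + s(ib) - s(c(ia, ib))
}

# CHARMM-style switching function on [switch_on, cutoff]
switch_factor <- function(r, switch_on, cutoff) {
  s <- ifelse(r <= switch_on, 1,
              ifelse(r >= cutoff, 0,
                     (cutoff^2 - r^2)^2 * (cutoff^2 + 2 * r^2 -
                        3 * switch_on^2) / (cutoff^2 - switch_on^2)^3))
  s
}

#' Pairwise interaction energy between two selections
#'
#' Sum over cross-side atom pairs of Coulomb (k q_i q_j / r, dielectric 1)
#' and Lennard-Jones (eps_ij, rmin_ij with geometric-mean epsilon and
#' arithmetic rmin combination) terms, both multiplied by a CHARMM-style
#' switching function that tapers from 1 at `switch_on_A` to 0 at
#' `cutoff_A`. Values are kcal/mol. This mirrors a pairwise-cutoff
#' post-processing energy, not a PME simulation energy.
#'
#' @param frame an `iface_frame`.
#' @param side_a,side_b `iface_selection`s.
#' @param params parameter table covering every selected atom (charge_e,
#'   epsilon_kcal_mol, rmin_half_A).
#' @param cutoff_A interaction cutoff.
#' @param switch_on_A switching inner radius.
#' @return list (class `energy_breakdown`): `electrostatic`, `vdw`, `total`.
#' @export
interaction_energy <- function(frame, side_a, side_b, params,
                               cutoff_A = 12, switch_on_A = 10) {
  ia <- select_atom_indices(frame, side_a)
  ib <- select_atom_indices(frame, side_b)
  if (!length(ia) || !length(ib)) stop("interaction_energy: empty side")
  pa <- match_params(frame$atoms[ia, , drop = FALSE], params)
  pb <- match_params(frame$atoms[ib, , drop = FALSE], params)
  r <- cross_dist(frame_coords(frame, ia), frame_coords(frame, ib))
  sw <- switch_factor(r, switch_on_A, cutoff_A)
  within <- r < cutoff_A & r > 0

  qq <- outer(pa$charge_e, pb$charge_e)
  elec <- sum((COULOMB_KCAL * qq / r * sw)[within])

  eps <- sqrt(outer(pa$epsilon_kcal_mol, pb$epsilon_kcal_mol))
  rmin <- outer(pa$rmin_half_A, pb$rmin_half_A, "+")
  s6 <- (rmin / r)^6
  vdw <- sum((eps * (s6^2 - 2 * s6) * sw)[within])

  structure(list(electrostatic = elec, vdw = vdw, total = elec + vdw),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> elec %.3f + vdw %.3f = %.3f kcal/mol\n",
              x$electrostatic, x$vdw, x$total))
  invisible(x)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping the mobile frame's fit
#' atoms onto the reference's. Atoms are matched by identity
#' (chain, residue, atom name); a proper rotation (det = +1) is always
#' returned.
#'
#' @param mobile,reference `iface_frame`s.
#' @param fit_selection `iface_selection` resolving to the same >= 3
#'   non-collinear heavy atoms in both frames.
#' @return list (class `rigid_transform`): `rotation` 3x3, `translation`
#'   3-vector; apply with [apply_transform()].
#' @export
superpose_kabsch <- function(mobile, reference, fit_selection) {
  mi <- heavy_indices(mobile, fit_selection)
  ri <- heavy_indices(reference, fit_selection)
  km <- atom_key(mobile$atoms[mi, , drop = FALSE])
  kr <- atom_key(reference$atoms[ri, , drop = FALSE])
  mm <- match(kr, km)
  if (anyNA(mm))
    stop("fit atoms missing from mobile frame: ",
         paste(utils::head(kr[is.na(mm)], 5), collapse = "; "))
  P <- frame_coords(mobile, mi[mm])     # mobile, reference order
  Q <- frame_coords(reference, ri)
  if (nrow(P) < 3) stop("need at least 3 fit atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))          # 3x3 H = P^T Q
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) fit atoms")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  structure(list(rotation = R, translation = as.numeric(cq - R %*% cp)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param transform a `rigid_transform`.
#' @param xyz n x 3 coordinate matrix.
#' @export
apply_transform <- function(transform, xyz) {
  sweep(xyz %*% t(transform$rotation), 2, transform$translation, "+")
}

rmsd_xyz <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

#' Partner-aligned segment RMSD series
#'
#' For every frame: superpose the frame onto the reference using the fit
#' selection (typically the fixed binding partner), then measure the heavy-
#' atom RMSD of the rmsd selection against the reference without refitting.
#' Global rigid motion of the whole complex therefore cancels; what remains
#' is the segment's motion relative to the partner.
#'
#' @param traj an `iface_trajectory`.
#' @param reference an `iface_frame`.
#' @param fit_selection selection used for superposition (e.g. the
#'   antibody).
#' @param rmsd_selection selection whose displacement is measured (e.g. the
#'   antigen's terminal loop or IgV domain).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
aligned_segment_rmsd <- function(traj, reference, fit_selection,
                                 rmsd_selection) {
  ref_idx <- heavy_indices(reference, rmsd_selection)
  if (!length(ref_idx)) stop("rmsd selection is empty in reference")
  ref_keys <- atom_key(reference$atoms[ref_idx, , drop = FALSE])
  ref_xyz <- frame_coords(reference, ref_idx)
  vapply(traj$frames, function(fr) {
    tf <- superpose_kabsch(fr, reference, fit_selection)
    idx <- heavy_indices(fr, rmsd_selection)
    keys <- atom_key(fr$atoms[idx, , drop = FALSE])
    m <- match(ref_keys, keys)
    if (anyNA(m))
      stop("rmsd atoms missing from frame ", fr$frame_index, ": ",
           paste(utils::head(ref_keys[is.na(m)], 5), collapse = "; "))
    rmsd_xyz(apply_transform(tf, frame_coords(fr, idx[m])), ref_xyz)
  }, numeric(1))
}

#' Count water molecules near a selection
#'
#' A water counts if its oxygen lies within `radius_A` (inclusive) of any
#' heavy atom of the selection. Distinct molecules are identified by
#' (chain, residue number).
#'
#' @param frame an `iface_frame`.
#' @param selection `iface_selection` (heavy atoms are used).
#' @param radius_A inclusive distance cutoff.
#' @return integer count.
#' @export
count_waters_within <- function(frame, selection, radius_A = 4.0) {
  sel_idx <- heavy_indices(frame, selection)
  if (!length(sel_idx)) stop("count_waters_within: empty selection")
  at <- frame$atoms
  wo <- which(at$is_water & infer_or_stored_element(at) == "O")
  if (!length(wo)) return(0L)
  D <- cross_dist(frame_coords(frame, wo), frame_coords(frame, sel_idx))
  near <- apply(D, 1, min) <= radius_A
  length(unique(paste(at$chain_id[wo[near]], at$residue_seq[wo[near]])))
}
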