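# Scenario construction: segment truncation and rigid rotation ---------------
#
# The binding-order scenarios are built from a native complex frame: cut a
# terminal segment off, or swing a segment 90 degrees away from the binding
# partner about a hinge at the segment boundary, leaving everything else
# untouched.

#' Remove a residue segment from a frame
#'
#' All atoms of the segment are deleted; the remaining atoms keep their order
#' and coordinates. The residue left adjacent to the cut is recorded as
#' capping metadata (no cap atoms are built - caps matter to an MD engine,
#' not to geometric analysis).
#'
#' @param frame an `iface_frame`.
#' @param segment a `residue_range` resolving to at least one residue.
#' @return an `iface_frame` with attribute `"new_terminus"` naming the
#'   first retained residue of the cut chain.
#' @export
truncate_segment <- function(frame, segment) {
  a <- frame$atoms
  in_seg <- a$chain_id == segment$chain_id &
    a$residue_seq >= segment$start & a$residue_seq <= segment$end
  if (!any(in_seg))
    stop("segment resolves to no residues: chain ", segment$chain_id,
         " ", segment$start, "-", segment$end)
  chain_rows <- a$chain_id == segment$chain_id
  if (sum(in_seg) == sum(chain_rows))
    stop("refusing to truncate: segment covers the whole chain ",
         segment$chain_id)
  remaining <- a$residue_seq[chain_rows & !in_seg]
  new_term <- if (any(remaining > segment$end))
    min(remaining[remaining > segment$end]) else max(remaining)
  out <- frame
  out$atoms <- a[!in_seg, , drop = FALSE]
  rownames(out$atoms) <- NULL
  attr(out, "new_terminus") <- list(chain_id = segment$chain_id,
                                    residue_seq = new_term,
                                    cap = "acetyl/amide metadata only")
  out
}

#' Plan a rigid rotation of a segment away from a partner
#'
#' The pivot is the C-alpha of the hinge residue: the residue bordering the
#' segment on the retained body's side (the residue adjacent to the segment
#' on its chain, outside the segment). The axis is the normalized cross
#' product of (segment centroid - pivot) and (partner centroid - pivot);
#' the sign of the angle is chosen so the rotated segment centroid moves
#' away from the partner centroid ("backward at the interface").
#'
#' @param frame an `iface_frame`.
#' @param segment `residue_range` to rotate.
#' @param partner `iface_selection` for the fixed binding partner.
#' @param angle_deg rotation magnitude in degrees, in (-360, 360].
#' @return a `rotation_plan` with fields segment, hinge_residue, axis_unit,
#'   pivot, angle_deg.
#' @export
plan_rotation <- function(frame, segment, partner, angle_deg = 90) {
  if (angle_deg <= -360 || angle_deg > 360)
    stop("angle_deg must lie in (-360, 360]")
  seg_idx <- select_atom_indices(
    frame, selection_spec(segment, atom_class = "heavy"))
  par_idx <- select_atom_indices(frame, partner)
  if (!length(seg_idx)) stop("segment selection is empty")
  if (!length(par_idx)) stop("partner selection is empty")

  a <- frame$atoms
  chain_res <- sort(unique(a$residue_seq[a$chain_id == segment$chain_id]))
  seg_res <- chain_res[chain_res >= segment$start & chain_res <= segment$end]
  body_res <- setdiff(chain_res, seg_res)
  if (!length(body_res))
    stop("segment covers the whole chain; no hinge residue exists")
  # hinge: body residue numerically adjacent to the segment boundary
  hinge <- if (any(body_res > max(seg_res)))
    min(body_res[body_res > max(seg_res)]) else max(body_res[body_res < min(seg_res)])
  ca <- which(a$chain_id == segment$chain_id & a$residue_seq == hinge &
                a$atom_name == "CA")
  if (!length(ca))
    stop("hinge residue ", hinge, " has no CA atom")
  pivot <- as.numeric(frame_coords(frame, ca[1]))

  seg_cen <- colMeans(frame_coords(frame, seg_idx))
  par_cen <- colMeans(frame_coords(frame, par_idx))
  v1 <- seg_cen - pivot
  v2 <- par_cen - pivot
  ax <- cross3(v1, v2)
  nrm <- sqrt(sum(ax^2))
  if (nrm < 1e-8 * sqrt(sum(v1^2)) * sqrt(sum(v2^2)) || nrm == 0) {
    warning("degenerate geometry (collinear centroids); using fallback axis")
    ax <- fallback_axis(v2)
  } else {
    ax <- ax / nrm
  }

  plan <- rotation_plan(segment, hinge, ax, pivot, angle_deg)
  # "backward": pick the sign that increases segment-partner separation
  d0 <- sqrt(sum((seg_cen - par_cen)^2))
  dplus <- centroid_distance_after(frame, seg_idx, par_cen, plan)
  plan_neg <- plan; plan_neg$angle_deg <- -angle_deg
  dminus <- centroid_distance_after(frame, seg_idx, par_cen, plan_neg)
  if (dminus > dplus) plan <- plan_neg
  plan
}

rotation_plan <- function(segment, hinge_residue, axis_unit, pivot,
                          angle_deg) {
  axis_unit <- as.numeric(axis_unit)
  if (abs(sqrt(sum(axis_unit^2)) - 1) > 1e-9)
    stop("axis_unit must have unit norm")
  structure(list(segment = segment, hinge_residue = as.integer(hinge_residue),
                 axis_unit = axis_unit, pivot = as.numeric(pivot),
                 angle_deg = angle_deg),
            class = "rotation_plan")
}

centroid_distance_after <- function(frame, seg_idx, par_cen, plan) {
  rot <- rotate_segment(frame, plan)
  sqrt(sum((colMeans(frame_coords(rot, seg_idx)) - par_cen)^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# unit vector orthogonal to v, smallest-index convention
fallback_axis <- function(v) {
  i <- which.min(abs(v))
  e <- c(0, 0, 0); e[i] <- 1
  ax <- cross3(v, e)
  ax / sqrt(sum(ax^2))
}

#' Rotation matrix about a unit axis (Rodrigues)
#' @param axis_unit unit 3-vector.
#' @param angle_deg angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis_unit, angle_deg) {
  th <- angle_deg * pi / 180
  u <- axis_unit / sqrt(sum(axis_unit^2))
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rotation plan to a frame
#'
#' Segment atoms (all atom classes, hydrogens included) are rotated rigidly
#' about (axis, pivot); every other atom is untouched.
#'
#' @param frame an `iface_frame`.
#' @param plan a `rotation_plan`.
#' @return rotated `iface_frame`.
#' @export
rotate_segment <- function(frame, plan) {
  idx <- select_atom_indices(
    frame, selection_spec(plan$segment, atom_class = "all"))
  if (!length(idx)) stop("rotation segment resolves to no atoms")
  R <- rotation_matrix(plan$axis_unit, plan$angle_deg)
  xyz <- frame_coords(frame, idx)
  xyz <- sweep(xyz, 2, plan$pivot) %*% t(R)
  xyz <- sweep(xyz, 2, plan$pivot, "+")
  set_frame_coords(frame, idx, xyz)
}

#' Steric clash report between two selections
#'
#' Reports the minimum heavy-atom distance across the two selections and
#' every pair below the cutoff.
#'
#' @param frame an `iface_frame`.
#' @param a,b disjoint `iface_selection`s.
#' @param cutoff_A clash cutoff in Angstrom.
#' @return a `clash_report`: min_distance_A, n_pairs_below_cutoff,
#'   offending_pairs (data.frame).
#' @export
clash_check <- function(frame, a, b, cutoff_A = 2.0) {
  ia <- heavy_indices(frame, a)
  ib <- heavy_indices(frame, b)
  if (!length(ia) || !length(ib)) stop("clash_check: empty selection")
  if (length(intersect(ia, ib)))
    stop("clash_check: selections overlap")
  D <- cross_dist(frame_coords(frame, ia), frame_coords(frame, ib))
  below <- which(D < cutoff_A, arr.ind = TRUE)
  at <- frame$atoms
  pairs <- data.frame(
    atom_a = atom_key(at[ia[below[, 1]], , drop = FALSE]),
    atom_b = atom_key(at[ib[below[, 2]], , drop = FALSE]),
    distance_A = D[below],
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$distance_A), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(min_distance_A = min(D),
                 n_pairs_below_cutoff = nrow(pairs),
                 offending_pairs = pairs,
                 cutoff_A = cutoff_A),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf("<clash_report> min distance %.3f A; %d pair(s) below %.1f A\n",
              x$min_distance_A, x$n_pairs_below_cutoff, x$cutoff_A))
  invisible(x)
}

heavy_indices <- function(frame, spec) {
  spec$atom_class <- "heavy"
  select_atom_indices(frame, spec)
}

cross_dist <- function(A, B) {
  # ||a-b|| via the expansion; clamp tiny negatives from rounding
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}
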