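# Synthetic two-body complexes with known ground truth -----------------------
#
# The generator emulates, at toy scale, an antigen with a rigid body (an
# IgV-like domain) plus a flexible terminal loop, bound to a two-chain
# antibody. Specific donor-acceptor contacts follow scripted Bernoulli
# on/off schedules with known occupancy: in an "on" frame the acceptor
# oxygen sits collinear with the donor N-H at 2.8 A (well inside the
# 3.5 A / 30 deg criteria), in an "off" frame it is displaced to 6.5 A.
# Everything else is rigid, so every pipeline stage can be checked against
# stored ground truth. Geometry is cartoonish on purpose: residues are
# 4-atom stubs (CA, N, H, O) laid out so that no accidental cross-side
# contact satisfies the bond criteria.

#' Specification of a synthetic complex
#'
#' @param n_frames number of trajectory frames (>= 1).
#' @param seed RNG seed controlling the Bernoulli bond schedules.
#' @param loop_residues antigen terminal-loop residue numbers (chain P).
#' @param body_residues antigen body residue numbers (chain P).
#' @param n_heavy,n_light residues in the antibody heavy (H) and light (L)
#'   chain blobs.
#' @param bond_schedules data.frame with columns `donor_res` (antigen
#'   residue carrying the engineered N-H donor), `acceptor_chain` ("H" or
#'   "L"), `acceptor_res`, `occupancy` in [0, 1].
#' @param rotation_angle_deg starting angle for rotation-scenario
#'   trajectories (see [generate_rotation_trajectory()]).
#' @param dt_ps time between frames, ps.
#' @return list of class `toy_spec`.
#' @export
toy_spec <- function(n_frames = 200, seed = 1,
                     loop_residues = 25:33, body_residues = 34:45,
                     n_heavy = 8, n_light = 6,
                     bond_schedules = default_bond_schedules(),
                     rotation_angle_deg = 90, dt_ps = 200) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (any(bond_schedules$occupancy < 0 | bond_schedules$occupancy > 1))
    stop("occupancies must lie in [0, 1]")
  if (!all(bond_schedules$donor_res %in% c(loop_residues, body_residues)))
    stop("schedule donors must be antigen residues")
  if (!all(bond_schedules$acceptor_chain %in% c("H", "L")))
    stop("acceptor chains must be H or L")
  structure(list(n_frames = as.integer(n_frames), seed = as.integer(seed),
                 loop_residues = loop_residues,
                 body_residues = body_residues,
                 n_heavy = n_heavy, n_light = n_light,
                 bond_schedules = bond_schedules,
                 rotation_angle_deg = rotation_angle_deg,
                 dt_ps = dt_ps),
            class = "toy_spec")
}

#' Default scripted bond schedules
#'
#' Three bonds on the terminal loop (residues 28-30) and two on the body
#' (residues 36 and 40, standing in for the BC/FG epitope), at occupancies
#' spanning the range seen in real occupancy tables.
#' @export
default_bond_schedules <- function() {
  data.frame(
    donor_res      = c(29L, 30L, 28L, 36L, 40L),
    acceptor_chain = c("H", "H", "H", "L", "H"),
    acceptor_res   = c(33L, 31L, 99L, 56L, 101L),
    occupancy      = c(0.9, 0.5, 0.3, 0.7, 0.4),
    stringsAsFactors = FALSE)
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# residue stub: CA at base, N at +y with its hydrogen 1.0 A along `dir`
# (the engineered bond direction), O acceptor at -y
residue_stub <- function(chain, resseq, resname, base, dir = c(1, 0, 0)) {
  N <- base + c(0, 1.5, 0)
  H <- N + dir
  O <- base + c(0, -1.5, 0)
  data.frame(
    serial = NA_integer_,
    atom_name = c("N", "CA", "O", "HN"),
    element = c("N", "C", "O", "H"),
    residue_name = resname,
    residue_seq = resseq,
    chain_id = chain,
    x = c(N[1], base[1], O[1], H[1]),
    y = c(N[2], base[2], O[2], H[2]),
    z = c(N[3], base[3], O[3], H[3]),
    stringsAsFactors = FALSE)
}

# static layout of the toy complex; returns the atom table of the frame
# with every scheduled bond ON, plus bookkeeping for the toggling atoms
toy_layout <- function(spec) {
  atoms <- list()
  # antigen body: along -x, starting just behind the hinge at x = -4.
  # Body bond sites point +z so they clear the 3 A residue spacing.
  for (j in seq_along(spec$body_residues)) {
    r <- spec$body_residues[j]
    atoms[[length(atoms) + 1]] <-
      residue_stub("P", r, "ALA", c(-4 - 3 * (j - 1), 0, 0),
                   dir = c(0, 0, 1))
  }
  # terminal loop: a rank at x = 4, spread along y so engineered bond
  # sites stay >= 6 A apart; centroid off the body axis so the rotation
  # geometry is non-degenerate
  for (k in seq_along(spec$loop_residues)) {
    r <- spec$loop_residues[k]
    atoms[[length(atoms) + 1]] <-
      residue_stub("P", r, "SER", c(4, 6 * (k - 1) - 12, 0))
  }
  # antibody blobs, far enough (>= 4.5 A) from every antigen atom
  for (j in seq_len(spec$n_heavy)) {
    atoms[[length(atoms) + 1]] <-
      residue_stub("H", j, "GLY", c(16 + 3 * ((j - 1) %% 4), 30,
                                    4 * ((j - 1) %/% 4)))
  }
  for (j in seq_len(spec$n_light)) {
    atoms[[length(atoms) + 1]] <-
      residue_stub("L", j, "GLY", c(16 + 3 * ((j - 1) %% 4), 42,
                                    4 * ((j - 1) %/% 4)))
  }
  at <- do.call(rbind, atoms)

  # engineered acceptor residues (CA + O only) keyed to their donor N
  sched <- spec$bond_schedules
  toggles <- data.frame(row_on_x = numeric(0))
  acc_rows <- integer(0)
  on_xyz <- off_xyz <- matrix(0, nrow(sched), 3)
  for (s in seq_len(nrow(sched))) {
    dn <- which(at$chain_id == "P" & at$residue_seq == sched$donor_res[s] &
                  at$atom_name == "N")
    dh <- which(at$chain_id == "P" & at$residue_seq == sched$donor_res[s] &
                  at$atom_name == "HN")
    stopifnot(length(dn) == 1, length(dh) == 1)
    N <- c(at$x[dn], at$y[dn], at$z[dn])
    dir <- c(at$x[dh], at$y[dh], at$z[dh]) - N   # unit by construction
    on_xyz[s, ] <- N + 2.8 * dir
    off_xyz[s, ] <- N + 6.5 * dir
    ca_pos <- N + 4.0 * dir + c(0, 2.5, 0)
    acc <- data.frame(
      serial = NA_integer_,
      atom_name = c("CA", "O"),
      element = c("C", "O"),
      residue_name = "GLY",
      residue_seq = sched$acceptor_res[s],
      chain_id = sched$acceptor_chain[s],
      x = c(ca_pos[1], on_xyz[s, 1]),
      y = c(ca_pos[2], on_xyz[s, 2]),
      z = c(ca_pos[3], on_xyz[s, 3]),
      stringsAsFactors = FALSE)
    acc_rows <- c(acc_rows, nrow(at) + 2L)   # the O row
    at <- rbind(at, acc)
  }
  if (anyDuplicated(paste(at$chain_id, at$residue_seq, at$atom_name)))
    stop("unrealizable toy geometry: duplicate atom identities ",
         "(schedule acceptor residues collide with blob residues?)")
  at$serial <- seq_len(nrow(at))
  list(atoms = at, acceptor_o_rows = acc_rows,
       on_xyz = on_xyz, off_xyz = off_xyz)
}

toy_params <- function(atoms) {
  prm <- data.frame(chain = atoms$chain_id, residue_seq = atoms$residue_seq,
                    atom_name = atoms$atom_name, stringsAsFactors = FALSE)
  el <- atoms$element
  # round toy numbers; per-stub charges sum to zero
  prm$charge_e <- c(N = -0.47, C = 0.66, O = -0.50, H = 0.31)[el]
  prm$epsilon_kcal_mol <- c(N = 0.20, C = 0.11, O = 0.12, H = 0.046)[el]
  prm$rmin_half_A <- c(N = 1.85, C = 2.00, O = 1.70, H = 0.225)[el]
  prm$radius_A <- c(N = 1.55, C = 1.70, O = 1.52, H = 1.20)[el]
  is_w <- atoms$residue_name %in% WATER_RESIDUE_NAMES
  prm$charge_e[is_w] <- -0.834
  rownames(prm) <- NULL
  prm
}

#' Expected hydrogen-bond keys of a toy spec
#' @param spec a `toy_spec`.
#' @param layout internal; reuses a computed layout.
#' @return character vector of direction-specific bond keys, one per
#'   schedule row.
#' @export
toy_bond_keys <- function(spec, layout = toy_layout(spec)) {
  sched <- spec$bond_schedules
  at <- layout$atoms
  resname_of <- function(ch, rs) at$residue_name[at$chain_id == ch &
                                                   at$residue_seq == rs][1]
  vapply(seq_len(nrow(sched)), function(s)
    sprintf("P:%s%d:N>%s:%s%d:O",
            resname_of("P", sched$donor_res[s]), sched$donor_res[s],
            sched$acceptor_chain[s],
            resname_of(sched$acceptor_chain[s], sched$acceptor_res[s]),
            sched$acceptor_res[s]),
    character(1))
}

#' Generate a synthetic complex trajectory with scripted bond schedules
#'
#' Deterministic for a fixed seed. Each scheduled bond is realized per
#' frame by an independent Bernoulli draw at its occupancy; the acceptor
#' oxygen toggles between the bonded and the displaced position, all other
#' atoms are static.
#'
#' @param spec a [toy_spec()].
#' @param replica_label replica label for the trajectory.
#' @return list: `trajectory` (`iface_trajectory`), `params` (parameter
#'   table), `truth` (ground truth: `keys`, `occupancy` named by key,
#'   `on_matrix` frames x bonds, `realized_ratio`).
#' @export
generate_toy_complex <- function(spec = toy_spec(), replica_label = "Equ1") {
  layout <- toy_layout(spec)
  sched <- spec$bond_schedules
  keys <- toy_bond_keys(spec, layout)
  on_mat <- with_seed(spec$seed, {
    matrix(stats::runif(spec$n_frames * nrow(sched)) <
             rep(sched$occupancy, each = spec$n_frames),
           nrow = spec$n_frames)
  })
  colnames(on_mat) <- keys

  frames <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    at <- layout$atoms
    off <- !on_mat[t, ]
    if (any(off)) {
      rows <- layout$acceptor_o_rows[off]
      at$x[rows] <- layout$off_xyz[off, 1]
      at$y[rows] <- layout$off_xyz[off, 2]
      at$z[rows] <- layout$off_xyz[off, 3]
    }
    frames[[t]] <- iface_frame(at, frame_index = t,
                               time_ps = (t - 1) * spec$dt_ps)
  }
  truth <- list(keys = keys,
                occupancy = stats::setNames(sched$occupancy, keys),
                on_matrix = on_mat,
                realized_ratio = stats::setNames(colMeans(on_mat), keys))
  list(trajectory = iface_trajectory(frames, replica_label),
       params = toy_params(layout$atoms),
       truth = truth)
}

#' Generate a rotated-segment return trajectory
#'
#' The antigen terminal loop starts rotated by `spec$rotation_angle_deg`
#' about the hinge (the planned rotation away from the antibody) and
#' interpolates linearly back to 0 degrees over the frames, with the
#' antibody and antigen body fixed - the synthetic analogue of a displaced
#' segment re-binding its partner. All scheduled bonds are "on" in the
#' underlying native geometry, so the final frame recovers them.
#'
#' @param spec a [toy_spec()].
#' @param replica_label replica label.
#' @return list: `trajectory`, `params`, `truth` (per-frame `angle_deg`
#'   and the exact rigid-rotation `rmsd` of the loop's heavy atoms
#'   relative to the native frame), `native_frame`, `plan`.
#' @export
generate_rotation_trajectory <- function(spec = toy_spec(),
                                         replica_label = "Equ1") {
  layout <- toy_layout(spec)
  base <- iface_frame(layout$atoms, frame_index = 1, time_ps = 0)
  segment <- residue_range("P", min(spec$loop_residues),
                           max(spec$loop_residues))
  partner <- chain_selection("H", "L")
  plan <- plan_rotation(base, segment, partner,
                        angle_deg = spec$rotation_angle_deg)

  n <- spec$n_frames
  angles <- if (n == 1) plan$angle_deg else
    plan$angle_deg * (1 - (seq_len(n) - 1) / (n - 1))
  seg_idx <- select_atom_indices(
    base, selection_spec(segment, atom_class = "heavy"))
  base_xyz <- frame_coords(base, seg_idx)

  frames <- vector("list", n)
  rmsd_true <- numeric(n)
  for (t in seq_len(n)) {
    p <- plan; p$angle_deg <- angles[t]
    fr <- rotate_segment(base, p)
    fr$frame_index <- t
    fr$time_ps <- (t - 1) * spec$dt_ps
    frames[[t]] <- fr
    rmsd_true[t] <- rmsd_xyz(frame_coords(fr, seg_idx), base_xyz)
  }
  list(trajectory = iface_trajectory(frames, replica_label),
       params = toy_params(layout$atoms),
       truth = list(angle_deg = angles, rmsd = rmsd_true),
       native_frame = base, plan = plan)
}

#' Add a deterministic water shell around a selection
#'
#' Water oxygens are placed on golden-spiral directions around the centroid
#' of the target's heavy atoms, at radii stepping across the radial band.
#' The expected number of waters within `count_radius_A` of the target is
#' computed exhaustively and stored, so the placement needs no tuning.
#'
#' @param frame an `iface_frame`.
#' @param target `iface_selection` the shell surrounds.
#' @param n_waters number of water molecules (single-oxygen waters).
#' @param band `c(inner, outer)` radial band from the target centroid, A.
#' @param min_clearance_A minimum allowed water-water distance; a band too
#'   narrow to hold `n_waters` at this spacing is a generation error.
#'   Candidate positions closer than this to a solute atom are dropped
#'   (the shell wraps the solute, it does not interpenetrate it).
#' @param count_radius_A radius used for the stored expected count.
#' @return list: `frame` (augmented), `expected_count`, `n_placed`,
#'   `water_chain`.
#' @export
place_water_shell <- function(frame, target, n_waters = 20,
                              band = c(3, 6), min_clearance_A = 2.0,
                              count_radius_A = 4.0) {
  if (band[1] > band[2] || band[1] <= min_clearance_A)
    stop("radial band must satisfy outer >= inner > clearance")
  idx <- heavy_indices(frame, target)
  if (!length(idx)) stop("empty target selection")
  cen <- colMeans(frame_coords(frame, idx))
  dirs <- sphere_points(n_waters)
  radii <- band[1] + (seq_len(n_waters) - 0.5) / n_waters *
    (band[2] - band[1])
  pos <- sweep(dirs * radii, 2, cen, "+")

  if (n_waters > 1) {
    dw <- cross_dist(pos, pos); diag(dw) <- Inf
    if (min(dw) < min_clearance_A)
      stop("water band too dense: waters closer than ", min_clearance_A,
           " A to each other")
  }
  prot <- frame_coords(frame)
  keep <- apply(cross_dist(pos, prot), 1, min) >= min_clearance_A
  if (!any(keep))
    stop("water band too dense: every candidate sits within ",
         min_clearance_A, " A of a solute atom")
  pos <- pos[keep, , drop = FALSE]
  n_placed <- nrow(pos)

  waters <- data.frame(
    serial = max(frame$atoms$serial, 0) + seq_len(n_placed),
    atom_name = "O", element = "O", residue_name = "HOH",
    residue_seq = seq_len(n_placed), chain_id = "W",
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    stringsAsFactors = FALSE)
  out <- frame
  out$atoms <- rbind(frame$atoms[, names(waters)], waters)
  out <- iface_frame(out$atoms, frame_index = frame$frame_index,
                     time_ps = frame$time_ps)

  d_target <- cross_dist(pos, frame_coords(frame, idx))
  expected <- sum(apply(d_target, 1, min) <= count_radius_A)
  list(frame = out, expected_count = expected, n_placed = n_placed,
       water_chain = "W")
}
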