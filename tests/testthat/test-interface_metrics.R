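# SASA, buried SASA, interaction energy, Kabsch, aligned RMSD, water counts

single_atom_frame <- function() quick_frame("CA", "C", 0, 0, 0)

test_that("sasa matches isolated-sphere and two-sphere analytic areas", {
  # single atom, element radius 1.7, probe 1.4 -> 4*pi*3.1^2
  s1 <- sasa(single_atom_frame(), probe_A = 1.4, n_points = 960)
  expect_equal(s1$total, 4 * pi * 3.1^2, tolerance = 0.01)

  # two atoms far apart: sum of isolated spheres
  fr2 <- quick_frame(c("CA", "N"), c("C", "N"), x = c(0, 100),
                     y = c(0, 0), z = c(0, 0), residue_seq = c(1L, 2L))
  s2 <- sasa(fr2)
  expect_equal(s2$total, 4 * pi * (3.1^2 + 2.95^2), tolerance = 0.01)

  # overlapping spheres vs the closed-form spherical-cap formula
  prm <- data.frame(chain = "P", residue_seq = c(1L, 2L),
                    atom_name = c("X1", "X2"), charge_e = 0,
                    epsilon_kcal_mol = 0, rmin_half_A = 1,
                    radius_A = c(1.9, 1.7))
  fr3 <- quick_frame(c("X1", "X2"), c("C", "C"), x = c(0, 3),
                     y = c(0, 0), z = c(0, 0), residue_seq = c(1L, 2L))
  s3 <- sasa(fr3, params = prm, probe_A = 1.4, n_points = 960)
  analytic <- two_sphere_area(1.9 + 1.4, 1.7 + 1.4, 3.0)
  expect_equal(s3$total, analytic, tolerance = 0.01)
  expect_equal(s3$total, sum(s3$per_atom))
})

test_that("quadrature error shrinks as n_points grows", {
  fr <- quick_frame(c("X1", "X2"), c("C", "C"), x = c(0, 3),
                    y = c(0, 0), z = c(0, 0), residue_seq = c(1L, 2L))
  prm <- data.frame(chain = "P", residue_seq = c(1L, 2L),
                    atom_name = c("X1", "X2"), charge_e = 0,
                    epsilon_kcal_mol = 0, rmin_half_A = 1,
                    radius_A = c(1.9, 1.7))
  analytic <- two_sphere_area(3.3, 3.1, 3.0)
  errs <- vapply(c(60, 240, 960, 3840), function(np)
    abs(sasa(fr, params = prm, n_points = np)$total - analytic), numeric(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("missing radii raise a parameter error naming atoms", {
  prm <- data.frame(chain = "P", residue_seq = 1L, atom_name = "X1",
                    charge_e = 0, epsilon_kcal_mol = 0, rmin_half_A = 1,
                    radius_A = 1.9)
  fr <- quick_frame(c("X1", "X2"), c("C", "C"), x = c(0, 3), y = c(0, 0),
                    z = c(0, 0), residue_seq = c(1L, 2L))
  expect_error(sasa(fr, params = prm), "X2")
})

test_that("buried SASA: symmetry, far-separation zero, compositional oracle", {
  g <- generate_toy_complex(toy_spec(n_frames = 1, seed = 6))
  fr <- g$trajectory$frames[[1]]
  ab <- buried_sasa(fr, antigen_side(), antibody_side(), n_points = 480)
  ba <- buried_sasa(fr, antibody_side(), antigen_side(), n_points = 480)
  expect_equal(ab, ba)
  expect_gt(ab, 0)

  # compositional: sum-minus-union assembled by hand from sasa()
  ia <- select_atom_indices(fr, selection_spec(residue_range("P"), "heavy"))
  ihl <- setdiff(which(!fr$atoms$is_hydrogen),
                 c(ia, which(fr$atoms$is_water)))
  by_hand <- sasa(subset_frame(fr, idx = ia), n_points = 480)$total +
    sasa(subset_frame(fr, idx = ihl), n_points = 480)$total -
    sasa(subset_frame(fr, idx = c(ia, ihl)), n_points = 480)$total
  expect_equal(ab, by_hand, tolerance = 1e-9)

  # pull the partners 100 A apart: buried area vanishes
  far <- fr
  hl <- far$atoms$chain_id %in% c("H", "L")
  far$atoms$x[hl] <- far$atoms$x[hl] + 100
  expect_equal(buried_sasa(far, antigen_side(), antibody_side(),
                           n_points = 480), 0, tolerance = 1e-6)
  # bound: buried <= SASA(a) + SASA(b)
  expect_lt(ab, sasa(subset_frame(fr, idx = ia), n_points = 480)$total +
              sasa(subset_frame(fr, idx = ihl), n_points = 480)$total)
})

test_that("Coulomb hand oracle and cutoff behaviour", {
  prm <- data.frame(chain = c("P", "H"), residue_seq = 1L,
                    atom_name = "Q", charge_e = c(1, -1),
                    epsilon_kcal_mol = 0, rmin_half_A = 1, radius_A = 1.5)
  fr5 <- quick_frame(c("Q", "Q"), c("N", "N"), x = c(0, 5), y = c(0, 0),
                     z = c(0, 0), chain_id = c("P", "H"))
  e <- interaction_energy(fr5, antigen_side(), chain_selection("H"), prm)
  expect_equal(e$electrostatic, 332.0636 * (-1) / 5, tolerance = 1e-9)
  expect_equal(e$vdw, 0)
  expect_equal(e$total, e$electrostatic + e$vdw)

  fr13 <- quick_frame(c("Q", "Q"), c("N", "N"), x = c(0, 13), y = c(0, 0),
                      z = c(0, 0), chain_id = c("P", "H"))
  e13 <- interaction_energy(fr13, antigen_side(), chain_selection("H"), prm)
  expect_equal(e13$total, 0)
})

test_that("interaction energy equals the brute-force double loop", {
  g <- generate_toy_complex(toy_spec(n_frames = 2, seed = 9))
  fr <- g$trajectory$frames[[1]]
  ia <- select_atom_indices(fr, antigen_side())
  ib <- select_atom_indices(fr, antibody_side())
  e <- interaction_energy(fr, antigen_side(), antibody_side(), g$params)
  o <- oracle_energy(fr, ia, ib, g$params)
  expect_equal(e$electrostatic, o$elec, tolerance = 1e-9)
  expect_equal(e$vdw, o$vdw, tolerance = 1e-9)

  # symmetry in side order; additivity over a partition of side b
  e_swap <- interaction_energy(fr, antibody_side(), antigen_side(),
                               g$params)
  expect_equal(e_swap$total, e$total, tolerance = 1e-9)
  eh <- interaction_energy(fr, antigen_side(), chain_selection("H"),
                           g$params)
  el <- interaction_energy(fr, antigen_side(), chain_selection("L"),
                           g$params)
  expect_equal(eh$total + el$total, e$total, tolerance = 1e-9)
})

test_that("Kabsch recovers identity and known rotations", {
  fr <- make_complex_frame()
  tf <- superpose_kabsch(fr, fr, chain_selection("H"))
  expect_equal(tf$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tf$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)

  R30 <- rotation_matrix(c(1, 1, 0) / sqrt(2), 30)
  moved <- fr
  xyz <- frame_coords(fr) %*% t(R30)
  moved$atoms$x <- xyz[, 1] + 2
  moved$atoms$y <- xyz[, 2] - 1
  moved$atoms$z <- xyz[, 3] + 4
  tf2 <- superpose_kabsch(moved, fr, chain_selection("H"))
  # recovered rotation undoes R30
  expect_lt(max(abs(tf2$rotation %*% R30 - diag(3))), 1e-6)
  fitted <- apply_transform(tf2, frame_coords(moved))
  expect_lt(max(abs(fitted - frame_coords(fr))), 1e-6)
})

test_that("Kabsch on noisy clouds beats any coarse rotation grid", {
  set.seed(21)
  P <- matrix(rnorm(60), ncol = 3)
  Rtrue <- rotation_matrix(c(0, 1, 2) / sqrt(5), 40)
  Q <- P %*% t(Rtrue) + matrix(rnorm(60, sd = 0.1), ncol = 3)
  mk <- function(M, ch) quick_frame(paste0("C", 1:20), rep("C", 20),
                                    M[, 1], M[, 2], M[, 3], chain_id = ch,
                                    residue_seq = 1:20)
  mob <- mk(P, "P"); ref <- mk(Q, "P")
  tf <- superpose_kabsch(mob, ref, chain_selection("P"))
  r_kabsch <- sqrt(mean(rowSums(
    (apply_transform(tf, P) - Q)^2)))
  # coarse grid over axis-angle space
  cp <- colMeans(P); cq <- colMeans(Q)
  best <- Inf
  for (ax in list(c(1,0,0), c(0,1,0), c(0,0,1), c(0,1,2)/sqrt(5),
                  c(1,1,1)/sqrt(3)))
    for (ang in seq(0, 350, by = 10)) {
      Rg <- rotation_matrix(ax, ang)
      Pg <- sweep(sweep(P, 2, cp) %*% t(Rg), 2, cq, "+")
      best <- min(best, sqrt(mean(rowSums((Pg - Q)^2))))
    }
  expect_lte(r_kabsch, best + 1e-12)
  expect_error(superpose_kabsch(
    quick_frame(c("A","B","C"), rep("C",3), c(0,1,2), c(0,0,0), c(0,0,0),
                residue_seq = 1:3),
    quick_frame(c("A","B","C"), rep("C",3), c(0,1,2), c(0,0,0), c(0,0,0),
                residue_seq = 1:3),
    chain_selection("P")), "collinear")
})

test_that("aligned segment RMSD: zeros, closed form, rigid-motion invariance", {
  rt <- generate_rotation_trajectory(toy_spec(n_frames = 15, seed = 2))
  fit <- antibody_side()
  seg <- selection_spec(residue_range("P", 25, 33))

  # repeated reference -> all zeros
  const <- iface_trajectory(rep(list(rt$native_frame), 4))
  expect_equal(aligned_segment_rmsd(const, rt$native_frame, fit, seg),
               rep(0, 4), tolerance = 1e-9)

  # rotation series matches the exact rigid-rotation RMSD from ground truth
  r <- aligned_segment_rmsd(rt$trajectory, rt$native_frame, fit, seg)
  expect_equal(r, rt$truth$rmsd, tolerance = 1e-6)
  # monotone return to the native pose
  expect_true(all(diff(r) <= 1e-9))

  # a global rigid motion of whole frames changes nothing
  moved <- iface_trajectory(lapply(rt$trajectory$frames, rigid_move,
                                   axis = c(2, 1, 0), angle_deg = 50,
                                   shift = c(10, -3, 7)))
  expect_equal(aligned_segment_rmsd(moved, rt$native_frame, fit, seg), r,
               tolerance = 1e-6)
})

test_that("closed-form check: constant 90-degree rotation series", {
  spec <- toy_spec(n_frames = 3)
  rt <- generate_rotation_trajectory(spec)
  base <- rt$native_frame
  plan <- rt$plan
  seg_idx <- select_atom_indices(
    base, selection_spec(residue_range("P", 25, 33), "heavy"))
  X <- sweep(frame_coords(base, seg_idx), 2, plan$pivot)
  R <- rotation_matrix(plan$axis_unit, plan$angle_deg)
  closed_form <- sqrt(mean(rowSums((X %*% t(R) - X)^2)))
  rot <- rotate_segment(base, plan)
  traj <- iface_trajectory(list(rot, rot))
  r <- aligned_segment_rmsd(traj, base, antibody_side(),
                            selection_spec(residue_range("P", 25, 33)))
  expect_equal(r, rep(closed_form, 2), tolerance = 1e-9)
})

test_that("water counts: boundary inclusion and exhaustive oracle", {
  fr <- make_complex_frame()
  loop <- selection_spec(residue_range("P", 25, 27))
  loop_idx <- select_atom_indices(
    fr, selection_spec(residue_range("P", 25, 27), "heavy"))
  a1 <- frame_coords(fr, loop_idx[1])

  add_waters <- function(frame, pos) {
    w <- data.frame(serial = max(frame$atoms$serial) + seq_len(nrow(pos)),
                    atom_name = "O", element = "O", residue_name = "HOH",
                    residue_seq = seq_len(nrow(pos)), chain_id = "W",
                    x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    stringsAsFactors = FALSE)
    iface_frame(rbind(frame$atoms[, names(w)], w))
  }
  # no waters at all
  expect_equal(count_waters_within(fr, loop), 0L)
  # one at 3.9 A, one at 4.1 A from a loop atom (along -y, away from rest)
  frw <- add_waters(fr, rbind(a1 - c(0, 3.9, 0), a1 - c(0, 4.1, 0)))
  expect_equal(count_waters_within(frw, loop, 4.0), 1L)

  # dense synthetic shell equals the brute-force count
  g <- generate_toy_complex(toy_spec(n_frames = 1, seed = 13))
  shell <- place_water_shell(g$trajectory$frames[[1]],
                             selection_spec(residue_range("P", 25, 33)),
                             n_waters = 30, band = c(4.5, 7))
  got <- count_waters_within(shell$frame,
                             selection_spec(residue_range("P", 25, 33)))
  sel_idx <- select_atom_indices(
    shell$frame, selection_spec(residue_range("P", 25, 33), "heavy"))
  expect_equal(got, oracle_water_count(shell$frame, sel_idx))
  expect_equal(got, shell$expected_count)
})

test_that("energy and SASA are invariant under global rigid motion", {
  g <- generate_toy_complex(toy_spec(n_frames = 1, seed = 17))
  fr <- g$trajectory$frames[[1]]
  moved <- rigid_move(fr, axis = c(1, 3, 1), angle_deg = 67,
                      shift = c(-8, 2, 14))
  e0 <- interaction_energy(fr, antigen_side(), antibody_side(), g$params)
  e1 <- interaction_energy(moved, antigen_side(), antibody_side(),
                           g$params)
  expect_equal(e1$total, e0$total, tolerance = 1e-9)
  s0 <- buried_sasa(fr, antigen_side(), antibody_side(), n_points = 240)
  s1 <- buried_sasa(moved, antigen_side(), antibody_side(), n_points = 240)
  expect_equal(s1, s0, tolerance = 0.05)   # quadrature grid is body-fixed
})
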