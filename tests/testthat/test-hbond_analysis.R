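# Hydrogen-bond detection, survival ratios, replica summaries, retention

hb_frame <- function(acc_x, h = c(1, 0, 0)) {
  # donor N at origin with one hydrogen, acceptor O on the other chain
  quick_frame(c("N", "HN", "O"), c("N", "H", "O"),
              x = c(0, h[1], acc_x[1]), y = c(0, h[2], acc_x[2]),
              z = c(0, h[3], acc_x[3]),
              chain_id = c("P", "P", "H"), residue_seq = c(1L, 1L, 1L))
}

test_that("geometric criteria: collinear ideal, distance and angle cutoffs", {
  geom <- hbond_geometry()
  ok <- detect_hbonds(hb_frame(c(2.8, 0, 0)), antigen_side(),
                      chain_selection("H"), geom)
  expect_equal(nrow(ok), 1)
  expect_equal(ok$key, "P:ALA1:N>H:ALA1:O")

  # distance >= 3.5 fails
  expect_equal(nrow(detect_hbonds(hb_frame(c(3.6, 0, 0)), antigen_side(),
                                  chain_selection("H"), geom)), 0)
  # acceptor at 3.0 A but 45 degrees off the D-H direction fails
  a45 <- 3.0 * c(cos(45 * pi / 180), sin(45 * pi / 180), 0)
  expect_equal(nrow(detect_hbonds(hb_frame(a45), antigen_side(),
                                  chain_selection("H"), geom)), 0)
  # 25 degrees passes
  a25 <- 3.0 * c(cos(25 * pi / 180), sin(25 * pi / 180), 0)
  expect_equal(nrow(detect_hbonds(hb_frame(a25), antigen_side(),
                                  chain_selection("H"), geom)), 1)
})

test_that("hydrogen-free input is an explicit error", {
  fr <- quick_frame(c("N", "O"), c("N", "O"), x = c(0, 2.8), y = c(0, 0),
                    z = c(0, 0), chain_id = c("P", "H"),
                    residue_seq = c(1L, 1L))
  expect_error(detect_hbonds(fr, antigen_side(), chain_selection("H")),
               "no hydrogens")
})

test_that("detector equals the exhaustive triple-loop oracle", {
  # irregular pseudo-random frames, both chains rich in N/O/H
  for (seed in c(7, 8, 9)) {
    set.seed(seed)
    n <- 60
    at <- data.frame(
      serial = 1:n,
      atom_name = sample(c("N", "O", "HN", "CA", "OG", "ND2"), n, TRUE),
      residue_name = "ALA",
      residue_seq = rep(1:10, length.out = n),
      chain_id = rep(c("P", "H"), each = n / 2),
      x = round(runif(n, 0, 12), 3), y = round(runif(n, 0, 8), 3),
      z = round(runif(n, 0, 8), 3), stringsAsFactors = FALSE)
    at$element <- substr(at$atom_name, 1, 1)
    # de-duplicate identities
    at$atom_name <- paste0(at$atom_name, seq_len(n))
    fr <- iface_frame(at)
    ia <- select_atom_indices(fr, antigen_side())
    ib <- select_atom_indices(fr, chain_selection("H"))
    got <- detect_hbonds(fr, antigen_side(), chain_selection("H"))
    expect_identical(sort(got$key), oracle_hbonds(fr, ia, ib),
                     label = paste("seed", seed))
  }
})

test_that("detection is invariant under global rigid transforms", {
  g <- generate_toy_complex(toy_spec(n_frames = 1, seed = 4))
  fr <- g$trajectory$frames[[1]]
  base <- detect_hbonds(fr, antigen_side(), antibody_side())
  moved <- rigid_move(fr, axis = c(1, 2, 2), angle_deg = 73,
                      shift = c(-4, 9, 2))
  expect_identical(detect_hbonds(moved, antigen_side(),
                                 antibody_side())$key, base$key)
})

test_that("survival ratios count detection frames exactly", {
  # scripted 41-of-100 schedule
  sched <- data.frame(donor_res = 29L, acceptor_chain = "H",
                      acceptor_res = 33L, occupancy = 0.41)
  g <- generate_toy_complex(toy_spec(n_frames = 100, seed = 123,
                                     bond_schedules = sched))
  # force exactly 41 on-frames by regenerating until realized == scheduled
  # is unnecessary: assert against the realized truth instead, then build
  # an exact 41/100 trajectory from the on-matrix
  sr <- survival_ratio(g$trajectory, antigen_side(), antibody_side())
  expect_equal(unname(sr$ratio[match(g$truth$keys, sr$key)]),
               unname(g$truth$realized_ratio))

  # exact-count construction: 41 on-frames then 59 off-frames
  frames <- g$trajectory$frames
  on_idx <- which(g$truth$on_matrix[, 1])
  off_idx <- which(!g$truth$on_matrix[, 1])
  pick <- c(rep(on_idx[1], 41), rep(off_idx[1], 59))
  traj41 <- iface_trajectory(lapply(seq_along(pick), function(i) {
    f <- frames[[pick[i]]]; f$frame_index <- i; f$time_ps <- i - 1; f
  }))
  sr41 <- survival_ratio(traj41, antigen_side(), antibody_side())
  expect_equal(sr41$ratio, 0.41)
})

test_that("equilibration discard uses the ceiling rule before counting", {
  sched <- data.frame(donor_res = 29L, acceptor_chain = "H",
                      acceptor_res = 33L, occupancy = 0.5)
  g <- generate_toy_complex(toy_spec(n_frames = 101, seed = 42,
                                     bond_schedules = sched))
  sr <- survival_ratio(g$trajectory, antigen_side(), antibody_side(),
                       discard_fraction = 0.2)
  expect_equal(attr(sr, "n_analyzed"), 80)   # 101 - ceiling(20.2)
  kept <- g$truth$on_matrix[22:101, 1]
  expect_equal(sr$ratio[sr$key == g$truth$keys[1]], mean(kept))
})

test_that("replica summaries reproduce printed-table arithmetic", {
  mk <- function(ratios) {
    df <- data.frame(don_chain = "P", don_resseq = 29L, don_resname = "ASP",
                     don_atom = "OD1", acc_chain = "H", acc_resseq = 33L,
                     acc_resname = "GLY", acc_atom = "N",
                     key = "P:ASP29:OD1>H:GLY33:N",
                     ratio = ratios, stringsAsFactors = FALSE)
    df
  }
  recs <- list(Equ1 = mk(0.52), Equ2 = mk(0.70), Equ3 = mk(0.76))
  s <- summarize_replicas(recs)
  expect_equal(round(s$max, 2), 0.76)
  expect_equal(round(s$ave, 2), 0.66)
  expect_equal(round(s$std, 2), 0.12)          # n-1 std, frozen from print
  expect_equal(s$loop_class, "N-terminal")

  recs2 <- list(Equ1 = mk(0.37), Equ2 = mk(0.15), Equ3 = mk(0.08))
  s2 <- summarize_replicas(recs2)
  expect_equal(round(c(s2$max, s2$ave, s2$std), 2), c(0.37, 0.20, 0.15))

  # a bond absent from one replica counts as ratio 0 there
  recs3 <- list(Equ1 = mk(0.30), Equ2 = mk(0.30)[0, ], Equ3 = mk(0.30))
  s3 <- summarize_replicas(recs3)
  expect_equal(s3$Equ2, 0)
  expect_equal(s3$ave, 0.2)
  expect_gte(s3$max, s3$ave)

  expect_warning(summarize_replicas(list(Equ1 = mk(0.3))), "single replica")
})

test_that("retention filter is inclusive at the rounded threshold and monotone", {
  t2 <- ingest_printed_table(printed_table_path("table2"))
  # bond 17 prints max exactly 0.20 and must be retained
  kept <- filter_retained(t2, 0.2)
  expect_true(17 %in% kept$bond_no)
  expect_equal(nrow(filter_retained(t2, 1.1)), 0)
  # monotone: raising the threshold never adds rows
  n_prev <- Inf
  for (th in c(0.1, 0.2, 0.3, 0.5, 0.8)) {
    n <- nrow(filter_retained(t2, th))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("loop classification follows the configured ranges", {
  expect_equal(classify_loop(29), "N-terminal")
  expect_equal(classify_loop(61), "BC")
  expect_equal(classify_loop(131), "FG")
  expect_equal(classify_loop(200), "other")
  expect_error(classify_loop(29, list(A = c(1, 10), B = c(5, 20))),
               "overlap")
})
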