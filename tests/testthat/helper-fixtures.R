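# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (explicit loops, closed forms) and share no code with
# the package internals they check.

# quick frame from parallel vectors
quick_frame <- function(atom_name, element, x, y, z,
                        chain_id = "P", residue_seq = 1L,
                        residue_name = "ALA", time_ps = 0) {
  n <- length(atom_name)
  iface_frame(data.frame(
    serial = seq_len(n),
    atom_name = atom_name, element = element,
    residue_name = rep_len(residue_name, n),
    residue_seq = rep_len(as.integer(residue_seq), n),
    chain_id = rep_len(chain_id, n),
    x = x, y = y, z = z, stringsAsFactors = FALSE), time_ps = time_ps)
}

# a small two-chain protein-like frame with assorted elements
make_complex_frame <- function(n_res_a = 6, n_res_b = 6, gap = 8) {
  rows <- list()
  add_res <- function(chain, rs, base) {
    data.frame(
      serial = NA_integer_,
      atom_name = c("N", "CA", "C", "O", "HN"),
      element = c("N", "C", "C", "O", "H"),
      residue_name = "ALA", residue_seq = rs, chain_id = chain,
      x = base[1] + c(0, 1.2, 2.2, 2.6, -0.9),
      y = base[2] + c(0, 0.8, 0, -1.1, 0.4),
      z = base[3] + c(0, 0, 0.6, 0.6, -0.3),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_res_a))
    rows[[length(rows) + 1]] <- add_res("P", i + 24L, c(3.5 * i, 0, 0))
  for (i in seq_len(n_res_b))
    rows[[length(rows) + 1]] <- add_res("H", i, c(3.5 * i, gap, 1))
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  iface_frame(at)
}

rigid_move <- function(frame, axis = c(0, 0, 1), angle_deg = 25,
                       shift = c(3, -2, 5)) {
  R <- rotation_matrix(axis / sqrt(sum(axis^2)), angle_deg)
  xyz <- frame_coords(frame) %*% t(R)
  frame$atoms$x <- xyz[, 1] + shift[1]
  frame$atoms$y <- xyz[, 2] + shift[2]
  frame$atoms$z <- xyz[, 3] + shift[3]
  frame
}

# --- oracles ----------------------------------------------------------------

# exhaustive triple-loop H-bond detector (donor heavy / hydrogen / acceptor)
oracle_hbonds <- function(frame, idx_a, idx_b, max_da = 3.5, max_ang = 30) {
  at <- frame$atoms
  el <- ifelse(nzchar(at$element), toupper(at$element),
               substr(gsub("[^A-Za-z]", "", at$atom_name), 1, 1))
  pos <- function(i) c(at$x[i], at$y[i], at$z[i])
  keys <- character(0)
  for (sides in list(c(1, 2), c(2, 1))) {
    don_side <- list(idx_a, idx_b)[[sides[1]]]
    acc_side <- list(idx_a, idx_b)[[sides[2]]]
    for (d in don_side) {
      if (at$is_hydrogen[d] || !(el[d] %in% c("N", "O"))) next
      for (a in acc_side) {
        if (at$is_hydrogen[a] || !(el[a] %in% c("N", "O"))) next
        rda <- sqrt(sum((pos(d) - pos(a))^2))
        if (rda >= max_da || rda == 0) next
        for (h in which(at$is_hydrogen)) {
          if (sqrt(sum((pos(h) - pos(d))^2)) >= 1.2) next
          v1 <- pos(h) - pos(d); v2 <- pos(a) - pos(d)
          ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                   sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          if (ang < max_ang) {
            keys <- c(keys, sprintf("%s:%s%d:%s>%s:%s%d:%s",
                                    at$chain_id[d], at$residue_name[d],
                                    at$residue_seq[d], at$atom_name[d],
                                    at$chain_id[a], at$residue_name[a],
                                    at$residue_seq[a], at$atom_name[a]))
            break
          }
        }
      }
    }
  }
  sort(unique(keys))
}

# brute-force pairwise energy with CHARMM switching
oracle_energy <- function(frame, idx_a, idx_b, params,
                          cutoff = 12, ron = 10) {
  at <- frame$atoms
  key <- paste(params$chain, params$residue_seq, params$atom_name)
  p_of <- function(i) params[match(paste(at$chain_id[i], at$residue_seq[i],
                                         at$atom_name[i]), key), ]
  elec <- vdw <- 0
  for (i in idx_a) for (j in idx_b) {
    r <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                (at$z[i] - at$z[j])^2)
    if (r >= cutoff || r == 0) next
    s <- if (r <= ron) 1 else
      (cutoff^2 - r^2)^2 * (cutoff^2 + 2 * r^2 - 3 * ron^2) /
      (cutoff^2 - ron^2)^3
    pi_ <- p_of(i); pj <- p_of(j)
    elec <- elec + 332.0636 * pi_$charge_e * pj$charge_e / r * s
    eps <- sqrt(pi_$epsilon_kcal_mol * pj$epsilon_kcal_mol)
    rmin <- pi_$rmin_half_A + pj$rmin_half_A
    vdw <- vdw + eps * ((rmin / r)^12 - 2 * (rmin / r)^6) * s
  }
  list(elec = elec, vdw = vdw, total = elec + vdw)
}

# analytic SASA of two intersecting solvent spheres (radii already
# probe-expanded): total exposed area of both
two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  x2 <- d - x1
  a1 <- 4 * pi * R1^2 - 2 * pi * R1 * (R1 - x1)
  a2 <- 4 * pi * R2^2 - 2 * pi * R2 * (R2 - x2)
  a1 + a2
}

# exhaustive water count: distinct waters with oxygen within r of any
# selection heavy atom
oracle_water_count <- function(frame, sel_idx, radius = 4.0) {
  at <- frame$atoms
  waters <- unique(at$residue_seq[at$is_water])
  n <- 0
  for (w in waters) {
    o <- which(at$is_water & at$residue_seq == w & at$atom_name == "O")
    hit <- FALSE
    for (i in sel_idx) {
      if (at$is_hydrogen[i]) next
      if (sqrt((at$x[o] - at$x[i])^2 + (at$y[o] - at$y[i])^2 +
                 (at$z[o] - at$z[i])^2) <= radius) { hit <- TRUE; break }
    }
    n <- n + hit
  }
  n
}

antigen_side <- function() chain_selection("P")
antibody_side <- function() chain_selection("H", "L")
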