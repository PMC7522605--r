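# Study-design orchestration --------------------------------------------------
#
# One config carries every threshold of the analysis (hydrogen-bond
# geometry 3.5 A / 30 deg, retention 0.2, water radius 4.0 A, clash 2.0 A,
# energy cutoff 12 A with switching from 10 A, 20% equilibration discard)
# so that a report is regenerable from config + inputs alone.

#' Analysis run configuration
#'
#' @param antigen_chain,heavy_chain,light_chain chain identifiers.
#' @param n_loop,igv `c(start, end)` residue ranges of the antigen
#'   terminal loop and IgV-like body segment.
#' @param loop_ranges loop classification ranges (see [classify_loop()]).
#' @param geom an [hbond_geometry()].
#' @param retention_threshold maximum-survival retention cutoff.
#' @param water_radius_A water-accessibility radius.
#' @param clash_cutoff_A steric guard for built scenarios.
#' @param energy_cutoff_A,energy_switch_on_A nonbonded cutoff/switch radii.
#' @param equilibration_fraction leading fraction of frames discarded.
#' @param rotation_angle_deg scenario rotation magnitude.
#' @param seed seed recorded for provenance.
#' @export
run_config <- function(antigen_chain = "P", heavy_chain = "H",
                       light_chain = "L",
                       n_loop = c(25, 33), igv = c(34, 143),
                       loop_ranges = default_loop_ranges(),
                       geom = hbond_geometry(),
                       retention_threshold = 0.2,
                       water_radius_A = 4.0,
                       clash_cutoff_A = 2.0,
                       energy_cutoff_A = 12, energy_switch_on_A = 10,
                       equilibration_fraction = 0.2,
                       rotation_angle_deg = 90,
                       seed = 1L) {
  cfg <- list(antigen_chain = antigen_chain, heavy_chain = heavy_chain,
              light_chain = light_chain, n_loop = n_loop, igv = igv,
              loop_ranges = loop_ranges, geom = geom,
              retention_threshold = retention_threshold,
              water_radius_A = water_radius_A,
              clash_cutoff_A = clash_cutoff_A,
              energy_cutoff_A = energy_cutoff_A,
              energy_switch_on_A = energy_switch_on_A,
              equilibration_fraction = equilibration_fraction,
              rotation_angle_deg = rotation_angle_deg,
              seed = as.integer(seed))
  class(cfg) <- "iface_config"
  cfg
}

config_sides <- function(cfg) {
  list(antigen = chain_selection(cfg$antigen_chain),
       antibody = chain_selection(cfg$heavy_chain, cfg$light_chain))
}

#' Build every binding scenario from native complexes
#'
#' For each native input frame, four systems are produced: the native
#' complex, the loop-truncated complex, the loop rotated 90 degrees away
#' from the antibody, and the body (IgV) segment rotated 90 degrees away.
#' Rotated constructs must pass a steric clash check against everything
#' that stayed fixed, or the build fails with the offending report.
#'
#' @param natives named list of `iface_frame` native complexes.
#' @param config a [run_config()].
#' @return named list (one entry per input) of scenario lists, each with
#'   `frame` and (for rotated builds) `clash_report` and `plan`.
#' @export
build_all_scenarios <- function(natives, config = run_config()) {
  if (!length(natives)) stop("no native inputs")
  if (is.null(names(natives)))
    names(natives) <- paste0("complex", seq_along(natives))
  sides <- config_sides(config)
  lapply(natives, function(fr) {
    loop_rng <- residue_range(config$antigen_chain,
                              config$n_loop[1], config$n_loop[2])
    igv_rng <- residue_range(config$antigen_chain,
                             config$igv[1], config$igv[2])
    list(
      native = list(frame = fr),
      n_truncated = list(frame = truncate_segment(fr, loop_rng)),
      n_rotated = build_rotated(fr, loop_rng, sides$antibody, config),
      igv_rotated = build_rotated(fr, igv_rng, sides$antibody, config))
  })
}

build_rotated <- function(frame, segment, partner, config) {
  plan <- plan_rotation(frame, segment, partner,
                        angle_deg = config$rotation_angle_deg)
  rotated <- rotate_segment(frame, plan)
  seg_sel <- selection_spec(segment, atom_class = "heavy")
  seg_idx <- select_atom_indices(rotated, seg_sel)
  rest_idx <- setdiff(seq_len(nrow(rotated$atoms)),
                      select_atom_indices(
                        rotated, selection_spec(segment, atom_class = "all")))
  rest_idx <- rest_idx[!rotated$atoms$is_hydrogen[rest_idx]]
  report <- clash_check_idx(rotated, seg_idx, rest_idx,
                            config$clash_cutoff_A)
  if (report$n_pairs_below_cutoff > 0)
    stop("rotated build clashes (", report$n_pairs_below_cutoff,
         " pair(s) below ", config$clash_cutoff_A, " A); closest: ",
         report$offending_pairs$atom_a[1], " - ",
         report$offending_pairs$atom_b[1])
  list(frame = rotated, clash_report = report, plan = plan)
}

# clash check on explicit index sets (internal; clash_check() is the
# selection-based public face)
clash_check_idx <- function(frame, ia, ib, cutoff_A = 2.0) {
  D <- cross_dist(frame_coords(frame, ia), frame_coords(frame, ib))
  below <- which(D < cutoff_A, arr.ind = TRUE)
  at <- frame$atoms
  pairs <- data.frame(
    atom_a = atom_key(at[ia[below[, 1]], , drop = FALSE]),
    atom_b = atom_key(at[ib[below[, 2]], , drop = FALSE]),
    distance_A = D[below], stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$distance_A), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(min_distance_A = min(D),
                 n_pairs_below_cutoff = nrow(pairs),
                 offending_pairs = pairs, cutoff_A = cutoff_A),
            class = "clash_report")
}

#' Run the full interface analysis over replica trajectories
#'
#' @param trajectories nested named list: scenario -> replica label ->
#'   `iface_trajectory`.
#' @param params atom parameter table covering all analyzed atoms (needed
#'   for the energy metric; NULL skips energies).
#' @param config a [run_config()].
#' @param metrics character subset of c("hbonds", "sasa", "energy",
#'   "waters") to compute per frame.
#' @return `report_bundle`: `bond_tables` (per scenario, retention filter
#'   applied), `series` (long data.frame of per-frame metrics),
#'   `provenance`.
#' @export
run_analysis <- function(trajectories, params = NULL,
                         config = run_config(),
                         metrics = c("hbonds", "sasa")) {
  if (!length(trajectories)) stop("no trajectories configured")
  if (is.null(names(trajectories)))
    stop("trajectories must be a named list (scenario -> replica -> traj)")
  sides <- config_sides(config)
  bond_tables <- list()
  series_rows <- list()

  for (scen in names(trajectories)) {
    reps <- trajectories[[scen]]
    if (!length(reps)) stop("scenario ", scen, " has an empty replica list")
    records <- list()
    for (lb in names(reps)) {
      traj <- reps[[lb]]
      records[[lb]] <- survival_ratio(
        traj, sides$antigen, sides$antibody, config$geom,
        discard_fraction = config$equilibration_fraction)
      series_rows[[length(series_rows) + 1]] <-
        frame_metric_rows(traj, scen, lb, sides, params, config, metrics)
    }
    summaries <- summarize_replicas(records,
                                    antigen_chain = config$antigen_chain,
                                    loop_ranges = config$loop_ranges)
    bond_tables[[scen]] <- filter_retained(summaries,
                                           config$retention_threshold)
  }

  structure(list(
    bond_tables = bond_tables,
    series = do.call(rbind, series_rows),
    provenance = list(config = config,
                      package_version =
                        as.character(utils::packageVersion("ifacedyn")),
                      timestamp = NA)),   # deterministic output: no clock
    class = "report_bundle")
}

frame_metric_rows <- function(traj, scen, lb, sides, params, config,
                              metrics) {
  rows <- lapply(traj$frames, function(fr) {
    out <- data.frame(system = scen, replica = lb,
                      frame = fr$frame_index, time_ps = fr$time_ps,
                      stringsAsFactors = FALSE)
    if ("hbonds" %in% metrics)
      out$n_hbonds <- nrow(detect_hbonds(fr, sides$antigen,
                                         sides$antibody, config$geom))
    if ("sasa" %in% metrics)
      out$buried_sasa_A2 <- buried_sasa(fr, sides$antigen, sides$antibody,
                                        params = params)
    if ("energy" %in% metrics && !is.null(params)) {
      e <- interaction_energy(fr, sides$antigen, sides$antibody, params,
                              cutoff_A = config$energy_cutoff_A,
                              switch_on_A = config$energy_switch_on_A)
      out$e_elec <- e$electrostatic; out$e_vdw <- e$vdw
      out$e_total <- e$total
    }
    if ("waters" %in% metrics)
      out$n_waters <- count_waters_within(
        fr, sides$antigen, radius_A = config$water_radius_A)
    out
  })
  do.call(rbind, rows)
}

#' Recompute replica summaries from a printed per-run ratio table
#'
#' The entry point for checking published occupancy tables: given the
#' per-replica survival ratios exactly as printed, recompute the
#' max / ave / std (sample, n-1) columns. Printed summary columns, if
#' present, are kept with a `printed_` prefix for side-by-side comparison.
#'
#' @param x path to a TSV, or a data.frame. Required columns: `equ1`,
#'   `equ2`, ... (numeric per-run ratios); all other columns pass through.
#' @return data.frame with recomputed `max`, `ave`, `std` and, if the
#'   input carried a `loop` column, `loop_class`.
#' @export
ingest_printed_table <- function(x) {
  df <- if (is.character(x))
    utils::read.delim(x, stringsAsFactors = FALSE) else as.data.frame(x)
  run_cols <- grep("^equ[0-9]+$", names(df), ignore.case = TRUE,
                   value = TRUE)
  if (nrow(df) == 0) {
    df$max <- df$ave <- df$std <- numeric(0)
    return(df)
  }
  if (!length(run_cols)) stop("no per-run ratio columns (equ1, equ2, ...)")
  mat <- as.matrix(df[, run_cols, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "numeric")
  if (anyNA(mat)) stop("non-numeric survival ratio in rows: ",
                       paste(which(rowSums(is.na(mat)) > 0), collapse = ", "))
  if (any(mat < 0 | mat > 1)) stop("survival ratios must lie in [0, 1]")
  for (nm in c("max", "ave", "std"))
    if (nm %in% names(df)) names(df)[names(df) == nm] <- paste0("printed_", nm)
  df$max <- apply(mat, 1, max)
  df$ave <- rowMeans(mat)
  df$std <- if (length(run_cols) > 1) apply(mat, 1, stats::sd) else 0
  if ("loop" %in% names(df)) df$loop_class <- df$loop
  attr(df, "replica_labels") <- run_cols
  df
}

#' Path to a bundled printed occupancy table
#'
#' Bundled tables (TSV) carry the per-run survival ratios of published
#' occupancy tables for the eight study systems:
#' `table1` native complexes I and II, `table2` loop-truncated,
#' `table3` loop-rotated, `table4` body-rotated.
#'
#' @param name one of "table1".."table4".
#' @export
printed_table_path <- function(name = c("table1", "table2", "table3",
                                        "table4")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".tsv"), package = "ifacedyn",
              mustWork = TRUE)
}
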