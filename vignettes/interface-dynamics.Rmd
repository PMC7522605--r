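---
title: "Quantifying antibody-antigen interface dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying antibody-antigen interface dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifacedyn)
```

## The problem

Antibody epitopes are often composite: a checkpoint receptor such as PD-1
presents both a flexible N-terminal loop and loops of its IgV domain (the BC
and FG loops) to an antibody like nivolumab. Which part binds first, and
which part holds the complex together, is a dynamic question that a single
crystal structure cannot answer. The standard experimental design is to run
replicate equilibrium MD simulations of the native complex and of engineered
variants - the loop cut off, the loop swung away from the partner, or the
domain swung away - and then to quantify each trajectory's interface.

`ifacedyn` implements the post-processing side of that design. It does not
run MD; it consumes multi-model PDB trajectories (or its own synthetic
stand-ins) and produces the interface observables:

* per-frame interfacial hydrogen bonds and their per-replica
  **survival ratios** with max / mean / sd summaries,
* **buried SASA** as the interface-area measure,
* pairwise **interaction energy** (Coulomb + Lennard-Jones, switched
  cutoff),
* **partner-aligned segment RMSD**,
* **water accessibility** around interface loops, with replica-level
  significance testing.

## The model and its conventions

**Hydrogen bonds.** A bond exists between donor heavy atom D and acceptor A
(both N or O, on opposite binding partners) when the D-A distance is below
3.5 Å and the bonding angle is below 30°. The source convention leaves
"bonding angle" underspecified; we take the common trajectory-analysis
reading - the angle H-D-A at the donor between the D→H and D→A vectors -
and expose the D-H···A-linearity alternative via
`hbond_geometry(angle_convention = "dha")`. Donor capability is decided
geometrically (a hydrogen within 1.2 Å of the heavy atom), so no bonded
topology file is needed; input structures must therefore carry explicit
hydrogens, and hydrogen-free input is a hard error rather than a silent
distance-only fallback. Keys are direction-specific: the same atom pair
with donor and acceptor roles swapped is a different bond, matching how
published occupancy tables list the donor atom first.

**Survival ratio.** For one replica, the ratio of a bond is (frames
detected) / (frames analyzed). Across replicas we report max, arithmetic
mean, and the *sample* (n-1) standard deviation - the n-1 choice is not
cosmetic: the printed summary columns of the study's occupancy tables only
reproduce under it (verified for 108 of 109 rows; the one exception is a
documented misprint whose mean is inconsistent with any 3-value average).
A bond absent from a replica contributes ratio 0 there. The retention
filter keeps bonds whose maximum ratio, rounded to two decimals, is at or
above 0.2; inclusivity at exactly 0.20 is deliberate, because published
tables retain such rows.

**Equilibration.** Replicate runs reach a local minimum after roughly the
first fifth of the trajectory, so `run_config()` defaults to discarding the
leading 20 % of frames (ceiling rule). The discard lives in the config, not
hard-wired into `survival_ratio()`, because the printed-table and
scripted-fixture checks must count every frame.

**Buried SASA.** Shrake-Rupley with a deterministic golden-section spiral
(960 points per atom, probe 1.4 Å, heavy atoms only; the algorithm is a
package choice - the source used hand-written visualization-tool scripts
without naming one). Buried area is SASA(A) + SASA(B) − SASA(A∪B)
*without* halving, covering both faces of the interface; this matches the
magnitudes (~1,500-2,100 Å²) quoted for antibody epitopes in the
crystallographic literature the design follows.

**Interaction energy.** A pairwise post-processing energy, not a simulation
energy: Coulomb k·q·q/r with k = 332.0636 kcal·Å/(mol·e²) and dielectric 1,
plus Lennard-Jones with geometric-mean ε and arithmetic r_min combination,
both multiplied by a CHARMM-style switching function from 10 Å to the 12 Å
cutoff. No Ewald summation: the reference implementation in the field (an
energy plugin over a cutoff) behaves the same way, which is why absolute
kcal/mol values from full PME simulations are not comparable and are not
used as test surfaces.

**Aligned segment RMSD.** Each frame is superposed onto the reference by a
Kabsch fit of the *partner* (the antibody), then the heavy-atom RMSD of the
segment of interest (terminal loop or IgV body) is measured without
refitting. Global rigid motion cancels exactly; what remains is segment
motion relative to the partner.

**Water accessibility.** The count of distinct water molecules whose oxygen
lies within 4.0 Å (inclusive) of any heavy atom of the loop. Between-system
comparison uses a two-sided Welch t-test on per-replica means (n = replicas,
not frames), which avoids pretending autocorrelated frames are independent;
stars follow the usual `*` p < 0.05, `**` p < 0.01 convention.

## Scenario construction

Variants are built from a native frame:

* `truncate_segment()` removes a residue range and records the new terminus
  as capping metadata (cap atoms belong to MD preparation, not to geometric
  analysis, so none are built).
* `plan_rotation()` + `rotate_segment()` swing a segment rigidly about a
  hinge. The source states only "rotated backward at the interface with
  90°"; the axis and pivot are a package decision, made once: pivot at the
  Cα of the hinge residue (the body residue adjacent to the segment), axis
  along the cross product of the segment- and partner-centroid arms, and
  the sign of the angle chosen so the segment centroid moves *away* from
  the partner. Collinear-centroid degeneracy falls back to a deterministic
  orthogonal axis with a warning. Every rotated build must pass a 2.0 Å
  heavy-atom clash check against everything that stayed fixed, or the
  build fails with the offending pairs.

`build_all_scenarios()` applies all four constructions per native input,
so two crystal-structure inputs yield the eight-system study design.

## What the synthetic generator emulates - and what it does not

`generate_toy_complex()` builds a cartoon two-rigid-body complex: an
antigen chain with a body ("IgV") and a terminal loop, a two-chain
antibody, engineered donor-acceptor sites, and scripted per-frame
Bernoulli on/off schedules with known occupancies (defaults 0.9, 0.5, 0.3
on the loop and 0.7, 0.4 on the body - spanning the range seen in real
occupancy tables). In an "on" frame the acceptor oxygen sits collinear
with the donor N-H at 2.8 Å; "off" displaces it to 6.5 Å. Geometry is laid
out so no accidental contact satisfies the bond criteria, which is what
makes ground truth exact. `generate_rotation_trajectory()` produces a
segment relaxing from 90° back to 0° with the partner fixed, with the
exact rigid-rotation RMSD stored per frame; `place_water_shell()` adds a
deterministic water shell with an exhaustively computed expected count.

The generator is deliberately *not* physical: frames are independent (no
dwell-time kinetics), residues are 4-atom stubs, parameters are round
numbers, and solvent has no dynamics. A green test therefore establishes
that each analysis stage recovers known geometric/statistical ground truth
- not that the package reproduces any particular force field's energetics.
Trajectory-scale published numbers (buried SASA ≈ 1,600-1,800 Å²,
energies ≈ −260/−320 kcal/mol) require the original 100 ns trajectories
and are out of desk-scale reach by design; the published per-run survival
ratio tables, which are inputs rather than simulations, are checked
exactly via `ingest_printed_table()`.

## Numerical choices

* Golden-spiral quadrature makes SASA deterministic; the two-sphere
  analytic benchmark is met within 1 % at 960 points and error decreases
  monotonically with more points.
* Kabsch uses SVD with a determinant correction, always returning a proper
  rotation; collinear fit sets are rejected.
* Altloc handling keeps the highest-occupancy conformer, ties prefer
  altloc "A" - a deterministic tie-break.
* Residue numbering is author (PDB) numbering; ranges are inclusive on
  both ends (`P:25-34` has 10 residues when complete).
* Water residue names default to HOH/TIP3/WAT/SOL; hydrogens are
  recognized by element when present, else by the first alphabetic
  character of the atom name.
* Loop classification defaults: N-terminal 25-33, BC 56-64, FG 127-135.
  The FG upper bound is a reading (it keeps residues 133/135 in the FG
  class, as published tables do), not a stated fact; it is configurable.
* KDE summaries use Silverman's bandwidth with a 5 % prominence floor for
  mode counting, so the bimodality of re-binding runs is reported
  deterministically.

## Known limitations

* No mmCIF or binary trajectory formats (DCD/XTC); multi-model PDB is the
  interchange format.
* No protonation-state assignment or hydrogen building - hydrogens must be
  present.
* No PME electrostatics, free-energy estimates, or per-residue energy
  decomposition.
* The frame-saving interval of a trajectory is caller-supplied data
  (`dt_ps`); the package never assumes one.

## A worked example

```{r example, eval = FALSE}
library(ifacedyn)

# three synthetic replicas of the native system
reps <- list(
  Equ1 = generate_toy_complex(toy_spec(n_frames = 200, seed = 1), "Equ1")$trajectory,
  Equ2 = generate_toy_complex(toy_spec(n_frames = 200, seed = 2), "Equ2")$trajectory,
  Equ3 = generate_toy_complex(toy_spec(n_frames = 200, seed = 3), "Equ3")$trajectory)
g   <- generate_toy_complex(toy_spec(n_frames = 200, seed = 1))
cfg <- run_config(n_loop = c(25, 33), igv = c(34, 45),
                  equilibration_fraction = 0)

rb <- run_analysis(list(native = reps), params = g$params, config = cfg)
rb$bond_tables$native[, c("key", "Equ1", "Equ2", "Equ3",
                          "max", "ave", "std", "loop_class")]

# published occupancy table, summaries recomputed
t1 <- ingest_printed_table(printed_table_path("table1"))
nrow(filter_retained(t1[t1$complex == "Complex I", ]))   # 15
```
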