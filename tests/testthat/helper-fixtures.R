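# Shared fixtures: tiny PDB texts and small synthetic systems, built in code.

# 3-residue, 9-atom toy protein (two chains for chain-id checks)
toy_pdb_lines <- function() {
  c("CRYST1   30.000   30.000   30.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  N   SER A   2       3.300   1.500   0.000  1.00  0.00           N",
    "ATOM      5  CA  SER A   2       4.200   2.600   0.000  1.00  0.00           C",
    "ATOM      6  OG  SER A   2       5.500   2.100   0.000  1.00  0.00           O",
    "ATOM      7  N   GLY B   1       0.000   5.000   0.000  1.00  0.00           N",
    "ATOM      8  CA  GLY B   1       1.400   5.200   0.000  1.00  0.00           C",
    "ATOM      9  C   GLY B   1       2.200   6.400   0.000  1.00  0.00           C",
    "END")
}

write_toy_pdb <- function(lines = toy_pdb_lines()) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# 2-frame solvent fixture: 10 waters + 2 cosolvent molecules
toy_traj_lines <- function() {
  wat <- function(i, x, y, z, model_shift = 0)
    sprintf("ATOM  %5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
            i, i, x + model_shift, y, z)
  gol <- function(i, resno, x, y, z)
    sprintf("ATOM  %5d  C%d  GOL A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, (i - 1) %% 3 + 1, resno, x, y, z)
  frame <- function(shift) {
    w <- vapply(1:10, function(i) wat(i, i, 0, 0, shift), character(1))
    g <- c(gol(11, 11, 2, 2, 2), gol(12, 11, 2.5, 2, 2), gol(13, 11, 3, 2, 2),
           gol(14, 12, 8, 8, 8), gol(15, 12, 8.5, 8, 8), gol(16, 12, 9, 8, 8))
    c(w, g)
  }
  c("CRYST1   40.000   40.000   40.000  90.00  90.00  90.00 P 1           1",
    "MODEL        1", frame(0), "ENDMDL",
    "MODEL        2", frame(0.25), "ENDMDL", "END")
}

# single-atom solute with a chosen radius
one_atom_solute <- function(radius = 1.5) {
  solute(data.frame(x = 0, y = 0, z = 0, elety = "X", elem = "X",
                    chain = "A", resno = 1L, resid = "SYN", radius = radius))
}

# in-memory trajectory from a list of coordinate matrices, all-water
water_traj <- function(frames, box = NULL) {
  solvent_trajectory(frames, mol_species = rep("water", nrow(frames[[1L]])),
                     box = box)
}

# small mixed trajectory with explicit species
mixed_traj <- function(frames, species, box = NULL) {
  solvent_trajectory(frames, mol_species = species, box = box)
}

# quick uniform-solvent scenario around a small sphere
null_scenario <- function(seed, n_frames = 100, N_w = 300, N_x = 30,
                          box = c(36, 36, 36)) {
  scenario(sphere_solute(12, 4), box = box, N_w = N_w, N_x = N_x,
           n_frames = n_frames, seed = seed)
}

# noiseless 1:1 binding isotherm
langmuir_responses <- function(conc, K_A, R_max) R_max * K_A * conc / (1 + K_A * conc)
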