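# Shared fixtures and independent oracles. Oracles deliberately avoid
# the code paths they check: plain distance matrices and explicit loops
# instead of the package's pair enumeration.

.ensure_helix <- function(n) infer_bonds(make_ideal_helix(n)$structure)
.ensure_helix_obj <- function(h) infer_bonds(h$structure)

# write PDB text lines to a temp file and parse the first chain
parse_pdb_text <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  parse_pdb(f)
}

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, b = 0, element = substr(name, 1, 1),
                          record = "ATOM  ", alt = " ") {
  name4 <- if (nchar(name) <= 3) formatC(paste0(" ", name), width = -4) else name
  sprintf("%s%5d %s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, alt, resn, chain, resno, x, y, z, occ, b,
          formatC(element, width = 2))
}

# a minimal two-chain fixture: ALA-GLY on chain A, SER on chain B, one water
two_chain_pdb <- function() {
  c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 0.000, 0.000, 0.000),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.458, 0.000, 0.000),
    pdb_atom_line(3, "C",  "ALA", "A", 1, 2.009, 1.421, 0.000),
    pdb_atom_line(4, "O",  "ALA", "A", 1, 1.251, 2.390, 0.000),
    pdb_atom_line(5, "CB", "ALA", "A", 1, 1.988, -0.773, 1.199),
    pdb_atom_line(6, "N",  "GLY", "A", 2, 3.332, 1.536, 0.000),
    pdb_atom_line(7, "CA", "GLY", "A", 2, 4.041, 2.806, 0.000),
    pdb_atom_line(8, "C",  "GLY", "A", 2, 5.548, 2.600, 0.000),
    pdb_atom_line(9, "N",  "SER", "B", 1, 20.000, 0.000, 0.000),
    pdb_atom_line(10, "CA", "SER", "B", 1, 21.458, 0.000, 0.000),
    pdb_atom_line(11, "OG", "SER", "B", 1, 22.000, 1.300, 0.000),
    pdb_atom_line(12, "O", "HOH", "A", 90, 8.0, 8.0, 8.0, record = "HETATM"),
    "END"
  )
}

# distance-band contact counts by explicit double loop on a full
# distance matrix; valid for bond-free structures (atom clouds)
brute_contact_counts <- function(structure, config = default_config()) {
  at <- structure$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  r <- config$vdw_radii[at$element]
  kd <- config$kd_scale
  n <- nrow(at)
  counts <- c(repulsive = 0, vdw = 0, london = 0, hydrophobic = 0)
  wsum <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      rs <- r[[i]] + r[[j]]
      if (d < rs) counts["repulsive"] <- counts["repulsive"] + 1
      else if (d <= rs + config$bands$vdw_outer) counts["vdw"] <- counts["vdw"] + 1
      else if (d <= rs + config$bands$london_outer) counts["london"] <- counts["london"] + 1
      if (d <= config$hydrophobic$cutoff &&
          at$element[i] %in% c("C", "S") && at$element[j] %in% c("C", "S")) {
        counts["hydrophobic"] <- counts["hydrophobic"] + 1
        wsum <- wsum + (kd[[at$res_code[i]]] + kd[[at$res_code[j]]]) / 2
      }
    }
  }
  list(counts = counts, hydrophobic_weight = wsum)
}

# brute-force k-mer window counter
brute_kmer_counts <- function(sequence, k) {
  L <- nchar(sequence)
  if (L < k) return(table(character(0)))
  words <- vapply(seq_len(L - k + 1), function(i) substr(sequence, i, i + k - 1),
                  character(1))
  table(words)
}

# rigid rotation + translation of a structure's coordinates
rigid_transform <- function(structure, angles = c(0.3, 1.1, -0.7),
                            shift = c(5, -3, 2)) {
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                           3, byrow = TRUE)
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3, byrow = TRUE)
  R <- rx(angles[1]) %*% rz(angles[2]) %*% rx(angles[3])
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(R), 2, shift, `+`)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure$bonds <- NULL
  structure$sp2 <- NULL
  structure
}

benzene_mol2_lines <- function() {
  c("@<TRIPOS>MOLECULE", "benzene", " 6 6 1", "SMALL", "NO_CHARGES", "",
    "@<TRIPOS>ATOM",
    "  1 C1   1.3970  0.0000 0.0 C.ar 1 BNZ 0.0",
    "  2 C2   0.6985  1.2098 0.0 C.ar 1 BNZ 0.0",
    "  3 C3  -0.6985  1.2098 0.0 C.ar 1 BNZ 0.0",
    "  4 C4  -1.3970  0.0000 0.0 C.ar 1 BNZ 0.0",
    "  5 C5  -0.6985 -1.2098 0.0 C.ar 1 BNZ 0.0",
    "  6 C6   0.6985 -1.2098 0.0 C.ar 1 BNZ 0.0",
    "@<TRIPOS>BOND",
    " 1 1 2 ar", " 2 2 3 ar", " 3 3 4 ar",
    " 4 4 5 ar", " 5 5 6 ar", " 6 6 1 ar")
}

write_mol2 <- function(lines) {
  f <- tempfile(fileext = ".mol2")
  writeLines(lines, f)
  f
}

# hexagonal 6-carbon structure matching the benzene MOL2 atom count
benzene_structure <- function() {
  ang <- seq(0, by = pi / 3, length.out = 6)
  lines <- vapply(seq_len(6), function(i) {
    pdb_atom_line(i, "CB", "ALA", "A", i, 1.397 * cos(ang[i]),
                  1.397 * sin(ang[i]), 0)
  }, character(1))
  parse_pdb_text(c(lines, "END"))[[1]]
}

# Monte-Carlo ASA oracle for one sphere (center, radius) shadowed by
# other expanded spheres: random points, seeded, independent of the
# golden-spiral lattice under test.
mc_sphere_asa <- function(center, radius, others_xyz, others_r,
                          n = 1e6, seed = 99) {
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  pts <- sweep(v * radius, 2, center, `+`)
  acc <- rep(TRUE, n)
  if (length(others_r)) {
    for (b in seq_along(others_r)) {
      dx <- sweep(pts, 2, others_xyz[b, ], `-`)
      acc <- acc & rowSums(dx^2) > others_r[b]^2
    }
  }
  mean(acc) * 4 * pi * radius^2
}

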