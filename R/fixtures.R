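# Synthetic structures and sequences with ground truth known by
# construction. Fixtures are emitted as real PDB text and re-read
# through parse_pdb(), so anything built here exercises the full
# parsing path rather than internal constructors.

#' Write a protein structure as PDB text
#'
#' Minimal ATOM-record writer (chain from the structure, occupancy 1.00,
#' B-factor 0.00) used by the fixture generators and for round-trip
#' tests.
#'
#' @param structure A \code{protein_structure}.
#' @param path Output file path (optional).
#' @return The PDB lines, invisibly when \code{path} is given.
#' @export
write_pdb <- function(structure, path = NULL) {
  at <- structure$atoms
  res <- structure$residues
  resno <- res$resno[at$res_index]
  name4 <- ifelse(nchar(at$name) <= 3,
                  formatC(paste0(" ", at$name), width = -4),
                  substr(at$name, 1, 4))
  lines <- sprintf(
    "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), name4, at$res_name, structure$chain_id, resno,
    at$x, at$y, at$z, 1.00, 0.00,
    formatC(ifelse(at$element == "SE", "SE", at$element), width = 2))
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

# Build one residue's atom rows (data.frame) for fixture assembly.
.fixture_atoms <- function(names, elements, xyz, res_name, res_index,
                           resno = res_index) {
  data.frame(serial = NA_integer_, name = names, element = elements,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             res_index = res_index, res_code = unname(.aa_321[res_name]),
             res_name = res_name,
             is_sidechain = !(names %in% .backbone_atoms),
             vdw_radius = NA_real_, stringsAsFactors = FALSE)
}

# Assemble a protein_structure directly, then round-trip through PDB
# text and the public parser.
.fixture_structure <- function(atoms, chain_id = "A") {
  atoms$serial <- seq_len(nrow(atoms))
  first <- !duplicated(atoms$res_index)
  residues <- data.frame(res_index = atoms$res_index[first],
                         res_code = atoms$res_code[first],
                         res_name = atoms$res_name[first],
                         resno = atoms$res_index[first],
                         icode = "", stringsAsFactors = FALSE)
  s <- structure(list(chain_id = chain_id, atoms = atoms,
                      residues = residues, bonds = NULL, sp2 = NULL,
                      sequence = paste(residues$res_code, collapse = "")),
                 class = "protein_structure")
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  write_pdb(s, f)
  parse_pdb(f)[[1]]
}

#' Ideal poly-alanine alpha helix with known hydrogen-bond pattern
#'
#' Builds an n-residue poly-alanine chain with ideal helical backbone
#' dihedrals (phi = -57, psi = -47, omega = 180 degrees) and standard
#' bond lengths and angles, using internal-coordinate chain extension.
#' In such a helix the backbone amide of residue \code{i + 4} donates to
#' the carbonyl oxygen of residue \code{i}, giving exactly
#' \code{n_res - 4} expected backbone hydrogen bonds.
#'
#' @param n_res Number of residues (>= 5 so at least one hydrogen bond
#'   exists).
#' @return List: \code{structure} (a \code{protein_structure} re-read
#'   through the PDB parser), \code{expected_hbonds} (\code{n_res - 4}),
#'   and \code{hbond_pairs} (data.frame of expected donor/acceptor atom
#'   indices and their residue indices).
#' @export
make_ideal_helix <- function(n_res) {
  if (n_res < 5) stop("n_res must be >= 5 (no i -> i+4 hydrogen bond below that)")
  phi <- -57; psi <- -47; omega <- 180
  b_NCa <- 1.458; b_CaC <- 1.525; b_CN <- 1.329
  a_NCaC <- 111.2; a_CaCN <- 116.2; a_CNCa <- 121.7

  N <- matrix(NA_real_, n_res, 3)
  CA <- matrix(NA_real_, n_res, 3)
  C <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_NCa, 0, 0)
  ang <- a_NCaC * pi / 180
  C[1, ] <- CA[1, ] + b_CaC * c(-cos(ang), sin(ang), 0)
  for (i in 2:n_res) {
    N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          b_CN, a_CaCN, psi)
    CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                           b_NCa, a_CNCa, omega)
    C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ],
                          b_CaC, a_NCaC, phi)
  }
  O <- matrix(NA_real_, n_res, 3)
  CB <- matrix(NA_real_, n_res, 3)
  for (i in seq_len(n_res)) {
    # carbonyl O in the peptide plane, anti to the next N
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi + 180)
    CB[i, ] <- .place_atom(N[i, ], C[i, ], CA[i, ], 1.521, 110.5, 122.6)
  }
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    .fixture_atoms(c("N", "CA", "C", "O", "CB"),
                   c("N", "C", "C", "O", "C"),
                   rbind(N[i, ], CA[i, ], C[i, ], O[i, ], CB[i, ]),
                   "ALA", i)
  }))
  s <- .fixture_structure(atoms)
  don_idx <- which(s$atoms$name == "N")
  acc_idx <- which(s$atoms$name == "O")
  gt <- data.frame(
    donor_res = 5:n_res, acceptor_res = seq_len(n_res - 4),
    donor = don_idx[5:n_res], acceptor = acc_idx[seq_len(n_res - 4)]
  )
  list(structure = s, expected_hbonds = n_res - 4, hbond_pairs = gt)
}

#' Packed toy core: a cubic lattice of residues with a buried Leu pair
#'
#' Places alanine-like residues (N, CA, C, O, CB) on an
#' \code{n_side^3} cubic lattice. Residues on interior lattice sites are
#' surrounded on all six faces and are buried by construction; corner
#' residues are solvent exposed. When the lattice has at least two
#' interior sites (\code{n_side >= 4}), two adjacent interior sites
#' carry leucine-like residues (extra CG atom) whose side chains point
#' toward each other at hydrophobic-contact range (CG--CG 3.5
#' \enc{Å}{A}), giving a buried hydrophobic pair known by construction.
#'
#' @param n_side Lattice side length (default 4, i.e. 64 residues and an
#'   8-site interior).
#' @param spacing Lattice spacing in \enc{Å}{A} (default 5).
#' @return List: \code{structure}, \code{buried_res} (residue indices on
#'   interior lattice sites) and \code{leu_pair} (the two buried
#'   leucine residue indices, or NULL when \code{n_side < 4}).
#' @export
make_toy_core <- function(n_side = 4, spacing = 5) {
  stopifnot(n_side >= 2)
  grid <- expand.grid(ix = seq_len(n_side), iy = seq_len(n_side),
                      iz = seq_len(n_side))
  mid <- ceiling(n_side / 2)
  leu_sites <- if (n_side >= 4) {
    which((grid$ix %in% c(mid, mid + 1)) & grid$iy == mid & grid$iz == mid)
  } else integer(0)
  atoms <- NULL
  for (r in seq_len(nrow(grid))) {
    p <- as.numeric(grid[r, ]) * spacing
    ca <- p
    n <- p + c(-1.458, 0, 0)
    ang <- 111.2 * pi / 180
    cc <- p + 1.525 * c(-cos(ang), sin(ang), 0)
    o <- .place_atom(n, ca, cc, 1.231, 120.8, 0)
    cb <- p + c(0.5, -0.8, 1.2)
    if (r %in% leu_sites) {
      tilt <- if (r == leu_sites[1]) 1 else -1
      cg <- cb + c(0.55 * tilt, 0, 1.35)
      atoms <- rbind(atoms, .fixture_atoms(
        c("N", "CA", "C", "O", "CB", "CG"),
        c("N", "C", "C", "O", "C", "C"),
        rbind(n, ca, cc, o, cb, cg), "LEU", r))
    } else {
      atoms <- rbind(atoms, .fixture_atoms(
        c("N", "CA", "C", "O", "CB"), c("N", "C", "C", "O", "C"),
        rbind(n, ca, cc, o, cb), "ALA", r))
    }
  }
  interior <- grid$ix > 1 & grid$ix < n_side &
    grid$iy > 1 & grid$iy < n_side & grid$iz > 1 & grid$iz < n_side
  list(structure = .fixture_structure(atoms),
       buried_res = which(interior),
       leu_pair = if (length(leu_sites)) leu_sites else NULL)
}

#' Random atom cloud for brute-force contact oracles
#'
#' Seeded uniform placement of single-atom pseudo-residues inside a
#' cubic box, with a minimum pairwise separation (rejection sampling) so
#' that no accidental covalent bonds arise and every pair is a genuine
#' non-bonded pair.
#'
#' @param n Number of atoms (>= 2).
#' @param box Box edge length in \enc{Å}{A}.
#' @param seed Integer seed; same seed, same cloud.
#' @param elements Pool of element symbols to draw from.
#' @param min_sep Minimum pairwise distance (\enc{Å}{A}).
#' @return A \code{protein_structure} whose atoms are independent
#'   single-atom residues.
#' @export
make_atom_cloud <- function(n, box = 20, seed = 1,
                            elements = c("C", "N", "O", "S"),
                            min_sep = 2.7) {
  stopifnot(n >= 2)
  set.seed(seed)
  xyz <- matrix(NA_real_, n, 3)
  placed <- 0
  tries <- 0
  while (placed < n) {
    cand <- stats::runif(3, 0, box)
    if (placed == 0 ||
        min(sqrt(colSums((t(xyz[seq_len(placed), , drop = FALSE]) -
                            cand)^2))) >= min_sep) {
      placed <- placed + 1
      xyz[placed, ] <- cand
    }
    tries <- tries + 1
    if (tries > 1e6) stop("box too small for ", n,
                          " atoms at min_sep = ", min_sep)
  }
  el <- sample(elements, n, replace = TRUE)
  name <- paste0(el, "X")  # side-chain style names, element-resolvable
  atoms <- .fixture_atoms(name, el, xyz, "ALA", seq_len(n))
  .fixture_structure(atoms)
}

#' Seeded random amino acid sequence
#'
#' @param length Sequence length (>= 1).
#' @param alphabet Symbols to draw from (default: the 20 standard
#'   residues).
#' @param seed Integer seed.
#' @return Single character string of i.i.d. uniform draws.
#' @export
make_random_sequence <- function(length,
                                 alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                     "")[[1]],
                                 seed = 1) {
  stopifnot(length >= 1)
  set.seed(seed)
  paste(sample(alphabet, length, replace = TRUE), collapse = "")
}
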