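#' @importFrom stats setNames
NULL

# Resolve an element symbol from a PDB atom name (or bio3d elesy field).
# Returns NA for unresolvable names; callers decide whether that is fatal.
.resolve_element <- function(name, elesy = NA_character_) {
  known <- c("C", "N", "O", "S", "H", "P", "SE")
  out <- toupper(ifelse(is.na(elesy) | elesy == "", "", elesy))
  miss <- !(out %in% known)
  if (any(miss)) {
    cleaned <- toupper(gsub("[0-9']", "", name[miss]))
    guess <- ifelse(cleaned %in% known, cleaned, substr(cleaned, 1, 1))
    # Deuterium and proton variants both count as hydrogen
    guess[guess == "D"] <- "H"
    guess[!(guess %in% known)] <- NA_character_
    out[miss] <- guess
  }
  out[out == ""] <- NA_character_
  out
}

# Altloc resolution: within each (resno, icode, atom-name) group keep the
# copy with the highest occupancy, ties broken by altloc label 'A' (i.e.
# lexicographically smallest label).
.resolve_altloc <- function(atom) {
  alt <- ifelse(is.na(atom$alt), "", atom$alt)
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  key <- paste(atom$chain, atom$resno, ifelse(is.na(atom$insert), "", atom$insert),
               atom$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  keep <- !duplicated(key[ord])
  sort(ord[keep])
}

#' Parse a PDB file into per-chain protein structures
#'
#' Reads a PDB file, drops waters and non-peptide heteroatoms, resolves
#' alternate locations (highest occupancy, ties to label 'A'), and splits
#' the model into one structure per chain. Modified residues with a
#' standard peptide backbone (e.g. MSE, SEC, PYL, MVA) are retained and
#' mapped to their one-letter symbols.
#'
#' @param path Path to a PDB file.
#' @return A named list of \code{protein_structure} objects, one per
#'   chain, named \code{<file>_<chain>}. Chains without a single standard
#'   residue are skipped with a warning.
#' @seealso [parse_mol2()], [infer_bonds()]
#' @export
parse_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) {
    first_bad <- if (length(lines)) lines[[1]] else "<empty file>"
    stop("not PDB format (no ATOM records); first line: ", first_bad)
  }
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  atom <- pdb$atom

  # keep peptide residues only: ATOM records plus HETATMs with a known
  # 3-letter code; waters always excluded
  atom <- atom[!(atom$resid %in% .water_resids), , drop = FALSE]
  keep_het <- atom$type == "ATOM" | atom$resid %in% names(.aa_321)
  atom <- atom[keep_het, , drop = FALSE]
  if (nrow(atom) == 0) stop("no peptide atoms in ", path)
  atom <- atom[.resolve_altloc(atom), , drop = FALSE]

  atom$chain[is.na(atom$chain)] <- "A"
  stem <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  out <- list()
  for (ch in unique(atom$chain)) {
    a <- atom[atom$chain == ch, , drop = FALSE]
    std <- a$resid %in% names(.aa_321)
    if (!any(std)) {
      warning("chain ", ch, " of ", basename(path),
              " has no standard residue; skipped")
      next
    }
    if (any(!std)) {
      warning("chain ", ch, ": dropping ", sum(!std),
              " atoms of non-peptide residues (",
              paste(unique(a$resid[!std]), collapse = ","), ")")
      a <- a[std, , drop = FALSE]
    }
    out[[paste0(stem, "_", ch)]] <- .build_structure(a, ch)
  }
  if (length(out) == 0) stop("no chain with standard residues in ", path)
  out
}

# Assemble a protein_structure from a bio3d-style atom data.frame already
# restricted to one chain and to known residues.
.build_structure <- function(a, chain_id) {
  icode <- ifelse(is.na(a$insert), "", a$insert)
  ord <- order(a$resno, icode, seq_len(nrow(a)))
  a <- a[ord, , drop = FALSE]
  icode <- icode[ord]
  rkey <- paste(a$resno, icode, sep = "\r")
  res_index <- match(rkey, unique(rkey))

  element <- .resolve_element(a$elety, a$elesy)
  if (anyNA(element)) {
    bad <- which(is.na(element))[1]
    stop("unresolvable element for atom '", a$elety[bad], "' (serial ",
         a$eleno[bad], ", residue ", a$resid[bad], " ", a$resno[bad], ")")
  }

  atoms <- data.frame(
    serial = a$eleno,
    name = a$elety,
    element = element,
    x = a$x, y = a$y, z = a$z,
    res_index = res_index,
    res_code = unname(.aa_321[a$resid]),
    res_name = a$resid,
    is_sidechain = !(a$elety %in% .backbone_atoms),
    vdw_radius = NA_real_,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in chain ", chain_id)
  }
  first <- !duplicated(res_index)
  residues <- data.frame(
    res_index = res_index[first],
    res_code = atoms$res_code[first],
    res_name = atoms$res_name[first],
    resno = a$resno[first],
    icode = icode[first],
    stringsAsFactors = FALSE
  )
  structure(list(
    chain_id = chain_id,
    atoms = atoms,
    residues = residues,
    bonds = NULL,
    sp2 = NULL,
    sequence = paste(residues$res_code, collapse = "")
  ), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure: chain", x$chain_id, "|",
      nrow(x$residues), "residues |", nrow(x$atoms), "atoms |",
      if (is.null(x$bonds)) "no bond graph" else
        paste0(nrow(x$bonds$bonds), " bonds"), "\n")
  seq <- x$sequence
  if (nchar(seq) > 60) seq <- paste0(substr(seq, 1, 57), "...")
  cat("  sequence:", seq, "\n")
  invisible(x)
}

#' Parse a TRIPOS MOL2 file into a covalent bond graph
#'
#' Reads the \verb{@<TRIPOS>ATOM} and \verb{@<TRIPOS>BOND} sections and
#' returns typed bond edges plus per-atom sp2 flags derived from SYBYL
#' atom types and bond orders.
#'
#' @param path Path to a MOL2 file.
#' @param structure Optional \code{protein_structure} the MOL2 belongs
#'   to. If the atom counts disagree an error is raised, because bond
#'   indices could not be aligned safely.
#' @return A \code{bond_graph}: list with \code{bonds} (data.frame
#'   \code{i}, \code{j}, \code{type} with type in single/double/triple/
#'   amide/aromatic) and \code{sp2} (logical per atom).
#' @export
parse_mol2 <- function(path, structure = NULL) {
  m <- bio3d::read.mol2(path)
  n_atoms <- nrow(m$atom)
  if (!is.null(structure)) {
    if (n_atoms != nrow(structure$atoms)) {
      stop("MOL2 atom count (", n_atoms, ") != PDB atom count (",
           nrow(structure$atoms), "); refusing to pair them")
    }
  }
  type_map <- c("1" = "single", "2" = "double", "3" = "triple",
                am = "amide", ar = "aromatic")
  btype <- type_map[as.character(m$bond$type)]
  btype[is.na(btype)] <- "single"
  bonds <- data.frame(i = as.integer(m$bond$origin),
                      j = as.integer(m$bond$target),
                      type = unname(btype), stringsAsFactors = FALSE)
  bonds <- bonds[bonds$i != bonds$j, , drop = FALSE]
  if (any(bonds$i > n_atoms | bonds$j > n_atoms | bonds$i < 1 | bonds$j < 1)) {
    stop("MOL2 bond references an atom outside the ATOM section")
  }
  sp2_types <- c("C.2", "C.ar", "C.cat", "N.2", "N.ar", "N.am", "N.pl3",
                 "O.2", "O.co2")
  sp2 <- m$atom$elety %in% sp2_types
  part <- unique(c(bonds$i[bonds$type %in% c("double", "aromatic")],
                   bonds$j[bonds$type %in% c("double", "aromatic")]))
  sp2[part] <- TRUE
  structure(list(bonds = bonds, sp2 = sp2), class = "bond_graph")
}

#' Infer a covalent bond graph from geometry
#'
#' Fallback used when no MOL2 file accompanies a structure: two heavy
#' atoms are bonded when their distance does not exceed the sum of their
#' covalent radii plus a 0.45 \enc{Å}{A} tolerance. Inter-residue
#' backbone C--N bonds are typed \code{amide}; everything else is typed
#' \code{single}. sp2 flags come from residue templates (backbone
#' carbonyl C/O and amide N, side-chain aromatic and amide groups).
#'
#' @param structure A \code{protein_structure}.
#' @param config Configuration list, see [default_config()].
#' @return The structure with \code{bonds} (a \code{bond_graph}) and
#'   \code{sp2} filled in.
#' @export
infer_bonds <- function(structure, config = default_config()) {
  at <- structure$atoms
  n <- nrow(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  cov <- config$covalent_radii[at$element]
  cov[is.na(cov)] <- 0.77
  bonds <- data.frame(i = integer(0), j = integer(0),
                      type = character(0), stringsAsFactors = FALSE)
  if (n >= 2) {
    # candidate pairs within the maximum covalent reach
    reach <- 2 * max(cov) + config$covalent_tol
    cand <- .pairs_within(xyz, reach)
    if (nrow(cand)) {
      thr <- cov[cand$i] + cov[cand$j] + config$covalent_tol
      cand <- cand[cand$d <= thr, , drop = FALSE]
    }
    if (nrow(cand)) {
      type <- rep("single", nrow(cand))
      # peptide bond: backbone C of residue r to backbone N of residue r+1
      pep <- (at$name[cand$i] == "C" & at$name[cand$j] == "N" &
                at$res_index[cand$j] == at$res_index[cand$i] + 1) |
             (at$name[cand$j] == "C" & at$name[cand$i] == "N" &
                at$res_index[cand$i] == at$res_index[cand$j] + 1)
      type[pep] <- "amide"
      bonds <- data.frame(i = cand$i, j = cand$j, type = type,
                          stringsAsFactors = FALSE)
    }
  }
  sp2 <- at$name %in% c("C", "O", "N") & !(at$element == "H")
  for (rn in names(.sp2_atoms)) {
    sp2 <- sp2 | (at$res_name == rn & at$name %in% .sp2_atoms[[rn]])
  }
  structure$bonds <- structure(list(bonds = bonds, sp2 = sp2),
                               class = "bond_graph")
  structure$sp2 <- sp2
  structure
}

# Attach an externally parsed bond graph (e.g. from parse_mol2).
#' Attach a bond graph to a structure
#' @param structure A \code{protein_structure}.
#' @param graph A \code{bond_graph} from [parse_mol2()].
#' @return The structure with bonds set.
#' @export
set_bond_graph <- function(structure, graph) {
  stopifnot(inherits(graph, "bond_graph"))
  if (length(graph$sp2) != nrow(structure$atoms)) {
    stop("bond graph size does not match the structure")
  }
  structure$bonds <- graph
  structure$sp2 <- graph$sp2
  structure
}

# Make sure a structure carries a bond graph, inferring one if needed.
.ensure_bonds <- function(structure, config = default_config()) {
  if (is.null(structure$bonds)) structure <- infer_bonds(structure, config)
  structure
}

# Adjacency list (heavy + H) from the bond graph.
.adjacency <- function(structure) {
  n <- nrow(structure$atoms)
  adj <- vector("list", n)
  b <- structure$bonds$bonds
  if (!is.null(b) && nrow(b)) {
    for (k in seq_len(nrow(b))) {
      adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
      adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
    }
  }
  adj
}
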