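#' Assign van der Waals radii to every atom
#'
#' Element-wise lookup of Bondi-style radii; elements missing from the
#' table receive the configured default (1.70 \enc{Å}{A}) with a warning.
#'
#' @param structure A \code{protein_structure}.
#' @param config Configuration list, see [default_config()].
#' @return The structure with \code{atoms$vdw_radius} filled in.
#' @export
assign_vdw_radii <- function(structure, config = default_config()) {
  r <- config$vdw_radii[structure$atoms$element]
  if (anyNA(r)) {
    miss <- unique(structure$atoms$element[is.na(r)])
    warning("no vdW radius for element(s) ", paste(miss, collapse = ", "),
            "; using default ", config$vdw_default, " A")
    r[is.na(r)] <- config$vdw_default
  }
  structure$atoms$vdw_radius <- unname(r)
  structure
}

.has_radii <- function(structure) !anyNA(structure$atoms$vdw_radius)

#' Enumerate atom pairs within a distance cutoff
#'
#' Complete list of unordered atom pairs at distance \code{d <= cutoff},
#' annotated with the covalent-path class used to separate chain
#' geometry from genuine through-space interaction: \code{bonded_path}
#' is the number of covalent bonds on the shortest path between the two
#' atoms (1 = bonded, 2 = angle neighbour, 3 = torsion neighbour,
#' 4 = 1-5 pair), capped at 5 for anything farther apart or
#' disconnected. Non-bonded interaction features count pairs with
#' \code{bonded_path >= 5}: separations of up to four bonds are fixed
#' by bond lengths, angles and torsions -- every well-formed backbone
#' puts such pairs inside the van der Waals envelope -- so only the
#' 1-5-and-beyond pairs report real packing.
#'
#' @param structure A \code{protein_structure} (bonds inferred on the fly
#'   if absent).
#' @param cutoff Distance cutoff in \enc{Å}{A}; must be positive.
#' @param heavy_only Drop hydrogen atoms before pairing (default TRUE;
#'   all interaction features are heavy-atom based).
#' @return data.frame with columns \code{i}, \code{j} (atom row indices),
#'   \code{d} (\enc{Å}{A}) and \code{bonded_path}.
#' @export
neighbor_pairs <- function(structure, cutoff, heavy_only = TRUE) {
  stopifnot(cutoff > 0)
  structure <- .ensure_bonds(structure)
  at <- structure$atoms
  idx <- seq_len(nrow(at))
  if (heavy_only) idx <- idx[at$element != "H"]
  xyz <- as.matrix(at[idx, c("x", "y", "z")])
  p <- .pairs_within(xyz, cutoff)
  p$i <- idx[p$i]
  p$j <- idx[p$j]
  if (nrow(p) == 0) {
    p$bonded_path <- integer(0)
    return(p)
  }
  p$bonded_path <- .bond_path_class(structure, p$i, p$j, max_depth = 4L)
  p
}

# Shortest covalent path length between atom pairs, exact up to
# max_depth and capped at max_depth + 1 beyond (or when disconnected).
# Breadth-first search from each atom that occurs in the queries.
.bond_path_class <- function(structure, i, j, max_depth = 4L) {
  adj <- .adjacency(structure)
  n <- nrow(structure$atoms)
  out <- rep.int(max_depth + 1L, length(i))
  for (a in unique(i)) {
    dist <- rep.int(NA_integer_, n)
    dist[a] <- 0L
    frontier <- a
    for (d in seq_len(max_depth)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (!length(nxt)) break
      dist[nxt] <- d
      frontier <- nxt
    }
    sel <- which(i == a)
    dj <- dist[j[sel]]
    out[sel][!is.na(dj)] <- dj[!is.na(dj)]
  }
  out
}

#' Geometric center of an atom and its covalent neighbours
#'
#' Unweighted mean of the atom's own coordinates and those of all its
#' covalently bound neighbours. This center stands in for the (often
#' unresolved) hydrogen positions when scoring hydrogen-bond geometry,
#' so by default only heavy neighbours contribute -- results are then
#' identical whether or not explicit hydrogens are present.
#'
#' @param structure A \code{protein_structure} with bonds.
#' @param atom_id Atom row index.
#' @param heavy_only Ignore hydrogen neighbours (default TRUE).
#' @return Numeric 3-vector (\enc{Å}{A}).
#' @export
geometric_center <- function(structure, atom_id, heavy_only = TRUE) {
  structure <- .ensure_bonds(structure)
  adj <- .adjacency(structure)
  nb <- adj[[atom_id]]
  if (heavy_only) nb <- nb[structure$atoms$element[nb] != "H"]
  if (length(nb) == 0) stop("atom ", atom_id, " has no covalent neighbour; ",
                            "geometric center undefined")
  xyz <- as.matrix(structure$atoms[c(atom_id, nb), c("x", "y", "z")])
  colMeans(xyz)
}

#' Donor-side hydrogen-bond angle
#'
#' The angle at the donor between the direction from the donor to its
#' geometric center (the centroid of the donor and its covalent
#' neighbours) and the direction from the donor to the acceptor. Because
#' the implicit hydrogen sits opposite the covalent neighbours, a
#' perfectly linear D-H...A arrangement gives 180 degrees and a
#' perpendicular acceptor gives 90.
#'
#' @param structure A \code{protein_structure} with bonds.
#' @param donor,acceptor Atom row indices; must be N/O/S atoms with at
#'   least one covalent neighbour.
#' @return Angle in degrees, in \[0, 180\].
#' @export
hbond_angle <- function(structure, donor, acceptor) {
  structure <- .ensure_bonds(structure)
  at <- structure$atoms
  stopifnot(at$element[donor] %in% c("N", "O", "S", "SE"),
            at$element[acceptor] %in% c("N", "O", "S", "SE"))
  ctr <- geometric_center(structure, donor)
  dpos <- as.numeric(at[donor, c("x", "y", "z")])
  apos <- as.numeric(at[acceptor, c("x", "y", "z")])
  .angle_deg(ctr - dpos, apos - dpos)
}

# Template-based donor/acceptor/polarity classification of heavy atoms.
# Returns a data.frame with logical columns donor, acceptor and the
# 5-level polarity class.
.polarity_table <- function(structure) {
  at <- structure$atoms
  donor <- (at$name == "N" & at$res_name != "PRO" & !at$is_sidechain)
  acceptor <- at$name %in% c("O", "OXT") & !at$is_sidechain
  for (rn in names(.donor_atoms)) {
    donor <- donor | (at$res_name == rn & at$name %in% .donor_atoms[[rn]])
  }
  for (rn in names(.acceptor_atoms)) {
    acceptor <- acceptor |
      (at$res_name == rn & at$name %in% .acceptor_atoms[[rn]])
  }
  # apolar: carbons not bonded to N/O, plus sulfur/selenium
  structure <- .ensure_bonds(structure)
  adj <- .adjacency(structure)
  apolar <- logical(nrow(at))
  for (k in seq_len(nrow(at))) {
    if (at$element[k] %in% c("S", "SE")) {
      apolar[k] <- TRUE
    } else if (at$element[k] == "C") {
      nb <- adj[[k]]
      apolar[k] <- !any(at$element[nb] %in% c("N", "O"))
    }
  }
  cls <- ifelse(donor & acceptor, "donor_acceptor",
         ifelse(donor, "donor",
         ifelse(acceptor, "acceptor",
         ifelse(apolar, "apolar", "polar"))))
  data.frame(donor = donor, acceptor = acceptor, apolar = apolar,
             polarity_class = cls, stringsAsFactors = FALSE)
}

#' Detect intramolecular hydrogen bonds and score their geometry
#'
#' Scans all donor--acceptor pairs (template-assigned N/O/S donors, N/O
#' acceptors, heavy-atom only) beyond the covalent 1-5 horizon (see
#' [neighbor_pairs()]), keeps pairs with donor--acceptor distance \code{d <= d_max}
#' (3.5 \enc{Å}{A}) and donor angle \code{alpha >= alpha_min} (100
#' degrees), and scores each as the product of a linear distance weight
#' and a linear angle weight:
#' \deqn{w_d = clamp((d_{max} - d) / (d_{max} - d_{ideal}), 0, 1), \quad
#'       w_\alpha = (\alpha - \alpha_{min}) / (180 - \alpha_{min})}
#' An ideal bond (2.6 \enc{Å}{A}, 180 degrees) scores 1; bonds at either
#' threshold score 0.
#'
#' @param structure A \code{protein_structure}.
#' @param config Configuration list, see [default_config()].
#' @return data.frame with columns \code{donor}, \code{acceptor} (atom
#'   indices), \code{d_DA}, \code{alpha}, \code{score}.
#' @export
detect_hbonds <- function(structure, config = default_config()) {
  structure <- .ensure_bonds(structure, config)
  if (!.has_radii(structure)) structure <- assign_vdw_radii(structure, config)
  pol <- .polarity_table(structure)
  at <- structure$atoms
  hb <- config$hbond
  pairs <- neighbor_pairs(structure, hb$d_max, heavy_only = TRUE)
  pairs <- pairs[pairs$bonded_path >= config$nonbonded_min_path, , drop = FALSE]
  empty <- data.frame(donor = integer(0), acceptor = integer(0),
                      d_DA = numeric(0), alpha = numeric(0),
                      score = numeric(0))
  if (nrow(pairs) == 0) return(empty)
  # orient each candidate pair donor -> acceptor (both orders tried)
  cand <- rbind(
    data.frame(donor = pairs$i, acceptor = pairs$j, d_DA = pairs$d),
    data.frame(donor = pairs$j, acceptor = pairs$i, d_DA = pairs$d)
  )
  ok <- pol$donor[cand$donor] & pol$acceptor[cand$acceptor] &
    at$element[cand$acceptor] %in% c("N", "O")
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  adj <- .adjacency(structure)
  heavy <- at$element != "H"
  xyz <- as.matrix(at[, c("x", "y", "z")])
  centers <- new.env(parent = emptyenv())
  center_of <- function(a) {
    k <- as.character(a)
    if (!is.null(centers[[k]])) return(centers[[k]])
    nb <- adj[[a]]
    nb <- nb[heavy[nb]]
    ctr <- colMeans(xyz[c(a, nb), , drop = FALSE])
    centers[[k]] <- ctr
    ctr
  }
  cand$alpha <- vapply(seq_len(nrow(cand)), function(k) {
    d <- cand$donor[k]
    nb <- adj[[d]]
    if (!length(nb[heavy[nb]])) return(0)
    .angle_deg(center_of(d) - xyz[d, ], xyz[cand$acceptor[k], ] - xyz[d, ])
  }, numeric(1))
  cand <- cand[cand$alpha >= hb$alpha_min, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  w_d <- .clamp((hb$d_max - cand$d_DA) / (hb$d_max - hb$d_ideal), 0, 1)
  w_a <- (cand$alpha - hb$alpha_min) / (180 - hb$alpha_min)
  cand$score <- w_d * w_a
  rownames(cand) <- NULL
  cand
}
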