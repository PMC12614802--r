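# Non-bonded pairs (beyond the 1-5 covalent horizon) with radii sums.
.nonbonded <- function(structure, pairs,
                       min_path = default_config()$nonbonded_min_path) {
  p <- pairs[pairs$bonded_path >= min_path, , drop = FALSE]
  r <- structure$atoms$vdw_radius
  p$rsum <- r[p$i] + r[p$j]
  p
}

#' Count van der Waals contacts
#'
#' Non-bonded heavy-atom pairs whose distance lies in the contact band
#' \code{rsum <= d <= rsum + 0.7} \enc{Å}{A}, where \code{rsum} is the
#' sum of the two van der Waals radii. The 0.7 \enc{Å}{A} outer offset
#' delimits close contact from the longer-range dispersion shell.
#'
#' @param structure A \code{protein_structure} with radii assigned.
#' @param pairs Output of [neighbor_pairs()] at a cutoff covering the
#'   band of interest.
#' @param config Configuration list (band offsets).
#' @return Integer count.
#' @export
vdw_contacts <- function(structure, pairs, config = default_config()) {
  p <- .nonbonded(structure, pairs, config$nonbonded_min_path)
  sum(p$d >= p$rsum & p$d <= p$rsum + config$bands$vdw_outer)
}

#' Count repulsive (clash) contacts
#'
#' Non-bonded heavy-atom pairs closer than the sum of their van der
#' Waals radii, i.e. pairs whose electron clouds overlap.
#'
#' @inheritParams vdw_contacts
#' @return Integer count.
#' @export
repulsive_contacts <- function(structure, pairs, config = default_config()) {
  p <- .nonbonded(structure, pairs, config$nonbonded_min_path)
  sum(p$d < p$rsum)
}

#' Count London-dispersion contacts
#'
#' Non-bonded heavy-atom pairs in the dispersion shell beyond the van
#' der Waals contact band: \code{rsum + 0.7 < d <= rsum + 3.0}
#' \enc{Å}{A}. By construction this set is disjoint from the vdW
#' contact set.
#'
#' @inheritParams vdw_contacts
#' @return Integer count.
#' @export
london_contacts <- function(structure, pairs, config = default_config()) {
  p <- .nonbonded(structure, pairs, config$nonbonded_min_path)
  sum(p$d > p$rsum + config$bands$vdw_outer &
        p$d <= p$rsum + config$bands$london_outer)
}

#' Hydrophobic contacts and hydrophobicity sums
#'
#' A hydrophobic contact is a pair of apolar heavy atoms (carbon not
#' bonded to N/O, or sulfur) from the side chains of two distinct
#' residues at distance \code{d <= 4.5} \enc{Å}{A}. Four quantities are
#' returned: the raw contact count; the count restricted to the protein
#' interior (both residues with relative ASA below the burial
#' threshold); and the corresponding hydropathy-weighted sums, where
#' each contact contributes the mean Kyte--Doolittle value of its two
#' residues.
#'
#' @param structure A \code{protein_structure} with radii assigned.
#' @param pairs Output of [neighbor_pairs()].
#' @param asa Optional [compute_asa()] result (computed on the fly if
#'   missing).
#' @param config Configuration list.
#' @return Named list: \code{count_total}, \code{count_internal},
#'   \code{weighted_total}, \code{weighted_internal}.
#' @export
hydrophobic_contacts <- function(structure, pairs, asa = NULL,
                                 config = default_config()) {
  if (is.null(asa)) {
    asa <- compute_asa(structure, config$asa$probe, config$asa$n_points,
                       config)
  }
  pol <- .polarity_table(structure)
  at <- structure$atoms
  p <- .nonbonded(structure, pairs, config$nonbonded_min_path)
  p <- p[p$d <= config$hydrophobic$cutoff, , drop = FALSE]
  ok <- pol$apolar[p$i] & pol$apolar[p$j] &
    at$is_sidechain[p$i] & at$is_sidechain[p$j] &
    at$res_index[p$i] != at$res_index[p$j]
  p <- p[ok, , drop = FALSE]
  kd <- config$kd_scale
  ri <- at$res_index[p$i]
  rj <- at$res_index[p$j]
  codes <- structure$residues$res_code
  w <- (kd[codes[ri]] + kd[codes[rj]]) / 2
  w[is.na(w)] <- 0
  rel <- asa$per_residue_relative_asa
  buried <- rel < config$hydrophobic$burial_rasa
  internal <- buried[ri] & buried[rj]
  list(count_total = nrow(p),
       count_internal = sum(internal),
       weighted_total = sum(w),
       weighted_internal = sum(w[internal]))
}

#' Deformation effect (rotatable-bond count)
#'
#' Static proxy for the intrinsic conformational flexibility of the
#' chain: the number of rotatable bonds, i.e. acyclic single bonds
#' between two heavy atoms that each have at least two heavy
#' neighbours, excluding amide (peptide and side-chain amide) bonds and
#' bonds internal to ring templates.
#'
#' @param structure A \code{protein_structure} with a bond graph.
#' @return Integer count.
#' @export
deformation_effect <- function(structure) {
  structure <- .ensure_bonds(structure)
  at <- structure$atoms
  b <- structure$bonds$bonds
  if (is.null(b) || nrow(b) == 0) return(0L)
  heavy <- at$element != "H"
  bh <- b[heavy[b$i] & heavy[b$j], , drop = FALSE]
  if (nrow(bh) == 0) return(0L)
  # heavy-atom degree
  deg <- tabulate(c(bh$i, bh$j), nbins = nrow(at))
  in_ring <- logical(nrow(at))
  for (rn in names(.ring_atoms)) {
    in_ring <- in_ring | (at$res_name == rn & at$name %in% .ring_atoms[[rn]])
  }
  same_res <- at$res_index[bh$i] == at$res_index[bh$j]
  ring_bond <- in_ring[bh$i] & in_ring[bh$j] & same_res
  # side-chain amide C-N bonds (Asn/Gln) are planar, not rotatable
  sc_amide <- (at$res_name[bh$i] == "ASN" &
                 at$name[bh$i] %in% c("CG", "ND2") &
                 at$name[bh$j] %in% c("CG", "ND2")) |
              (at$res_name[bh$i] == "GLN" &
                 at$name[bh$i] %in% c("CD", "NE2") &
                 at$name[bh$j] %in% c("CD", "NE2"))
  rot <- bh$type == "single" & !ring_bond & !(sc_amide & same_res) &
    deg[bh$i] >= 2 & deg[bh$j] >= 2
  sum(rot)
}

#' Surface-tension features
#'
#' \code{total_surface_tension} is the atomic-solvation-weighted surface
#' sum \eqn{\sum_a \sigma(class_a) \cdot ASA_a} over heavy atoms, with
#' Eisenberg--McLachlan-style parameters per atom class (apolar carbon,
#' neutral N/O, charged O, charged N, sulfur).
#' \code{internal_tension} sums the absolute Kyte--Doolittle hydropathy
#' of all buried residues (relative ASA below the burial threshold),
#' capturing the cohesion of the packed interior.
#'
#' @param structure A \code{protein_structure} with radii assigned.
#' @param asa A [compute_asa()] result.
#' @param config Configuration list.
#' @return Named list: \code{total_surface_tension} (kcal/mol scale),
#'   \code{internal_tension} (unitless hydropathy sum).
#' @export
tension_features <- function(structure, asa, config = default_config()) {
  at <- structure$atoms
  sig <- config$solvation
  cls <- at$element
  cls[!(cls %in% c("C", "N", "O", "S"))] <- "default"
  for (rn in names(.charged_O)) {
    cls[at$res_name == rn & at$name %in% .charged_O[[rn]]] <- "O_charged"
  }
  for (rn in names(.charged_N)) {
    cls[at$res_name == rn & at$name %in% .charged_N[[rn]]] <- "N_charged"
  }
  cls[at$name == "OXT"] <- "O_charged"
  total <- sum(sig[cls] * asa$per_atom_asa, na.rm = TRUE)

  rel <- asa$per_residue_relative_asa
  buried <- rel < config$hydrophobic$burial_rasa
  kd <- config$kd_scale[structure$residues$res_code]
  kd[is.na(kd)] <- 0
  list(total_surface_tension = total,
       internal_tension = sum(abs(kd[buried])))
}

#' Names of the 11 interaction features, in export order
#' @return Character vector of length 11.
#' @export
interaction_feature_names <- function() {
  c("hydrophobic_contacts", "vdw_contacts", "deformation_effect",
    "hbond_score", "repulsive_contacts", "london_contacts",
    "total_hydrophobicity", "internal_hydrophobicity",
    "total_surface_tension", "internal_tension", "total_asa")
}

#' Compute the full interatomic-interaction feature vector
#'
#' Runs the whole structural pipeline on one chain -- radii assignment,
#' bond inference (unless a MOL2-derived graph is attached), neighbour
#' search, hydrogen-bond scoring, accessible surface area -- and emits
#' the 11 interaction/physicochemical features in a fixed order:
#' hydrophobic contact count, vdW contact count, deformation effect
#' (rotatable bonds), summed hydrogen-bond score, repulsive contact
#' count, London-dispersion contact count, total and internal
#' (contact-weighted) hydrophobicity, total surface tension, internal
#' tension, and total ASA.
#'
#' @param structure A \code{protein_structure}.
#' @param config Configuration list, see [default_config()].
#' @return Named numeric vector of length 11.
#' @export
interaction_vector <- function(structure, config = default_config()) {
  structure <- .ensure_bonds(structure, config)
  structure <- assign_vdw_radii(structure, config)
  cutoff <- max(config$neighbor_cutoff,
                2 * max(structure$atoms$vdw_radius) +
                  config$bands$london_outer)
  pairs <- neighbor_pairs(structure, cutoff)
  asa <- compute_asa(structure, config$asa$probe, config$asa$n_points, config)
  hb <- detect_hbonds(structure, config)
  hyd <- hydrophobic_contacts(structure, pairs, asa, config)
  ten <- tension_features(structure, asa, config)
  out <- c(
    hyd$count_total,
    vdw_contacts(structure, pairs, config),
    deformation_effect(structure),
    sum(hb$score),
    repulsive_contacts(structure, pairs, config),
    london_contacts(structure, pairs, config),
    hyd$weighted_total,
    hyd$weighted_internal,
    ten$total_surface_tension,
    ten$internal_tension,
    asa$total_asa
  )
  names(out) <- interaction_feature_names()
  out
}
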