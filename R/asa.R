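# Deterministic golden-spiral point set on the unit sphere. Using a
# fixed lattice (rather than random sampling) makes ASA bit-reproducible
# without any seed.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere (default radius 1.4 \enc{Å}{A}) over the
#' heavy-atom van der Waals spheres, sampling each expanded sphere with a
#' deterministic golden-spiral lattice. A sample point is accessible when
#' it lies outside every neighbouring expanded sphere; the accessible
#' fraction times the expanded-sphere area gives the per-atom ASA.
#'
#' @param structure A \code{protein_structure} (radii assigned on the
#'   fly if absent). Hydrogens are ignored.
#' @param probe Probe radius in \enc{Å}{A}.
#' @param n_points Sphere sample points per atom (>= 32; accuracy floor).
#' @param config Configuration list (radius tables).
#' @return List of class \code{asa_result}: \code{per_atom_asa}
#'   (\enc{Å²}{A^2}, 0 for hydrogens), \code{total_asa}, and
#'   \code{per_residue_relative_asa} -- residue ASA divided by the
#'   tabulated maximum exposure in an extended Gly-X-Gly reference.
#' @export
compute_asa <- function(structure, probe = 1.4, n_points = 256L,
                        config = default_config()) {
  if (n_points < 32) stop("n_points must be >= 32 for a usable ASA estimate")
  if (!.has_radii(structure)) structure <- assign_vdw_radii(structure, config)
  at <- structure$atoms
  heavy <- which(at$element != "H")
  xyz <- as.matrix(at[heavy, c("x", "y", "z")])
  rad <- at$vdw_radius[heavy] + probe
  n <- length(heavy)
  sp <- .sphere_points(as.integer(n_points))
  per_atom <- numeric(nrow(at))

  if (n > 0) {
    # neighbour lists from one pass over pairs within max reach
    reach <- 2 * max(rad)
    nb_pairs <- .pairs_within(xyz, reach)
    nb_pairs <- nb_pairs[nb_pairs$d < rad[nb_pairs$i] + rad[nb_pairs$j], ,
                         drop = FALSE]
    nb <- vector("list", n)
    if (nrow(nb_pairs)) {
      s <- split(c(nb_pairs$j, nb_pairs$i), c(nb_pairs$i, nb_pairs$j))
      nb[as.integer(names(s))] <- s
    }
    area <- numeric(n)
    for (a in seq_len(n)) {
      pts <- sweep(sp * rad[a], 2, xyz[a, ], `+`)
      acc <- rep(TRUE, n_points)
      for (b in nb[[a]]) {
        if (!any(acc)) break
        dx <- pts[acc, 1] - xyz[b, 1]
        dy <- pts[acc, 2] - xyz[b, 2]
        dz <- pts[acc, 3] - xyz[b, 3]
        acc[acc] <- dx * dx + dy * dy + dz * dz > rad[b]^2
      }
      area[a] <- sum(acc) / n_points * 4 * pi * rad[a]^2
    }
    per_atom[heavy] <- area
  }

  res_asa <- tapply(per_atom, at$res_index, sum)
  codes <- structure$residues$res_code
  maxa <- config$max_asa[codes]
  maxa[is.na(maxa)] <- mean(config$max_asa)
  rel <- as.numeric(res_asa[as.character(structure$residues$res_index)]) /
    unname(maxa)
  structure(list(per_atom_asa = per_atom,
                 total_asa = sum(per_atom),
                 per_residue_relative_asa = rel),
            class = "asa_result")
}
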