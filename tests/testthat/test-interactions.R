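# two disconnected carbon pseudo-residues at distance d
two_carbons <- function(d) {
  s <- parse_pdb_text(c(pdb_atom_line(1, "CB", "ALA", "A", 1, 0, 0, 0),
                        pdb_atom_line(2, "CB", "ALA", "A", 2, d, 0, 0),
                        "END"))[[1]]
  assign_vdw_radii(s)
}

test_that("distance bands split contacts at the documented boundaries", {
  cases <- list(
    # d, repulsive, vdw, london   (C+C radius sum = 3.40)
    list(3.00, 1, 0, 0),
    list(3.40, 0, 1, 0),   # lower vdW boundary inclusive
    list(4.10, 0, 1, 0),   # = sum + 0.7, still vdW
    list(4.20, 0, 0, 1),   # just past the vdW band
    list(5.00, 0, 0, 1),   # inside the dispersion shell
    list(6.40, 0, 0, 1),   # = sum + 3.0, outer edge inclusive
    list(6.50, 0, 0, 0)    # beyond every band
  )
  for (cs in cases) {
    s <- two_carbons(cs[[1]])
    p <- neighbor_pairs(s, 7)
    expect_equal(repulsive_contacts(s, p), cs[[2]], label = paste("rep", cs[[1]]))
    expect_equal(vdw_contacts(s, p), cs[[3]], label = paste("vdw", cs[[1]]))
    expect_equal(london_contacts(s, p), cs[[4]], label = paste("lon", cs[[1]]))
  }
})

test_that("every non-bonded pair falls in exactly one band or none", {
  cfg <- default_config()
  for (seed in 1:5) {
    cl <- assign_vdw_radii(make_atom_cloud(80, box = 18, seed = seed))
    p <- neighbor_pairs(cl, 10)
    nb <- p[p$bonded_path >= cfg$nonbonded_min_path, ]
    r <- cl$atoms$vdw_radius
    rsum <- r[nb$i] + r[nb$j]
    in_rep <- nb$d < rsum
    in_vdw <- nb$d >= rsum & nb$d <= rsum + cfg$bands$vdw_outer
    in_lon <- nb$d > rsum + cfg$bands$vdw_outer &
      nb$d <= rsum + cfg$bands$london_outer
    expect_true(all(in_rep + in_vdw + in_lon <= 1))
    expect_equal(sum(in_rep), repulsive_contacts(cl, p))
    expect_equal(sum(in_vdw), vdw_contacts(cl, p))
    expect_equal(sum(in_lon), london_contacts(cl, p))
  }
})

test_that("widening the dispersion shell never loses contacts", {
  cl <- assign_vdw_radii(make_atom_cloud(100, box = 20, seed = 3))
  p <- neighbor_pairs(cl, 12)
  cfg <- default_config()
  prev <- -1
  for (outer in c(1.5, 2, 3, 4, 5)) {
    cfg$bands$london_outer <- outer
    now <- london_contacts(cl, p, cfg)
    expect_gte(now, prev)
    prev <- now
  }
})

test_that("contact counts match a brute-force double loop on atom clouds", {
  for (seed in 1:6) {
    n <- c(50, 100, 200, 300, 400, 500)[seed]
    cl <- assign_vdw_radii(make_atom_cloud(n, box = (n * 180)^(1/3), seed = seed))
    p <- neighbor_pairs(cl, 9)
    oracle <- brute_contact_counts(cl)
    expect_equal(repulsive_contacts(cl, p), unname(oracle$counts["repulsive"]))
    expect_equal(vdw_contacts(cl, p), unname(oracle$counts["vdw"]))
    expect_equal(london_contacts(cl, p), unname(oracle$counts["london"]))
    hyd <- hydrophobic_contacts(cl, p)
    expect_equal(hyd$count_total, unname(oracle$counts["hydrophobic"]))
    expect_equal(hyd$weighted_total, oracle$hydrophobic_weight)
  }
})

test_that("hydrophobic contacts require apolar side-chain atoms of distinct residues", {
  # Ser OG (polar O) next to a Leu-like CB: no hydrophobic contact
  lines <- c(pdb_atom_line(1, "CB", "SER", "A", 1, 0, 0, 0),
             pdb_atom_line(2, "OG", "SER", "A", 1, 0, 1.4, 0),
             pdb_atom_line(3, "CB", "LEU", "A", 5, 4.0, 1.4, 0),
             "END")
  s <- assign_vdw_radii(parse_pdb_text(lines)[[1]])
  p <- neighbor_pairs(s, 7)
  h <- hydrophobic_contacts(s, p)
  # OG is polar, and the Ser CB is polarised by its bonded oxygen: nothing counts
  expect_equal(h$count_total, 0)
  # two packed Leu-like CB atoms at 4 A do count
  s2 <- two_carbons(4.0)
  h2 <- hydrophobic_contacts(s2, neighbor_pairs(s2, 7))
  expect_equal(h2$count_total, 1)
  # the buried Leu pair of the toy core is counted in total and internal
  tc <- make_toy_core()
  stc <- assign_vdw_radii(tc$structure)
  ptc <- neighbor_pairs(stc, 6.8)
  htc <- hydrophobic_contacts(stc, ptc)
  expect_gte(htc$count_total, 1)
  expect_gte(htc$count_internal, 1)
  expect_lte(htc$count_internal, htc$count_total)
  expect_equal(htc$weighted_internal, htc$weighted_total)  # pair is buried
})

test_that("rotatable-bond count follows the template bookkeeping", {
  # single alanine: only CA-C qualifies
  h5 <- make_ideal_helix(5)
  lines <- write_pdb(h5$structure)
  single <- parse_pdb_text(c(lines[1:5], "END"))[[1]]
  expect_equal(deformation_effect(single), 1)
  # poly-Gly of n residues: (n-1) phi + n psi bonds = 2n - 1
  for (n in c(5, 9)) {
    hl <- write_pdb(make_ideal_helix(n)$structure)
    gly <- gsub("ALA", "GLY", hl[!grepl(" CB ", hl)])
    s <- parse_pdb_text(gly)[[1]]
    expect_equal(deformation_effect(s), 2 * n - 1)
  }
  # aromatic ring: nothing rotatable
  b <- benzene_structure()
  b <- set_bond_graph(b, parse_mol2(write_mol2(benzene_mol2_lines()), b))
  expect_equal(deformation_effect(b), 0)
})

test_that("surface tension composes solvation parameters with ASA", {
  iso <- assign_vdw_radii(parse_pdb_text(
    c(pdb_atom_line(1, "CB", "ALA", "A", 1, 0, 0, 0), "END"))[[1]])
  asa <- compute_asa(iso)
  ten <- tension_features(iso, asa)
  expect_equal(ten$total_surface_tension, 0.016 * 4 * pi * 3.1^2,
               tolerance = 0.005)
  expect_equal(ten$internal_tension, 0)  # single exposed residue
  # toy core: internal tension is the |KD| sum over its buried residues
  tc <- make_toy_core()
  stc <- assign_vdw_radii(tc$structure)
  atc <- compute_asa(stc)
  ttc <- tension_features(stc, atc)
  kd <- default_config()$kd_scale
  hand <- sum(abs(kd[tc$structure$residues$res_code[tc$buried_res]]))
  expect_equal(ttc$internal_tension, hand)
})

test_that("the interaction vector has 11 named features in fixed order", {
  h <- make_ideal_helix(10)
  iv <- interaction_vector(h$structure)
  expect_named(iv, interaction_feature_names())
  expect_length(iv, 11)
  expect_gt(iv[["hbond_score"]], 0)
  expect_equal(iv[["repulsive_contacts"]], 0)
  # single isolated residue: contacts all zero, ASA positive
  lines <- write_pdb(h$structure)
  single <- parse_pdb_text(c(lines[1:5], "END"))[[1]]
  ivs <- interaction_vector(single)
  expect_equal(unname(ivs[c("hydrophobic_contacts", "vdw_contacts",
                            "repulsive_contacts", "london_contacts")]),
               c(0, 0, 0, 0))
  expect_gt(ivs[["total_asa"]], 0)
})

test_that("the interaction vector is rigid-motion invariant", {
  h <- make_ideal_helix(10)$structure
  iv0 <- interaction_vector(h)
  iv1 <- interaction_vector(rigid_transform(h))
  exact <- c("hydrophobic_contacts", "vdw_contacts", "deformation_effect",
             "repulsive_contacts", "london_contacts")
  expect_equal(iv0[exact], iv1[exact], tolerance = 1e-9)
  expect_equal(iv0[["hbond_score"]], iv1[["hbond_score"]], tolerance = 1e-6)
  # ASA-derived features: the sampling lattice is orientation-fixed, so
  # rotation agreement is at the lattice resolution, not 1e-6
  asaish <- c("total_hydrophobicity", "internal_hydrophobicity",
              "total_surface_tension", "internal_tension", "total_asa")
  for (f in asaish) {
    denom <- max(abs(iv0[[f]]), 1)
    expect_lt(abs(iv0[[f]] - iv1[[f]]) / denom, 0.02)
  }
})
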